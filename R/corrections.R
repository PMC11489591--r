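#' Correction configuration
#'
#' Fixed pre-processing adjustments applied before any fitting:
#'
#' * `crust_mgca_fraction` (default 0.15): tow (ontogenetic) Mg/Ca is lowered
#'   by this fraction to make it comparable to crusted material, because
#'   gametogenic crust dilutes whole-test Mg/Ca by ~15%.
#' * `crust_d18O_offset` (default +2 permil): tow calcite d18O is raised to
#'   the crusted reference, the crust being isotopically heavier.
#' * `cleaning_mgca_fraction` (default 0.15, published range 0.10-0.15):
#'   compensating uplift for Mg lost during reductive cleaning.
#' * `sl_coeff` (default 0.11 permil per 10 m of sea level): ice-volume
#'   correction on d18O.
#' * `vital_effect_d18O` (default 0): optional species disequilibrium offset.
#'
#' @param crust_mgca_fraction,cleaning_mgca_fraction Fractions in [0, 0.3].
#' @param crust_d18O_offset Permil VPDB.
#' @param sl_coeff Permil per 10 m of relative sea-level change (> 0).
#' @param vital_effect_d18O Permil.
#' @return An object of class `correction_config`.
#' @export
correction_config <- function(crust_mgca_fraction = 0.15,
                              crust_d18O_offset = 2.0,
                              cleaning_mgca_fraction = 0.15,
                              sl_coeff = 0.11,
                              vital_effect_d18O = 0) {
  if (crust_mgca_fraction < 0 || crust_mgca_fraction > 0.3 ||
      cleaning_mgca_fraction < 0 || cleaning_mgca_fraction > 0.3) {
    abort("correction_config(): fractions must lie in [0, 0.3]")
  }
  if (sl_coeff <= 0) abort("correction_config(): sl_coeff must be > 0")
  structure(list(crust_mgca_fraction = crust_mgca_fraction,
                 crust_d18O_offset = crust_d18O_offset,
                 cleaning_mgca_fraction = cleaning_mgca_fraction,
                 sl_coeff = sl_coeff,
                 vital_effect_d18O = vital_effect_d18O),
            class = "correction_config")
}

#' Adjust tow Mg/Ca to the crusted reference
#'
#' Multiplies ontogenetic (tow) Mg/Ca by (1 - crust fraction), emulating the
#' Mg dilution that crust addition causes in sedimentary material. Refuses to
#' run on already-crusted samples: the adjustment must be applied exactly
#' once.
#'
#' @param mgca Measured Mg/Ca of tow material, mmol/mol (>= 0).
#' @param crust_state `"ontogenetic"` (required) - passing `"crusted"` raises
#'   a double-correction error.
#' @param cfg A [correction_config()].
#' @return Adjusted Mg/Ca, mmol/mol.
#' @examples
#' crust_adjust_mgca(1.0) # 0.85
#' @export
crust_adjust_mgca <- function(mgca, crust_state = "ontogenetic",
                              cfg = correction_config()) {
  if (any(crust_state == "crusted")) {
    abort(paste0("crust_adjust_mgca(): sample already crusted; applying the ",
                 "tow-to-crust adjustment twice would compound it"))
  }
  if (any(mgca < 0, na.rm = TRUE)) abort("crust_adjust_mgca(): mgca must be >= 0")
  mgca * (1 - cfg$crust_mgca_fraction)
}

#' Adjust tow calcite d18O to the crusted reference
#'
#' Adds the crust offset (default +2 permil) to ontogenetic calcite d18O.
#' Refuses already-crusted samples (double-correction guard).
#'
#' @param d18Oc Tow calcite d18O, permil VPDB.
#' @inheritParams crust_adjust_mgca
#' @return Adjusted d18O, permil VPDB.
#' @examples
#' crust_adjust_d18O(1.0) # 3.0
#' @export
crust_adjust_d18O <- function(d18Oc, crust_state = "ontogenetic",
                              cfg = correction_config()) {
  if (any(crust_state == "crusted")) {
    abort("crust_adjust_d18O(): sample already crusted (double-correction guard)")
  }
  d18Oc + cfg$crust_d18O_offset
}

#' Compensate Mg/Ca for reductive cleaning
#'
#' Reductive cleaning (and repeated acid leaching) strips Mg from
#' foraminiferal calcite; measured values from such protocols are raised by
#' the configured fraction (default +15%, published range +10-15%) so that
#' datasets cleaned differently can be pooled. Oxidative-only cleaning is
#' left unchanged; unknown methods pass through with a warning.
#'
#' @param mgca Measured Mg/Ca, mmol/mol.
#' @param cleaning `"reductive"`, `"oxidative"` or `"unknown"` (vectorized).
#' @param cfg A [correction_config()].
#' @return Adjusted Mg/Ca, mmol/mol.
#' @examples
#' cleaning_adjust_mgca(1.0, "reductive") # 1.15
#' @export
cleaning_adjust_mgca <- function(mgca, cleaning, cfg = correction_config()) {
  cleaning <- rep_len(cleaning, length(mgca))
  unknown <- !cleaning %in% c("reductive", "oxidative")
  if (any(unknown)) {
    warn(sprintf("cleaning_adjust_mgca(): %d sample(s) with unknown cleaning method left unchanged",
                 sum(unknown)))
  }
  ifelse(cleaning == "reductive", mgca * (1 + cfg$cleaning_mgca_fraction), mgca)
}

#' Read a sea-level curve CSV
#'
#' Expects columns `age_ka` (strictly increasing) and `rsl_m` (relative sea
#' level, m; negative at glacials).
#'
#' @param path CSV path.
#' @return A tibble `age_ka`, `rsl_m`.
#' @export
read_sealevel_curve <- function(path) {
  curve <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("age_ka", "rsl_m"), names(curve))
  if (length(miss)) {
    abort(paste0("read_sealevel_curve(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  validate_sealevel_curve(curve)
}

validate_sealevel_curve <- function(curve) {
  curve <- as_tibble(curve)
  if (is.unsorted(curve$age_ka, strictly = TRUE)) {
    abort("sea-level curve ages must be strictly increasing")
  }
  if (any(!is.finite(curve$rsl_m))) {
    abort("sea-level curve rsl_m must be finite")
  }
  curve
}

#' Correct calcite d18O for ice-volume (sea-level) changes
#'
#' Removes the whole-ocean d18O_sw enrichment tied to continental ice volume
#' before calcite d18O is interpreted as a carbonate-ion proxy:
#' d18O_corr = d18O + rsl(age)/10 * sl_coeff. With the sign convention that
#' relative sea level is negative at glacials, the correction subtracts at
#' glacials (at -120 m it removes 1.32 permil with the default 0.11
#' permil/10 m coefficient) and is the identity at rsl = 0.
#'
#' @param d18Oc Calcite d18O, permil VPDB (vectorized).
#' @param age_ka Sample age(s), ka; must lie inside the curve's range.
#' @param curve A sea-level curve tibble (`age_ka`, `rsl_m`).
#' @param cfg A [correction_config()].
#' @return Corrected d18O, permil VPDB.
#' @export
sealevel_correct_d18O <- function(d18Oc, age_ka, curve,
                                  cfg = correction_config()) {
  curve <- validate_sealevel_curve(curve)
  rng <- range(curve$age_ka)
  if (any(age_ka < rng[1] | age_ka > rng[2])) {
    abort(sprintf("sealevel_correct_d18O(): age outside curve range [%g, %g] ka",
                  rng[1], rng[2]))
  }
  rsl <- approx(curve$age_ka, curve$rsl_m, xout = age_ka)$y
  d18Oc + rsl / 10 * cfg$sl_coeff
}

#' Standardise a sample table to the crusted, oxidatively-cleaned reference
#'
#' Applies, each exactly once, the crust adjustments (tow Mg/Ca down by the
#' crust fraction, tow d18O up by the crust offset) and the reductive-cleaning
#' compensation, returning a table whose Mg/Ca and d18O are directly
#' comparable across tow, core-top and downcore material. Bookkeeping columns
#' `corr_crust` and `corr_cleaning` record what was applied; re-running on an
#' already-standardised table raises rather than silently compounding.
#'
#' @param samples A sample tibble with `mgca_mmolmol`, `crust_state`,
#'   `cleaning` and optionally `d18Oc_permil`.
#' @param cfg A [correction_config()].
#' @param adjust_d18O Also shift tow d18O to the crusted reference (default
#'   TRUE); when applied, `crust_state` becomes `"crusted"` and the original
#'   state is kept in `crust_state_original`. Set FALSE when the d18O -
#'   carbonate-ion lines will be fitted with per-group intercepts on
#'   as-measured values.
#' @return The table with adjusted values and bookkeeping columns.
#' @export
standardize_samples <- function(samples, cfg = correction_config(),
                                adjust_d18O = TRUE) {
  stopifnot(is.data.frame(samples))
  if (any(c("corr_crust", "corr_cleaning") %in% names(samples))) {
    abort("standardize_samples(): table already standardised (double-correction guard)")
  }
  samples <- as_tibble(samples)
  if (!"crust_state" %in% names(samples)) samples$crust_state <- "crusted"
  if (!"cleaning" %in% names(samples)) samples$cleaning <- "oxidative"
  tow <- samples$crust_state == "ontogenetic"
  if ("mgca_mmolmol" %in% names(samples)) {
    samples$mgca_mmolmol[tow] <-
      crust_adjust_mgca(samples$mgca_mmolmol[tow], "ontogenetic", cfg)
    samples$mgca_mmolmol <-
      cleaning_adjust_mgca(samples$mgca_mmolmol, samples$cleaning, cfg)
  }
  if (adjust_d18O && "d18Oc_permil" %in% names(samples)) {
    samples$d18Oc_permil[tow] <-
      crust_adjust_d18O(samples$d18Oc_permil[tow], "ontogenetic", cfg)
    samples$crust_state_original <- samples$crust_state
    samples$crust_state[tow] <- "crusted"
  }
  samples$corr_crust <- tow
  samples$corr_cleaning <- samples$cleaning == "reductive"
  samples
}
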