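#' Exponential Mg/Ca-temperature law
#'
#' Container for Mg/Ca = a * exp(b * T) laws. The default prediction law
#' (a = 0.4 mmol/mol, b = 0.09 per degree C) is the temperature-only
#' neogloboquadrinid sensitivity assumed shared between N. incompta and
#' N. pachyderma; the corrected calibration fitted by
#' [fit_temp_calibration()] is also returned in this class.
#'
#' @param a Pre-exponential coefficient, mmol/mol (> 0).
#' @param b Exponential temperature coefficient, per degree C (> 0).
#' @param a_se,b_se 2-sigma coefficient uncertainties (optional).
#' @param n,r2 Fit size and natural-scale r-squared (optional).
#' @param cov Coefficient covariance matrix from the fit (optional).
#' @return An object of class `exp_law`.
#' @examples
#' mgca_exp_law(0.372, 0.0936)
#' @export
mgca_exp_law <- function(a, b, a_se = NA_real_, b_se = NA_real_,
                         n = NA_integer_, r2 = NA_real_, cov = NULL) {
  if (!is.finite(a) || a <= 0) abort("exp_law: a must be > 0")
  if (!is.finite(b) || b <= 0) abort("exp_law: b must be > 0")
  structure(list(a = a, b = b, a_se = a_se, b_se = b_se,
                 n = n, r2 = r2, cov = cov),
            class = "exp_law")
}

#' Default temperature-only Mg/Ca prediction law
#'
#' Mg/Ca_pred = 0.4 * exp(0.09 T): the temperature-only sensitivity used to
#' normalise measured Mg/Ca and expose the carbonate-ion overprint.
#' @return An `exp_law` with a = 0.4, b = 0.09.
#' @export
mgca_pred_law <- function() mgca_exp_law(0.4, 0.09)

#' Power-law Mg/Ca sensitivity to carbonate ion
#'
#' Container for S([CO3]) = p * [CO3]^q, the non-thermal multiplier on Mg/Ca.
#' q must be negative: the overprint weakens as carbonate ion rises.
#'
#' @param p Coefficient (> 0).
#' @param q Exponent (< 0).
#' @inheritParams mgca_exp_law
#' @return An object of class `power_law`.
#' @examples
#' mgca_power_law(3227.95, -1.53)
#' @export
mgca_power_law <- function(p, q, p_se = NA_real_, q_se = NA_real_,
                           n = NA_integer_, r2 = NA_real_, cov = NULL) {
  if (!is.finite(p) || p <= 0) abort("power_law: p must be > 0")
  if (!is.finite(q) || q >= 0) abort("power_law: q must be < 0")
  structure(list(p = p, q = q, p_se = p_se, q_se = q_se,
                 n = n, r2 = r2, cov = cov),
            class = "power_law")
}

#' @export
print.exp_law <- function(x, ...) {
  cat(sprintf("Mg/Ca = %.4g * exp(%.4g T)", x$a, x$b))
  if (is.finite(x$a_se)) cat(sprintf("  [2s: a %.3g, b %.3g]", x$a_se, x$b_se))
  if (is.finite(x$r2)) cat(sprintf("  n = %d, r2 = %.3f", x$n, x$r2))
  cat("\n")
  invisible(x)
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("S([CO3]) = %.6g * [CO3]^%.4g", x$p, x$q))
  if (is.finite(x$p_se)) cat(sprintf("  [2s: p %.3g, q %.3g]", x$p_se, x$q_se))
  if (is.finite(x$r2)) cat(sprintf("  n = %d, r2 = %.3f", x$n, x$r2))
  cat("\n")
  invisible(x)
}

#' @method tidy exp_law
#' @export
tidy.exp_law <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b),
         std.error.2s = c(x$a_se, x$b_se))
}

#' @method glance exp_law
#' @export
glance.exp_law <- function(x, ...) tibble(n = x$n, r.squared = x$r2)

#' @method tidy power_law
#' @export
tidy.power_law <- function(x, ...) {
  tibble(term = c("p", "q"), estimate = c(x$p, x$q),
         std.error.2s = c(x$p_se, x$q_se))
}

#' @method glance power_law
#' @export
glance.power_law <- function(x, ...) tibble(n = x$n, r.squared = x$r2)

#' Predict Mg/Ca from temperature alone
#'
#' Evaluates the temperature-only exponential law a * exp(b T).
#'
#' @param temperature Calcification temperature, degrees C (vectorized).
#' @param law An [mgca_exp_law()]; defaults to the 0.4 * exp(0.09 T)
#'   prediction law.
#' @return Predicted Mg/Ca, mmol/mol.
#' @examples
#' predict_mgca(0)   # 0.4
#' predict_mgca(10)  # ~0.984
#' @export
predict_mgca <- function(temperature, law = mgca_pred_law()) {
  stopifnot(inherits(law, "exp_law"))
  law$a * exp(law$b * temperature)
}

#' Normalise measured Mg/Ca against the temperature-only prediction
#'
#' Mg/Ca_norm = Mg/Ca_meas / Mg/Ca_pred(T); values above 1 quantify how much
#' the measurement overshoots the purely thermal expectation.
#'
#' @param mgca Measured Mg/Ca, mmol/mol (> 0).
#' @inheritParams predict_mgca
#' @return Dimensionless normalised Mg/Ca.
#' @export
normalize_mgca <- function(mgca, temperature, law = mgca_pred_law()) {
  if (any(!is.finite(mgca) | mgca <= 0)) {
    abort("normalize_mgca(): mgca must be positive")
  }
  mgca / predict_mgca(temperature, law)
}

#' Carbonate-ion concentration at which the Mg/Ca overprint vanishes
#'
#' The published sensitivity 3227.95 * [CO3]^-1.53 equals unity at
#' 3227.95^(1/1.53) = 196.5 umol/kg, matching the observation that the
#' carbonate-ion effect on neogloboquadrinid Mg/Ca disappears near
#' 200 umol/kg. Used as the default level anchor of the sensitivity fit: a
#' correction factor must leave Mg/Ca untouched where the effect it corrects
#' is absent, and without a level constraint only the product of the
#' calibration pre-exponential and the sensitivity coefficient would be
#' identified.
#'
#' @return The no-effect threshold, umol/kg.
#' @export
co3_no_effect <- function() 3227.95^(1 / 1.53)

#' Fit the power-law Mg/Ca sensitivity to carbonate ion
#'
#' Fits S = p * [CO3]^q to normalised Mg/Ca. The noise on normalised Mg/Ca
#' scales with the sensitivity itself (a constant coefficient of variation),
#' so the default estimator is ordinary least squares in log-log space - the
#' classical, stable choice for multiplicative power laws. Natural-scale
#' nonlinear least squares (initialised from the log fit) is available via
#' `scale = "natural"` but is markedly noisier for the exponent under
#' realistic scatter. r-squared is always reported on the natural scale;
#' coefficient uncertainties are 2-sigma.
#'
#' When `anchor_co3` is supplied the fit is constrained to S(anchor_co3) = 1:
#' the exponent comes from the log-log slope and the coefficient is
#' p = anchor_co3^(-q). This identifying convention (used by the full
#' calibration chain with [co3_no_effect()]) keeps the correction neutral
#' where the carbonate-ion effect is absent.
#'
#' @param data A data frame with columns `mgca_norm` and `co3_umolkg`.
#' @param scale `"log"` (default) or `"natural"`.
#' @param anchor_co3 Optional carbonate-ion value (umol/kg) where the fitted
#'   sensitivity is constrained to unity; NULL (default) fits the level
#'   freely.
#' @return A [mgca_power_law()] with fitted coefficients, 2-sigma errors,
#'   `n`, `r2` and the coefficient covariance matrix (on the fitting scale).
#' @export
fit_co3_sensitivity <- function(data, scale = c("log", "natural"),
                                anchor_co3 = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data))
  need <- c("mgca_norm", "co3_umolkg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("fit_co3_sensitivity(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  d <- data[is.finite(data$mgca_norm) & is.finite(data$co3_umolkg), need]
  if (nrow(d) < 3) abort("fit_co3_sensitivity(): need at least 3 samples")
  if (any(d$co3_umolkg <= 0)) abort("fit_co3_sensitivity(): co3 must be > 0")
  if (length(unique(d$co3_umolkg)) < 2) {
    abort("fit_co3_sensitivity(): degenerate fit, all co3 values identical")
  }
  ok <- d$mgca_norm > 0
  init <- lm(log(mgca_norm) ~ log(co3_umolkg), data = d[ok, ])
  natural_r2 <- function(p, q) {
    fitted <- p * d$co3_umolkg^q
    1 - sum((d$mgca_norm - fitted)^2) /
      sum((d$mgca_norm - mean(d$mgca_norm))^2)
  }
  if (!is.null(anchor_co3)) {
    stopifnot(anchor_co3 > 0)
    q <- unname(coef(init)[2])
    q_se <- 2 * sqrt(diag(vcov(init)))[2]
    p <- anchor_co3^(-q)
    return(mgca_power_law(p, q,
                          p_se = unname(log(anchor_co3) * p * q_se), # delta
                          q_se = unname(q_se),
                          n = sum(ok), r2 = natural_r2(p, q),
                          cov = vcov(init)))
  }
  if (scale == "log") {
    cf <- coef(init)
    se <- sqrt(diag(vcov(init)))
    p <- exp(unname(cf[1]))
    q <- unname(cf[2])
    return(mgca_power_law(p, q,
                          p_se = 2 * p * unname(se[1]), # delta method
                          q_se = 2 * unname(se[2]),
                          n = sum(ok), r2 = natural_r2(p, q),
                          cov = vcov(init)))
  }
  start <- list(p = exp(unname(coef(init)[1])), q = unname(coef(init)[2]))
  fit <- minpack.lm::nlsLM(mgca_norm ~ p * co3_umolkg^q, data = d,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se2 <- 2 * sqrt(diag(vcov(fit)))
  mgca_power_law(unname(cf["p"]), unname(cf["q"]),
                 p_se = unname(se2["p"]), q_se = unname(se2["q"]),
                 n = nrow(d), r2 = natural_r2(cf["p"], cf["q"]),
                 cov = vcov(fit))
}

#' Evaluate the Mg/Ca carbonate-ion sensitivity
#'
#' S = p * [CO3]^q. Near the ~220 umol/kg top of the calibrated range the
#' sensitivity approaches unity (no carbonate-ion overprint); inputs above
#' 250 umol/kg trigger an out-of-calibration warning.
#'
#' @param co3 Carbonate-ion concentration, umol/kg (> 0, vectorized).
#' @param law A [mgca_power_law()].
#' @return Dimensionless sensitivity multiplier.
#' @examples
#' co3_sensitivity(200, mgca_power_law(3227.95, -1.53)) # ~0.97
#' @export
co3_sensitivity <- function(co3, law) {
  stopifnot(inherits(law, "power_law"))
  if (any(!is.finite(co3) | co3 <= 0)) {
    abort("co3_sensitivity(): co3 must be positive")
  }
  if (any(co3 > 250)) {
    warn("co3_sensitivity(): carbonate ion above 250 umol/kg, outside the calibrated range")
  }
  law$p * co3^law$q
}

#' Correct measured Mg/Ca for the carbonate-ion overprint
#'
#' Mg/Ca_corr = Mg/Ca_meas / S([CO3]): divides out the non-thermal power-law
#' multiplier so that the remainder responds to temperature only.
#'
#' @param mgca Measured Mg/Ca, mmol/mol (> 0).
#' @inheritParams co3_sensitivity
#' @return Corrected Mg/Ca, mmol/mol.
#' @export
correct_mgca <- function(mgca, co3, law) {
  if (any(!is.finite(mgca) | mgca <= 0)) {
    abort("correct_mgca(): mgca must be positive")
  }
  mgca / co3_sensitivity(co3, law)
}

#' Fit the corrected Mg/Ca-temperature exponential calibration
#'
#' Fits Mg/Ca_corr = a * exp(b T). The default is nonlinear least squares on
#' the natural scale (the corrected values carry an absolute, roughly
#' homoscedastic uncertainty), initialised from the log-linear ordinary
#' least-squares fit; `scale = "log"` performs the log-linear fit directly,
#' which spreads leverage evenly across the temperature range and is the
#' refit used inside the Monte Carlo slope ensemble. r-squared is reported
#' on the natural scale either way; the coefficient covariance is retained
#' for Monte Carlo propagation.
#'
#' @param data A data frame with columns `mgca_corr` and `temp_C`.
#' @param scale `"natural"` (default) or `"log"`.
#' @return An [mgca_exp_law()] with fitted coefficients, 2-sigma errors, `n`,
#'   natural-scale `r2` and covariance.
#' @export
fit_temp_calibration <- function(data, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data))
  need <- c("mgca_corr", "temp_C")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("fit_temp_calibration(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  d <- data[is.finite(data$mgca_corr) & is.finite(data$temp_C), need]
  if (nrow(d) < 3) abort("fit_temp_calibration(): need at least 3 samples")
  if (diff(range(d$temp_C)) <= 2) {
    abort("fit_temp_calibration(): degenerate fit, temperature range must span > 2 C")
  }
  ok <- d$mgca_corr > 0
  init <- lm(log(mgca_corr) ~ temp_C, data = d[ok, ])
  natural_r2 <- function(a, b) {
    1 - sum((d$mgca_corr - a * exp(b * d$temp_C))^2) /
      sum((d$mgca_corr - mean(d$mgca_corr))^2)
  }
  if (scale == "log") {
    cf <- coef(init)
    se <- sqrt(diag(vcov(init)))
    a <- exp(unname(cf[1]))
    b <- unname(cf[2])
    return(mgca_exp_law(a, b,
                        a_se = 2 * a * unname(se[1]), # delta method
                        b_se = 2 * unname(se[2]),
                        n = sum(ok), r2 = natural_r2(a, b),
                        cov = vcov(init)))
  }
  start <- list(a = exp(unname(coef(init)[1])), b = unname(coef(init)[2]))
  fit <- minpack.lm::nlsLM(mgca_corr ~ a * exp(b * temp_C), data = d,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se2 <- 2 * sqrt(diag(vcov(fit)))
  mgca_exp_law(unname(cf["a"]), unname(cf["b"]),
               a_se = unname(se2["a"]), b_se = unname(se2["b"]),
               n = nrow(d), r2 = natural_r2(cf["a"], cf["b"]),
               cov = vcov(fit))
}

#' Invert the corrected calibration to temperature
#'
#' T = ln(Mg/Ca_corr / a) / b.
#'
#' @param mgca_corr Corrected Mg/Ca, mmol/mol (> 0, vectorized).
#' @param law An [mgca_exp_law()], typically the fitted corrected calibration.
#' @return Temperature, degrees C.
#' @examples
#' invert_temperature(0.372, mgca_exp_law(0.372, 0.0936)) # 0
#' @export
invert_temperature <- function(mgca_corr, law) {
  stopifnot(inherits(law, "exp_law"))
  if (any(!is.finite(mgca_corr) | mgca_corr <= 0)) {
    abort("invert_temperature(): mgca_corr must be positive")
  }
  log(mgca_corr / law$a) / law$b
}

#' Shared-slope calcite d18O - carbonate ion lines
#'
#' Container for the oxygen-isotope carbonate-ion proxy: a common slope
#' (permil per umol/kg, negative) with separate intercepts for ontogenetic
#' (tow) and crusted (core-top/fossil) calcite; the crust is isotopically
#' heavier by ~2 permil.
#'
#' @param slope Common slope, permil per umol/kg (< 0).
#' @param intercept_ontogenetic,intercept_crusted Intercepts, permil VPDB
#'   (either may be NA when only one population was fitted).
#' @param n Number of samples behind the fit.
#' @param slope_se 2-sigma uncertainty on the slope (optional).
#' @return An object of class `oxy_carb_line`.
#' @export
oxy_carb_line <- function(slope, intercept_ontogenetic = NA_real_,
                          intercept_crusted = NA_real_, n = NA_integer_,
                          slope_se = NA_real_) {
  if (!is.finite(slope) || slope >= 0) abort("oxy_carb_line: slope must be < 0")
  if (is.finite(intercept_ontogenetic) && is.finite(intercept_crusted) &&
      intercept_crusted <= intercept_ontogenetic) {
    abort("oxy_carb_line: crusted intercept must exceed the ontogenetic one")
  }
  structure(list(slope = slope,
                 intercept_ontogenetic = intercept_ontogenetic,
                 intercept_crusted = intercept_crusted,
                 n = n, slope_se = slope_se),
            class = "oxy_carb_line")
}

#' @export
print.oxy_carb_line <- function(x, ...) {
  cat(sprintf("d18O_c = intercept %+.4g * [CO3]\n", x$slope))
  cat(sprintf("  intercepts: ontogenetic %.4g, crusted %.4g (n = %d)\n",
              x$intercept_ontogenetic, x$intercept_crusted, x$n))
  invisible(x)
}

#' @method tidy oxy_carb_line
#' @export
tidy.oxy_carb_line <- function(x, ...) {
  tibble(term = c("slope", "intercept_ontogenetic", "intercept_crusted"),
         estimate = c(x$slope, x$intercept_ontogenetic, x$intercept_crusted))
}

#' Fit the d18O - carbonate ion proxy lines
#'
#' ANCOVA-style common-slope, two-intercept least squares of calcite d18O on
#' carbonate-ion concentration, grouped by crust state. The shared-slope model
#' reflects the observation that ontogenetic and crusted populations carry
#' statistically identical slopes and differ only by a constant isotopic
#' offset. With a single crust group present an ordinary one-line fit is
#' returned (the other intercept stays NA).
#'
#' @param data A data frame with columns `d18Oc_permil`, `co3_umolkg` and
#'   `crust_state` (values `"ontogenetic"` or `"crusted"`).
#' @return An [oxy_carb_line()].
#' @export
fit_d18O_co3 <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("d18Oc_permil", "co3_umolkg", "crust_state")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("fit_d18O_co3(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  d <- data[is.finite(data$d18Oc_permil) & is.finite(data$co3_umolkg), need]
  if (length(unique(d$co3_umolkg)) < 2) {
    abort("fit_d18O_co3(): degenerate fit, insufficient spread in co3")
  }
  groups <- unique(d$crust_state)
  if (!all(groups %in% c("ontogenetic", "crusted"))) {
    abort("fit_d18O_co3(): crust_state must be 'ontogenetic' or 'crusted'")
  }
  if (length(groups) == 1) {
    fit <- lm(d18Oc_permil ~ co3_umolkg, data = d)
    ic <- unname(coef(fit)[1])
    sl <- unname(coef(fit)[2])
    sse <- suppressWarnings(2 * sqrt(diag(vcov(fit)))[2])
    if (groups == "ontogenetic") {
      return(oxy_carb_line(sl, intercept_ontogenetic = ic, n = nrow(d),
                           slope_se = unname(sse)))
    }
    return(oxy_carb_line(sl, intercept_crusted = ic, n = nrow(d),
                         slope_se = unname(sse)))
  }
  d$crust_state <- factor(d$crust_state, levels = c("ontogenetic", "crusted"))
  fit <- lm(d18Oc_permil ~ co3_umolkg + crust_state, data = d)
  cf <- coef(fit)
  oxy_carb_line(unname(cf["co3_umolkg"]),
                intercept_ontogenetic = unname(cf["(Intercept)"]),
                intercept_crusted = unname(cf["(Intercept)"] +
                                             cf["crust_statecrusted"]),
                n = nrow(d),
                slope_se = suppressWarnings(
                  unname(2 * sqrt(diag(vcov(fit)))["co3_umolkg"])))
}

#' Derive carbonate-ion concentration from calcite d18O
#'
#' [CO3] = (d18O_c - intercept) / slope with the intercept matching the crust
#' state of the material. Derived values outside (0, 350) umol/kg are flagged
#' in the `out_of_calibration` attribute and in a warning.
#'
#' @param d18Oc Calcite d18O, permil VPDB (vectorized). For downcore work this
#'   should already be ice-volume (sea-level) corrected.
#' @param line An [oxy_carb_line()].
#' @param crust_state `"crusted"` (default, fossil material) or
#'   `"ontogenetic"`.
#' @return Carbonate-ion concentration, umol/kg, with a logical attribute
#'   `out_of_calibration`.
#' @export
co3_from_d18O <- function(d18Oc, line, crust_state = "crusted") {
  stopifnot(inherits(line, "oxy_carb_line"))
  if (line$slope == 0) abort("co3_from_d18O(): zero slope")
  crust_state <- rep_len(crust_state, length(d18Oc))
  if (!all(crust_state %in% c("crusted", "ontogenetic"))) {
    abort("co3_from_d18O(): crust_state must be 'crusted' or 'ontogenetic' to select an intercept")
  }
  intercept <- ifelse(crust_state == "crusted",
                      line$intercept_crusted, line$intercept_ontogenetic)
  if (any(!is.finite(intercept) & is.finite(d18Oc))) {
    abort("co3_from_d18O(): no fitted intercept for requested crust state")
  }
  co3 <- (d18Oc - intercept) / line$slope
  flag <- is.finite(co3) & (co3 <= 0 | co3 >= 350)
  if (any(flag)) {
    warn(sprintf("co3_from_d18O(): %d derived value(s) outside (0, 350) umol/kg",
                 sum(flag)))
  }
  attr(co3, "out_of_calibration") <- flag
  co3
}

#' Replace core-top carbonate ion with d18O-derived values
#'
#' Crusted (core-top / fossil) samples rarely have reliable paired
#' water-column carbonate chemistry; the oxygen-isotope proxy line converts
#' their measured calcite d18O into a carbonate-ion estimate with much
#' smaller scatter than a hydrographic climatology. Tow samples keep their
#' water-column values. A `co3_2s` column records the per-sample 2-sigma
#' (analytical d18O noise mapped through the slope for derived values, the
#' prescribed hydrographic uncertainty otherwise) and `co3_source` records
#' the provenance.
#'
#' @param samples A sample tibble with `crust_state`, `d18Oc_permil` and
#'   `co3_umolkg`.
#' @param oxy_line A fitted [oxy_carb_line()].
#' @param d18O_2s Analytical 2-sigma on d18O, permil (default 0.2).
#' @param co3_2s Prescribed 2-sigma for water-column values (default 20).
#' @return The table with `co3_umolkg` replaced where derived, plus
#'   `co3_source` and `co3_2s` columns.
#' @export
derive_co3_for_crusted <- function(samples, oxy_line, d18O_2s = 0.2,
                                   co3_2s = 20) {
  stopifnot(is.data.frame(samples), inherits(oxy_line, "oxy_carb_line"))
  samples <- as_tibble(samples)
  use <- samples$crust_state == "crusted" & is.finite(samples$d18Oc_permil) &
    is.finite(oxy_line$intercept_crusted)
  samples$co3_source <- ifelse(use, "d18O", "watercolumn")
  samples$co3_2s <- ifelse(use, d18O_2s / abs(oxy_line$slope), co3_2s)
  if (any(use)) {
    derived <- suppressWarnings(
      co3_from_d18O(samples$d18Oc_permil[use], oxy_line, "crusted"))
    samples$co3_umolkg[use] <- as.numeric(derived)
  }
  samples
}

#' Assemble a full calibration model
#'
#' Bundles the fitted pieces the downcore pipeline needs: the corrected
#' Mg/Ca-temperature law, the carbonate-ion sensitivity, the d18O proxy
#' line(s), and the temperature-only prediction law used for normalisation.
#'
#' @param exp_law Corrected calibration ([mgca_exp_law()]).
#' @param power_law Carbonate-ion sensitivity ([mgca_power_law()]).
#' @param oxy_line d18O proxy line ([oxy_carb_line()]), optional until
#'   downcore use.
#' @param pred_law Temperature-only prediction law.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(exp_law, power_law, oxy_line = NULL,
                              pred_law = mgca_pred_law()) {
  stopifnot(inherits(exp_law, "exp_law"), inherits(power_law, "power_law"))
  if (!is.null(oxy_line)) stopifnot(inherits(oxy_line, "oxy_carb_line"))
  structure(list(exp_law = exp_law, power_law = power_law,
                 oxy_line = oxy_line, pred_law = pred_law),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model\n  corrected:  "); print(x$exp_law)
  cat("  sensitivity: "); print(x$power_law)
  if (!is.null(x$oxy_line)) { cat("  oxy proxy:   "); print(x$oxy_line) }
  invisible(x)
}

#' Fit the full calibration chain on a sample table
#'
#' Runs normalisation against the temperature-only law, the power-law
#' carbonate-ion sensitivity fit, the Mg/Ca correction, the corrected
#' exponential temperature calibration, and (when calcite d18O is present)
#' the d18O - carbonate ion proxy lines. Input Mg/Ca values are expected to
#' be already standardised for crust and cleaning offsets (see
#' [standardize_samples()]).
#'
#' @param samples A sample tibble with columns `mgca_mmolmol`, `temp_C`,
#'   `co3_umolkg`, and optionally `d18Oc_permil` + `crust_state`. As-measured
#'   tables are standardised internally (crust and cleaning adjustments on
#'   Mg/Ca, each applied once); tables already carrying the
#'   [standardize_samples()] bookkeeping columns are used as-is. The d18O
#'   proxy lines are always fitted on the as-measured d18O with per-group
#'   intercepts.
#' @param pred_law Temperature-only prediction law used for normalisation.
#' @param cfg A [correction_config()] for the internal standardisation.
#' @param use_d18O_co3 Derive crusted samples' carbonate ion from their d18O
#'   through the freshly fitted proxy line before the sensitivity fit
#'   (default TRUE, matching how core tops enter the combined calibration);
#'   tows always keep water-column values.
#' @param anchor_co3 Level anchor for the sensitivity fit (default
#'   [co3_no_effect()]); NULL for a free fit.
#' @return A [calibration_model()].
#' @export
fit_calibration <- function(samples, pred_law = mgca_pred_law(),
                            cfg = correction_config(),
                            use_d18O_co3 = TRUE,
                            anchor_co3 = co3_no_effect()) {
  stopifnot(is.data.frame(samples))
  need <- c("mgca_mmolmol", "temp_C", "co3_umolkg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("fit_calibration(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  oxy_data <- samples
  if (!"corr_crust" %in% names(samples)) {
    samples <- standardize_samples(samples, cfg, adjust_d18O = FALSE)
  }
  oline <- NULL
  if (all(c("d18Oc_permil", "crust_state") %in% names(oxy_data)) &&
      any(is.finite(oxy_data$d18Oc_permil))) {
    oline <- fit_d18O_co3(oxy_data[is.finite(oxy_data$d18Oc_permil), ])
  }
  if (use_d18O_co3 && !is.null(oline)) {
    # core tops: replace climatological carbonate ion with the d18O proxy
    samples <- derive_co3_for_crusted(samples, oline)
  }
  s <- dplyr::filter(samples, is.finite(.data$mgca_mmolmol),
                     is.finite(.data$temp_C), is.finite(.data$co3_umolkg),
                     .data$co3_umolkg > 0)
  s$mgca_norm <- normalize_mgca(s$mgca_mmolmol, s$temp_C, pred_law)
  plaw <- fit_co3_sensitivity(s, anchor_co3 = anchor_co3)
  s$mgca_corr <- correct_mgca(s$mgca_mmolmol, s$co3_umolkg, plaw)
  elaw <- fit_temp_calibration(s)
  calibration_model(elaw, plaw, oline, pred_law)
}
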