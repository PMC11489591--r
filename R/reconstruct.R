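#' Reconstruct sea-surface temperatures from a downcore record
#'
#' The end-to-end downcore pipeline for paired Mg/Ca - d18O series. Per row:
#' compensate Mg/Ca for reductive cleaning; remove the ice-volume d18O_sw
#' signal with the sea-level curve; derive carbonate ion from the corrected
#' d18O through the oxygen-isotope proxy line (crusted intercept by default -
#' fossil N. pachyderma is crusted); divide the Mg/Ca by the carbonate-ion
#' sensitivity; invert the corrected exponential calibration to temperature.
#' Rows whose derived carbonate ion falls outside the (0, 350) umol/kg
#' calibration window are flagged, computed anyway, and counted in a warning.
#' When an ensemble is supplied, per-row 95% intervals come from
#' [temperature_with_uncertainty()]; otherwise interval columns are NA.
#'
#' @param record A tibble with `age_ka`, `mgca_mmolmol`, `d18Oc_permil` and
#'   optionally `core_id`, `cleaning`, `crust_state`.
#' @param model A [calibration_model()] whose `oxy_line` carries an intercept
#'   for the record's crust state.
#' @param curve Optional sea-level curve (`age_ka`, `rsl_m`); omit for
#'   records where no ice-volume correction is wanted (all-Holocene data).
#' @param cfg A [correction_config()].
#' @param ensemble Optional [mc_calibration_ensemble()] for intervals.
#' @param spec Optional [uncertainty_spec()] overriding the ensemble's.
#' @param smooth_window Window for the three-point running average column
#'   (odd; default 3).
#' @return A tibble: all input columns plus `d18Oc_corr_permil`,
#'   `co3_umolkg`, `out_of_calibration`, `mgca_adj_mmolmol`, `mgca_corr`,
#'   `sst_C`, `sst_lo95`, `sst_hi95`, `sst_smooth3`.
#' @export
reconstruct_sst <- function(record, model, curve = NULL,
                            cfg = correction_config(), ensemble = NULL,
                            spec = NULL, smooth_window = 3) {
  stopifnot(is.data.frame(record), inherits(model, "calibration_model"))
  need <- c("age_ka", "mgca_mmolmol", "d18Oc_permil")
  miss <- setdiff(need, names(record))
  if (length(miss)) {
    abort(paste0("reconstruct_sst(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (is.null(model$oxy_line)) {
    abort(paste0("reconstruct_sst(): calibration model has no d18O proxy ",
                 "line; an intercept is required to derive carbonate ion"))
  }
  record <- as_tibble(record)
  if (nrow(record) == 0) {
    return(dplyr::mutate(record, d18Oc_corr_permil = numeric(),
                         co3_umolkg = numeric(), out_of_calibration = logical(),
                         mgca_adj_mmolmol = numeric(), mgca_corr = numeric(),
                         sst_C = numeric(), sst_lo95 = numeric(),
                         sst_hi95 = numeric(), sst_smooth3 = numeric()))
  }
  if (!"cleaning" %in% names(record)) record$cleaning <- "oxidative"
  if (!"crust_state" %in% names(record)) record$crust_state <- "crusted"

  record$mgca_adj_mmolmol <-
    cleaning_adjust_mgca(record$mgca_mmolmol, record$cleaning, cfg)
  record$d18Oc_corr_permil <- if (is.null(curve)) {
    record$d18Oc_permil
  } else {
    sealevel_correct_d18O(record$d18Oc_permil, record$age_ka, curve, cfg)
  }
  co3 <- suppressWarnings(
    co3_from_d18O(record$d18Oc_corr_permil, model$oxy_line,
                  record$crust_state))
  record$out_of_calibration <- attr(co3, "out_of_calibration")
  record$co3_umolkg <- as.numeric(co3)
  if (any(record$out_of_calibration, na.rm = TRUE)) {
    warn(sprintf(
      "reconstruct_sst(): %d row(s) with derived carbonate ion outside (0, 350) umol/kg; computed anyway",
      sum(record$out_of_calibration, na.rm = TRUE)))
  }
  usable <- record$co3_umolkg > 0 & is.finite(record$co3_umolkg) &
    is.finite(record$mgca_adj_mmolmol) & record$mgca_adj_mmolmol > 0
  record$mgca_corr <- NA_real_
  record$mgca_corr[usable] <- suppressWarnings(
    correct_mgca(record$mgca_adj_mmolmol[usable], record$co3_umolkg[usable],
                 model$power_law))
  record$sst_C <- NA_real_
  record$sst_C[usable] <-
    invert_temperature(record$mgca_corr[usable], model$exp_law)

  record$sst_lo95 <- NA_real_
  record$sst_hi95 <- NA_real_
  if (!is.null(ensemble)) {
    tw <- temperature_with_uncertainty(
      record$mgca_adj_mmolmol[usable], record$d18Oc_corr_permil[usable],
      ensemble, model$oxy_line, spec = spec,
      crust_state = record$crust_state[usable])
    record$sst_lo95[usable] <- pmin(tw$sst_lo95, record$sst_C[usable])
    record$sst_hi95[usable] <- pmax(tw$sst_hi95, record$sst_C[usable])
  }
  record$sst_smooth3 <- running_mean(record$sst_C, smooth_window)
  class(record) <- c("sst_series", class(record))
  record
}

#' Centered running mean with shrinking endpoints
#'
#' The smoother used for downcore SST display: a centered moving average of
#' odd window length whose endpoints average whatever neighbours exist
#' (shrinking window), so the series keeps its full length. NAs are dropped
#' within each window.
#'
#' @param x Numeric vector.
#' @param window Odd window length (default 3).
#' @return Numeric vector of the same length.
#' @examples
#' running_mean(c(0, 3, 0, 3, 0)) # 1.5 1 2 1 1.5
#' @export
running_mean <- function(x, window = 3) {
  if (window %% 2 != 1 || window < 1) {
    abort("running_mean(): window must be odd and >= 1")
  }
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Summary statistics over named age windows
#'
#' Per-window SST means with Monte Carlo 2-sigma (window means combine
#' per-sample spreads in quadrature), and all pairwise window differences
#' (e.g. interglacial minus glacial Delta-SST) with quadrature-combined
#' uncertainties.
#'
#' @param series A [reconstruct_sst()] output tibble (needs `age_ka`,
#'   `sst_C`, optionally `sst_lo95`/`sst_hi95`).
#' @param windows A named list of `c(age_min, age_max)` vectors in ka, e.g.
#'   `list(holocene = c(0, 12), lgm = c(18, 24))`.
#' @return A list of two tibbles: `$windows` (window, n, sst_mean, sst_2s)
#'   and `$pairs` (window_a, window_b, delta_sst = mean_a - mean_b,
#'   delta_2s).
#' @export
interval_stats <- function(series, windows) {
  stopifnot(is.data.frame(series), is.list(windows))
  if (is.null(names(windows)) || any(names(windows) == "")) {
    abort("interval_stats(): windows must be a named list")
  }
  per <- purrr::imap_dfr(windows, function(w, nm) {
    rows <- series[series$age_ka >= w[1] & series$age_ka <= w[2] &
                     is.finite(series$sst_C), ]
    if (nrow(rows) == 0) {
      abort(sprintf("interval_stats(): window '%s' [%g, %g] ka contains no samples",
                    nm, w[1], w[2]))
    }
    sig <- if (all(c("sst_lo95", "sst_hi95") %in% names(rows)) &&
               all(is.finite(rows$sst_hi95))) {
      (rows$sst_hi95 - rows$sst_lo95) / 4 # per-sample 1-sigma
    } else {
      rep(NA_real_, nrow(rows))
    }
    tibble(window = nm, n = nrow(rows), sst_mean = mean(rows$sst_C),
           sst_2s = if (all(is.finite(sig)))
             2 * sqrt(sum(sig^2)) / nrow(rows) else NA_real_)
  })
  prs <- NULL
  if (nrow(per) >= 2) {
    cmb <- utils::combn(per$window, 2)
    prs <- purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
      a <- per[per$window == cmb[1, j], ]
      b <- per[per$window == cmb[2, j], ]
      tibble(window_a = a$window, window_b = b$window,
             delta_sst = a$sst_mean - b$sst_mean,
             delta_2s = sqrt(a$sst_2s^2 + b$sst_2s^2))
    })
  }
  list(windows = per, pairs = prs)
}
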