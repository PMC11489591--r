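#' Monte Carlo uncertainty specification
#'
#' The 2-sigma input uncertainties propagated through the calibration and
#' temperature reconstruction:
#'
#' * `d18O_2s` (default 0.2 permil): analytical uncertainty on calcite d18O.
#' * `co3_2s` (default 20 umol/kg): conservative prescribed uncertainty on
#'   hydrographic carbonate-ion concentrations.
#' * `mgca_corr_2s` (default 0.2 mmol/mol): uncertainty carried by corrected
#'   Mg/Ca, treated as absolute on the corrected value (set
#'   `mgca_relative = TRUE` for a relative-fraction reading).
#' * `temp_2s` (default 2.8 degrees C): calcification-temperature uncertainty
#'   from depth assignment; 1.6 is the documented fallback where per-sample
#'   estimates are unavailable.
#' * `n_draws` (default 1000) and `seed` control the ensemble.
#'
#' @param d18O_2s,co3_2s,mgca_corr_2s,temp_2s Non-negative 2-sigma values.
#' @param n_draws Number of Monte Carlo draws (>= 100).
#' @param seed Optional integer seed.
#' @param distribution `"gaussian"` (default) or `"uniform"` perturbations;
#'   uniform draws cover the full +/- 2-sigma range.
#' @param mgca_relative Interpret `mgca_corr_2s` as a relative fraction.
#' @return An object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(d18O_2s = 0.2, co3_2s = 20, mgca_corr_2s = 0.2,
                             temp_2s = 2.8, n_draws = 1000, seed = NULL,
                             distribution = c("gaussian", "uniform"),
                             mgca_relative = FALSE) {
  distribution <- match.arg(distribution)
  if (any(c(d18O_2s, co3_2s, mgca_corr_2s, temp_2s) < 0)) {
    abort("uncertainty_spec(): all 2-sigma values must be >= 0")
  }
  if (n_draws < 100) abort("uncertainty_spec(): n_draws must be >= 100")
  structure(list(d18O_2s = d18O_2s, co3_2s = co3_2s,
                 mgca_corr_2s = mgca_corr_2s, temp_2s = temp_2s,
                 n_draws = as.integer(n_draws), seed = seed,
                 distribution = distribution, mgca_relative = mgca_relative),
            class = "uncertainty_spec")
}

# n perturbations with the stated 2-sigma under the configured distribution
draw_noise <- function(n, two_sigma, distribution) {
  if (two_sigma == 0) return(rep(0, n))
  if (distribution == "uniform") runif(n, -two_sigma, two_sigma)
  else rnorm(n, 0, two_sigma / 2)
}

# Redraw entries of x failing `ok` by re-applying `regen` to base values.
redraw_until <- function(x, base, ok, regen, max_tries = 100) {
  tries <- 0L; redrawn <- 0L
  bad <- !ok(x)
  while (any(bad) && tries < max_tries) {
    x[bad] <- regen(base[bad])
    redrawn <- redrawn + sum(bad)
    bad <- !ok(x)
    tries <- tries + 1L
  }
  if (any(bad)) abort("truncated resampling failed to produce valid draws")
  attr(x, "n_redrawn") <- redrawn
  x
}

#' Empirical interval summary of Monte Carlo draws
#'
#' Median with 68% (16-84) and 95% (2.5-97.5) empirical percentile intervals.
#' When a residual standard deviation is supplied, a 95% prediction interval
#' is added by combining the residual scatter with the draw spread in
#' quadrature about the median - the uncertainty applicable to one new
#' observation rather than to the fitted relationship.
#'
#' @param draws Numeric vector of at least 100 Monte Carlo draws.
#' @param resid_sd Optional residual standard deviation (1-sigma) for the
#'   prediction interval.
#' @return A one-row tibble: `median`, `ci68_lo`, `ci68_hi`, `ci95_lo`,
#'   `ci95_hi`, and `prediction95_lo`/`prediction95_hi` when `resid_sd` is
#'   given.
#' @export
interval_summary <- function(draws, resid_sd = NULL) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) {
    abort("interval_summary(): need at least 100 finite draws")
  }
  q <- quantile(draws, c(0.16, 0.84, 0.025, 0.975), names = FALSE)
  out <- tibble(median = median(draws),
                ci68_lo = q[1], ci68_hi = q[2],
                ci95_lo = q[3], ci95_hi = q[4])
  if (!is.null(resid_sd)) {
    hw <- (out$ci95_hi - out$ci95_lo) / 2
    phw <- sqrt(hw^2 + (qnorm(0.975) * resid_sd)^2)
    out$prediction95_lo <- out$median - phw
    out$prediction95_hi <- out$median + phw
  }
  out
}

#' Monte Carlo ensemble of calibration coefficients
#'
#' Two-stage ensemble mirroring how the correction scheme propagates its
#' uncertainties. A sensitivity stage refits the power law on `n_draws`
#' perturbed copies of (normalised Mg/Ca, carbonate ion), each draw jittering
#' carbonate ion within its prescribed 2-sigma and temperature within the
#' per-sample 2-sigma; its spread describes the sensitivity coefficients
#' (p, q). A calibration stage perturbs the centrally corrected Mg/Ca within
#' `mgca_corr_2s` - the corrected value's total uncertainty, which already
#' subsumes the carbonate-ion propagation - together with the per-sample
#' temperature uncertainties, and refits the exponential law; its spread
#' describes (a, b). Coefficients within each law are re-fitted jointly per
#' draw, so their error covariance is carried empirically by the ensemble
#' rather than assumed. The median of the draws is the central calibration
#' estimate; 2-sigma is read off the 2.5-97.5 percentile range.
#'
#' Draws whose fits fail are recorded and excluded; more than 5% failures
#' aborts with diagnostics.
#'
#' @param samples Standardised calibration table with `mgca_mmolmol`,
#'   `temp_C`, `co3_umolkg`; optional `temp_2s` and `co3_2s` columns supply
#'   per-sample uncertainties (CTD-paired tows vs depth-estimated core tops;
#'   d18O-derived vs climatological carbonate ion), falling back to the
#'   spec's scalars where absent.
#' @param spec An [uncertainty_spec()].
#' @param pred_law Temperature-only prediction law for normalisation.
#' @param anchor_co3 Level anchor for the sensitivity fits (default
#'   [co3_no_effect()]); NULL for free fits.
#' @return An object of class `mc_ensemble`: `$draws` (tibble of draw, p, q,
#'   a, b), `$point` (unperturbed [calibration_model()] pieces), `$summary`
#'   (per-coefficient [interval_summary()]), `$n_failed`, `$spec`.
#' @export
mc_calibration_ensemble <- function(samples, spec = uncertainty_spec(),
                                    pred_law = mgca_pred_law(),
                                    anchor_co3 = co3_no_effect()) {
  stopifnot(is.data.frame(samples), inherits(spec, "uncertainty_spec"))
  need <- c("mgca_mmolmol", "temp_C", "co3_umolkg")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("mc_calibration_ensemble(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  s <- dplyr::filter(samples, is.finite(.data$mgca_mmolmol),
                     is.finite(.data$temp_C), is.finite(.data$co3_umolkg))
  n <- nrow(s)
  t2s <- if ("temp_2s" %in% names(s)) s$temp_2s else rep(spec$temp_2s, n)
  c2s <- if ("co3_2s" %in% names(s)) s$co3_2s else rep(spec$co3_2s, n)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  # central chain: the point estimates all draws perturb around
  norm_c <- s$mgca_mmolmol / predict_mgca(s$temp_C, pred_law)
  plaw_c <- suppressWarnings(
    fit_co3_sensitivity(tibble(mgca_norm = norm_c,
                               co3_umolkg = s$co3_umolkg),
                        anchor_co3 = anchor_co3))
  corr_c <- s$mgca_mmolmol / (plaw_c$p * s$co3_umolkg^plaw_c$q)
  mg2s <- if (spec$mgca_relative) spec$mgca_corr_2s * corr_c
          else rep(spec$mgca_corr_2s, n)

  one_draw <- function() {
    # sensitivity stage: jitter carbonate ion and temperature, refit power law
    co3_j <- s$co3_umolkg + draw_noise(n, 1, spec$distribution) * c2s
    co3_j <- redraw_until(co3_j, s$co3_umolkg, function(x) x > 0,
                          function(b) b + draw_noise(length(b), 1,
                                                     spec$distribution) *
                            mean(c2s))
    t_j <- s$temp_C + draw_noise(n, 1, spec$distribution) * t2s
    plaw <- fit_co3_sensitivity(
      tibble(mgca_norm = s$mgca_mmolmol / predict_mgca(t_j, pred_law),
             co3_umolkg = co3_j),
      anchor_co3 = anchor_co3)
    # calibration stage: jitter the propagated corrected Mg/Ca and
    # temperature, refit the exponential law
    corr <- corr_c + draw_noise(n, 1, spec$distribution) * mg2s
    corr <- redraw_until(corr, corr_c, function(x) x > 0,
                         function(b) b + draw_noise(length(b), 1,
                                                    spec$distribution) *
                           mean(mg2s))
    t_j2 <- s$temp_C + draw_noise(n, 1, spec$distribution) * t2s
    # log-scale refit: even leverage across the temperature range,
    # reproducing the calibration's printed coefficient uncertainties
    elaw <- fit_temp_calibration(tibble(mgca_corr = corr, temp_C = t_j2),
                                 scale = "log")
    c(p = plaw$p, q = plaw$q, a = elaw$a, b = elaw$b)
  }

  draws <- vector("list", spec$n_draws)
  failed <- 0L
  for (i in seq_len(spec$n_draws)) {
    res <- tryCatch(suppressWarnings(one_draw()), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      draws[[i]] <- NULL
    } else {
      draws[[i]] <- res
    }
  }
  if (failed > 0.05 * spec$n_draws) {
    abort(sprintf(
      "mc_calibration_ensemble(): %d of %d draws failed to fit (> 5%%); check input noise scales",
      failed, spec$n_draws))
  }
  dmat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  draws_tbl <- as_tibble(dmat)
  draws_tbl$draw <- seq_len(nrow(draws_tbl))

  point <- suppressWarnings(
    fit_calibration(s, pred_law = pred_law, anchor_co3 = anchor_co3,
                    use_d18O_co3 = FALSE))
  summ <- purrr::map_dfr(c("p", "q", "a", "b"), function(cn) {
    dplyr::mutate(interval_summary(draws_tbl[[cn]]), coefficient = cn,
                  .before = 1)
  })
  structure(list(draws = draws_tbl[c("draw", "p", "q", "a", "b")],
                 point = point, summary = summ,
                 n_failed = failed, spec = spec),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("Monte Carlo calibration ensemble: %d draws (%d failed)\n",
              nrow(x$draws), x$n_failed))
  print(x$summary)
  invisible(x)
}

#' @method tidy mc_ensemble
#' @export
tidy.mc_ensemble <- function(x, ...) x$summary

#' @method glance mc_ensemble
#' @export
glance.mc_ensemble <- function(x, ...) {
  tibble(n_draws = nrow(x$draws), n_failed = x$n_failed)
}

#' Reconstructed temperature with Monte-Carlo-propagated uncertainty
#'
#' For each paired (Mg/Ca, d18O) observation, every ensemble draw perturbs
#' the calcite d18O within its analytical 2-sigma, converts it to carbonate
#' ion through the oxygen-isotope proxy line, corrects the measured Mg/Ca
#' with the central power law and inverts that draw's exponential calibration
#' to temperature. The reported 2-sigma is the half-width of the 2.5-97.5
#' percentile range. The default composition therefore combines the
#' calibration-coefficient uncertainty with the d18O-derived carbonate-ion
#' term; draw-wise power laws (`use_power_draws`) and an additional absolute
#' Mg/Ca perturbation (`include_mgca_noise`) are available but double-count
#' spread that the corrected-Mg/Ca uncertainty already carries into the
#' coefficient draws. Non-positive perturbed Mg/Ca or carbonate-ion draws
#' are redrawn (truncated sampling) and counted.
#'
#' @param mgca Measured (standardised) Mg/Ca, mmol/mol (vectorized).
#' @param d18Oc Ice-volume-corrected calcite d18O, permil VPDB (vectorized).
#' @param ensemble An [mc_calibration_ensemble()] result.
#' @param oxy_line An [oxy_carb_line()] with an intercept for `crust_state`.
#' @param spec An [uncertainty_spec()]; defaults to the ensemble's.
#' @param crust_state Intercept selector, default `"crusted"`.
#' @param include_mgca_noise Also perturb Mg/Ca by `mgca_corr_2s` (default
#'   FALSE: calibration + carbonate-ion terms only).
#' @param use_power_draws Correct with each draw's power law instead of the
#'   central one (default FALSE).
#' @return A tibble, one row per observation: `sst_C` (median), `sst_lo68`,
#'   `sst_hi68`, `sst_lo95`, `sst_hi95`, `sst_2s` (95% half-width),
#'   `co3_umolkg` (median derived carbonate ion), `n_redrawn`.
#' @export
temperature_with_uncertainty <- function(mgca, d18Oc, ensemble, oxy_line,
                                         spec = NULL,
                                         crust_state = "crusted",
                                         include_mgca_noise = FALSE,
                                         use_power_draws = FALSE) {
  stopifnot(inherits(ensemble, "mc_ensemble"),
            inherits(oxy_line, "oxy_carb_line"))
  if (is.null(spec)) spec <- ensemble$spec
  if (!is.null(spec$seed)) set.seed(spec$seed + 1L)
  nd <- nrow(ensemble$draws)
  crust_state <- rep_len(crust_state, length(mgca))

  purrr::map_dfr(seq_along(mgca), function(i) {
    if (!is.finite(mgca[i]) || !is.finite(d18Oc[i])) {
      return(tibble(sst_C = NA_real_, sst_lo68 = NA_real_, sst_hi68 = NA_real_,
                    sst_lo95 = NA_real_, sst_hi95 = NA_real_, sst_2s = NA_real_,
                    co3_umolkg = NA_real_, n_redrawn = 0L))
    }
    d18_j <- d18Oc[i] + draw_noise(nd, spec$d18O_2s, spec$distribution)
    co3_j <- suppressWarnings(
      as.numeric(co3_from_d18O(d18_j, oxy_line, crust_state[i])))
    co3_j <- redraw_until(
      co3_j, rep(d18Oc[i], nd), function(x) x > 0,
      function(b) suppressWarnings(as.numeric(co3_from_d18O(
        b + draw_noise(length(b), spec$d18O_2s, spec$distribution),
        oxy_line, crust_state[i]))))
    n_re <- attr(co3_j, "n_redrawn")
    sens_j <- if (use_power_draws) {
      ensemble$draws$p * co3_j^ensemble$draws$q
    } else {
      plaw_c <- ensemble$point$power_law
      plaw_c$p * co3_j^plaw_c$q
    }
    corr_j <- mgca[i] / sens_j
    if (include_mgca_noise) {
      mg2s <- if (spec$mgca_relative) spec$mgca_corr_2s * corr_j
              else rep(spec$mgca_corr_2s, nd)
      corr_pert <- corr_j + draw_noise(nd, 1, spec$distribution) * mg2s
      corr_pert <- redraw_until(corr_pert, corr_j, function(x) x > 0,
                                function(b) b + draw_noise(length(b), 1,
                                                           spec$distribution) *
                                  mean(mg2s))
      n_re <- n_re + attr(corr_pert, "n_redrawn")
      corr_j <- as.numeric(corr_pert)
    }
    t_j <- log(corr_j / ensemble$draws$a) / ensemble$draws$b
    q <- quantile(t_j, c(0.16, 0.84, 0.025, 0.975), names = FALSE)
    tibble(sst_C = median(t_j), sst_lo68 = q[1], sst_hi68 = q[2],
           sst_lo95 = q[3], sst_hi95 = q[4], sst_2s = (q[4] - q[3]) / 2,
           co3_umolkg = median(co3_j), n_redrawn = as.integer(n_re))
  })
}
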