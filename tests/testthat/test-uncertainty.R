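test_that("interval summaries report empirical percentiles and nest correctly", {
  expect_equal(interval_summary(rep(2, 200))$ci95_lo, 2)
  expect_equal(interval_summary(rep(2, 200))$ci95_hi, 2)

  set.seed(3)
  z <- rnorm(1e5)
  s <- interval_summary(z)
  expect_equal(s$ci95_lo, -1.96, tolerance = 0.02)
  expect_equal(s$ci95_hi, 1.96, tolerance = 0.02)
  expect_lte(s$ci95_lo, s$ci68_lo)
  expect_gte(s$ci95_hi, s$ci68_hi)
  expect_gte(s$median, s$ci68_lo)
  expect_lte(s$median, s$ci68_hi)
  # prediction interval strictly wider once residual scatter is added
  sp <- interval_summary(z, resid_sd = 0.5)
  expect_lt(sp$prediction95_lo, s$ci95_lo)
  expect_gt(sp$prediction95_hi, s$ci95_hi)
  expect_error(interval_summary(rnorm(50)), "at least 100")
})

test_that("zero input uncertainty collapses every draw onto the point fit", {
  cfg <- noiseless_config(seed = 8)
  std <- standardized_set(cfg)
  ens <- mc_calibration_ensemble(std, zero_noise_spec(seed = 1))
  expect_equal(ens$n_failed, 0L)
  expect_equal(unique(round(ens$draws$a, 12)), ens$point$exp_law$a,
               tolerance = 1e-9)
  expect_equal(unique(round(ens$draws$b, 12)), ens$point$exp_law$b,
               tolerance = 1e-9)
  expect_equal(max(ens$draws$q) - min(ens$draws$q), 0, tolerance = 1e-10)

  # degenerate noise propagates to a zero-width temperature interval at truth
  ts <- typical_sample(4, cfg)
  tw <- temperature_with_uncertainty(ts$mgca_mmolmol, ts$d18Oc_permil, ens,
                                     cfg$oxy_line, spec = zero_noise_spec(seed = 2))
  expect_equal(tw$sst_2s, 0, tolerance = 1e-9)
  expect_equal(tw$sst_C, 4, tolerance = 1e-6)
})

test_that("ensembles are bitwise reproducible under a fixed seed", {
  cfg <- default_config(seed = 21)
  std <- standardized_set(cfg)
  spec <- uncertainty_spec(n_draws = 150, seed = 99)
  e1 <- mc_calibration_ensemble(std, spec)
  e2 <- mc_calibration_ensemble(std, spec)
  expect_identical(e1$draws, e2$draws)
  t1 <- temperature_with_uncertainty(1.0, 3.0, e1, cfg$oxy_line, spec = spec)
  t2 <- temperature_with_uncertainty(1.0, 3.0, e2, cfg$oxy_line, spec = spec)
  expect_identical(t1, t2)
})

test_that("temperature interval width grows with each input 2-sigma", {
  cfg <- default_config(seed = 33)
  std <- standardized_set(cfg)
  ens <- mc_calibration_ensemble(std, uncertainty_spec(n_draws = 400, seed = 5))
  ts <- typical_sample(5, cfg)
  w <- function(spec) {
    temperature_with_uncertainty(ts$mgca_mmolmol, ts$d18Oc_permil, ens,
                                 cfg$oxy_line, spec = spec)$sst_2s
  }
  base <- w(uncertainty_spec(seed = 7))
  expect_gt(w(uncertainty_spec(d18O_2s = 0.4, seed = 7)), base)
  # Mg/Ca noise, once switched on, widens the interval further
  with_mg <- temperature_with_uncertainty(
    ts$mgca_mmolmol, ts$d18Oc_permil, ens, cfg$oxy_line,
    spec = uncertainty_spec(seed = 7), include_mgca_noise = TRUE)$sst_2s
  expect_gt(with_mg, base)
})

test_that("ensemble coefficient spreads track the prescribed uncertainty scale", {
  cfg <- default_config(seed = 13)
  std <- standardized_set(cfg)
  lo <- mc_calibration_ensemble(
    std, uncertainty_spec(mgca_corr_2s = 0.1, n_draws = 300, seed = 4))
  hi <- mc_calibration_ensemble(
    std, uncertainty_spec(mgca_corr_2s = 0.4, n_draws = 300, seed = 4))
  width <- function(e, cn) {
    s <- e$summary[e$summary$coefficient == cn, ]
    s$ci95_hi - s$ci95_lo
  }
  expect_gt(width(hi, "a"), width(lo, "a"))
  expect_gt(width(hi, "b"), width(lo, "b"))
})

test_that("95% temperature intervals cover the truth at close to nominal rate", {
  # fresh ensemble every 25 repetitions; generation and propagation share the
  # same noise composition (d18O + Mg/Ca terms)
  set.seed(606)
  n_rep <- 500
  hits <- logical(n_rep)
  fc <- default_config()
  spec <- uncertainty_spec(n_draws = 250)
  ens <- NULL
  for (i in seq_len(n_rep)) {
    if (i %% 25 == 1) {
      cal <- standardize_samples(
        simulate_calibration_set(forward_config(seed = 5000 + i)),
        adjust_d18O = FALSE)
      ens <- mc_calibration_ensemble(cal, spec)
    }
    t_true <- runif(1, -2, 15)
    truth <- typical_sample(t_true, fc)
    mg_obs <- (predict_mgca(t_true, fc$exp_law) + rnorm(1, 0, 0.1)) *
      co3_sensitivity(truth$co3_umolkg, fc$power_law)
    d18_obs <- truth$d18Oc_permil + rnorm(1, 0, 0.1)
    if (mg_obs <= 0) next
    tw <- temperature_with_uncertainty(mg_obs, d18_obs, ens, fc$oxy_line,
                                       spec = spec,
                                       include_mgca_noise = TRUE)
    hits[i] <- tw$sst_lo95 <= t_true && t_true <= tw$sst_hi95
  }
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("uncertainty spec validates and too many failed draws abort", {
  expect_error(uncertainty_spec(d18O_2s = -1), ">= 0")
  expect_error(uncertainty_spec(n_draws = 10), "n_draws")
  cfg <- default_config(seed = 3)
  std <- standardized_set(cfg)
  # three points cannot support a power-law refit when jittered degenerately
  tiny <- std[1:3, ]
  expect_error(
    mc_calibration_ensemble(tiny[, c("mgca_mmolmol", "temp_C")],
                            uncertainty_spec(n_draws = 100)),
    "missing columns")
})
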