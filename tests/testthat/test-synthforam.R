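test_that("noise-free samples lie exactly on the generating surfaces", {
  cfg <- noiseless_config(seed = 11)
  s <- simulate_calibration_set(cfg)
  crust_equiv <- ifelse(s$crust_state == "ontogenetic",
                        s$mgca_mmolmol * 0.85, s$mgca_mmolmol)
  expect_equal(crust_equiv,
               predict_mgca(s$temp_C, cfg$exp_law) *
                 co3_sensitivity(s$co3_umolkg, cfg$power_law),
               tolerance = 1e-12)
  intercept <- ifelse(s$crust_state == "ontogenetic", 4, 6)
  expect_equal(s$d18Oc_permil, intercept - 0.0279 * s$co3_umolkg,
               tolerance = 1e-12)
  expect_equal(s$temp_C, s$true_temp_C)
  expect_equal(s$co3_umolkg, s$true_co3_umolkg)
})

test_that("generation is deterministic per seed and respects configured ranges", {
  a <- simulate_calibration_set(forward_config(seed = 77))
  b <- simulate_calibration_set(forward_config(seed = 77))
  expect_identical(a, b)
  c <- simulate_calibration_set(forward_config(seed = 78))
  expect_false(identical(a$mgca_mmolmol, c$mgca_mmolmol))
  expect_true(all(a$temp_C >= -2 & a$temp_C <= 16))
  expect_true(all(a$co3_umolkg >= 50 & a$co3_umolkg <= 220))
  expect_equal(nrow(a), 235)
  expect_equal(mean(a$crust_state == "ontogenetic"), 0.5, tolerance = 0.01)
  # tow temperatures carry the CTD uncertainty; core tops cycle through the
  # three published population uncertainties
  expect_equal(unique(a$temp_2s[a$source == "tow"]), 0.2)
  expect_equal(sort(unique(a$temp_2s[a$source == "coretop"])),
               c(0.8, 1.6, 2.8), tolerance = 1e-12)
})

test_that("full-chain fit on a default-noise set recovers the exponent in its CI", {
  std <- standardized_set(default_config(seed = 204))
  model <- suppressWarnings(fit_calibration(std))
  expect_lt(abs(model$power_law$q - TRUE_Q), model$power_law$q_se)
  expect_lt(abs(model$oxy_line$slope - TRUE_OXY_SLOPE),
            2 * abs(model$oxy_line$slope_se))
})

test_that("doubling the noise widens coefficient CIs without biasing recovery", {
  fits <- lapply(c(1, 2), function(k) {
    spec <- uncertainty_spec(d18O_2s = 0.2 * k, co3_2s = 20 * k,
                             mgca_corr_2s = 0.2 * k, temp_2s = 2.8 * k)
    std <- standardized_set(forward_config(noise = spec, seed = 42))
    suppressWarnings(fit_calibration(std))
  })
  expect_gt(fits[[2]]$exp_law$a_se, fits[[1]]$exp_law$a_se)
  expect_gt(fits[[2]]$exp_law$b_se, fits[[1]]$exp_law$b_se)
  expect_gt(fits[[2]]$power_law$q_se, fits[[1]]$power_law$q_se)
  # doubled noise still covers the truth within its (wider) intervals
  expect_lt(abs(fits[[2]]$exp_law$b - TRUE_B), fits[[2]]$exp_law$b_se)
})

test_that("synthetic profiles support depth round trips and ambiguity cases", {
  sim <- simulate_profile(noiseless_config(seed = 2), planted_depth = 50)
  est <- infer_calcification_depth(sim$truth$d18Oc_permil, sim$equilibrium,
                                   sim$profile)
  expect_true(est$matched)
  expect_equal(est$depth_m, 50, tolerance = 1e-6)
  expect_true(all(diff(sim$profile$depth_m) > 0))
  expect_true(all(is.finite(sim$profile$co3_umolkg)))

  bumpy <- simulate_profile(noiseless_config(seed = 3), non_monotone = TRUE,
                            planted_depth = 120)
  est2 <- infer_calcification_depth(bumpy$truth$d18Oc_permil,
                                    bumpy$equilibrium, bumpy$profile)
  expect_gt(est2$ambiguity_count, 1)

  flat <- simulate_profile(noiseless_config(seed = 4), surface_temp = 3,
                           deep_temp = 3)
  off <- infer_calcification_depth(
    max(flat$equilibrium$d18Oc_eq_permil) + 0.5, flat$equilibrium,
    flat$profile)
  expect_false(off$matched)
})

test_that("downcore forward model embeds and the pipeline removes ice volume", {
  hist <- data.frame(age_ka = c(1, 5, 10, 18, 22, 26),
                     sst_C = c(10, 10, 10, 2, 2, 2),
                     rsl_m = c(0, 0, 0, -120, -120, -120))
  sim <- simulate_downcore(noiseless_config(seed = 6), hist)
  expect_equal(nrow(sim$record), 6)
  # glacial rows are enriched by exactly rsl/10 * 0.11 over the proxy line
  line_d18 <- 6 - 0.0279 * surface_co3_at(hist$sst_C)
  expect_equal(sim$record$d18Oc_permil, line_d18 - hist$rsl_m / 10 * 0.11,
               tolerance = 1e-10)
  expect_error(simulate_downcore(noiseless_config(),
                                 data.frame(age_ka = numeric(),
                                            sst_C = numeric(),
                                            rsl_m = numeric())),
               "empty")
})
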