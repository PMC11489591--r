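test_that("temperature-only Mg/Ca prediction and normalisation evaluate the law", {
  expect_identical(predict_mgca(0), 0.4)
  expect_equal(predict_mgca(10), 0.4 * exp(0.9), tolerance = 1e-12)
  expect_equal(predict_mgca(10), 0.9838, tolerance = 1e-4)
  expect_equal(predict_mgca(-2), 0.3341, tolerance = 1e-4)
  expect_equal(normalize_mgca(0.8, 0), 2)
  expect_equal(normalize_mgca(0.4, 0), 1)
  expect_equal(normalize_mgca(predict_mgca(10), 10), 1, tolerance = 1e-12)
  expect_error(normalize_mgca(-0.1, 5), "positive")
  expect_error(mgca_exp_law(-1, 0.09), "a must be")
  expect_error(mgca_power_law(100, 1.5), "q must be")
})

test_that("carbonate-ion sensitivity evaluates and corrects as a power law", {
  law <- mgca_power_law(3227.95, -1.53)
  expect_equal(co3_sensitivity(200, law), 3227.95 * 200^-1.53, tolerance = 1e-12)
  expect_equal(co3_sensitivity(200, law), 0.97, tolerance = 0.01)
  expect_equal(co3_sensitivity(100, law), 2.81, tolerance = 0.01)
  expect_equal(co3_sensitivity(50, law), 8.1, tolerance = 0.1)
  expect_error(co3_sensitivity(-5, law), "positive")
  expect_warning(co3_sensitivity(260, law), "250")

  expect_equal(correct_mgca(0.8, 100, mgca_power_law(200, -1)), 0.4)
  # unit sensitivity leaves the measurement untouched
  s1 <- (1 / 3227.95)^(1 / -1.53)
  expect_equal(correct_mgca(1.234, s1, law), 1.234, tolerance = 1e-10)
  # forward-inverse consistency at T = 5, co3 = 120
  mg <- 0.372 * exp(0.0936 * 5) * co3_sensitivity(120, law)
  expect_equal(correct_mgca(mg, 120, law), 0.594, tolerance = 5e-4)
})

test_that("power-law and exponential fits recover noiseless generators exactly", {
  co3 <- seq(50, 220, length.out = 40)
  fit1 <- fit_co3_sensitivity(
    data.frame(mgca_norm = 3227.95 * co3^-1.53, co3_umolkg = co3))
  expect_equal(fit1$p, 3227.95, tolerance = 1e-6)
  expect_equal(fit1$q, -1.53, tolerance = 1e-8)
  expect_equal(fit1$r2, 1, tolerance = 1e-10)
  fit2 <- fit_co3_sensitivity(
    data.frame(mgca_norm = 100 * co3^-1, co3_umolkg = co3))
  expect_equal(fit2$p, 100, tolerance = 1e-6)
  expect_equal(fit2$q, -1, tolerance = 1e-8)

  tt <- seq(-2, 16, length.out = 40)
  fit3 <- fit_temp_calibration(
    data.frame(mgca_corr = 0.372 * exp(0.0936 * tt), temp_C = tt))
  expect_equal(fit3$a, 0.372, tolerance = 1e-9)
  expect_equal(fit3$b, 0.0936, tolerance = 1e-9)
  fit4 <- fit_temp_calibration(
    data.frame(mgca_corr = 0.4 * exp(0.09 * tt), temp_C = tt))
  expect_equal(fit4$a, 0.4, tolerance = 1e-9)
  expect_equal(fit4$b, 0.09, tolerance = 1e-9)

  expect_error(fit_co3_sensitivity(
    data.frame(mgca_norm = c(1, 2, 3), co3_umolkg = c(100, 100, 100))),
    "degenerate")
  expect_error(fit_temp_calibration(
    data.frame(mgca_corr = c(1, 1.1, 1.2), temp_C = c(5, 5.5, 6))),
    "degenerate")
})

test_that("noisy synthetic fits recover generator coefficients within 95% CIs", {
  cfg <- default_config(seed = 104)
  std <- standardized_set(cfg)
  std$mgca_norm <- normalize_mgca(std$mgca_mmolmol, std$temp_C)
  plaw <- fit_co3_sensitivity(std)
  expect_lt(abs(plaw$q - TRUE_Q), plaw$q_se)
  std$mgca_corr <- suppressWarnings(
    correct_mgca(std$mgca_mmolmol, std$co3_umolkg, plaw))
  elaw <- fit_temp_calibration(std)
  expect_lt(abs(elaw$a - TRUE_A), elaw$a_se)
  expect_lt(abs(elaw$b - TRUE_B), elaw$b_se)
})

test_that("temperature inversion is the exact inverse of the exponential law", {
  law <- mgca_exp_law(0.372, 0.0936)
  expect_equal(invert_temperature(0.372, law), 0)
  expect_equal(invert_temperature(0.594, law), 5, tolerance = 1e-3)
  expect_equal(invert_temperature(predict_mgca(7.3, law), law), 7.3,
               tolerance = 1e-10)
  expect_error(invert_temperature(-1, law), "positive")
})

test_that("shared-slope d18O-co3 fit recovers groups, single groups, noisy slopes", {
  co3 <- rep(seq(60, 200, length.out = 20), 2)
  grp <- rep(c("ontogenetic", "crusted"), each = 20)
  d18 <- ifelse(grp == "crusted", 6, 4) - 0.0279 * co3
  fit <- fit_d18O_co3(data.frame(d18Oc_permil = d18, co3_umolkg = co3,
                                 crust_state = grp))
  expect_equal(fit$slope, -0.0279, tolerance = 1e-10)
  expect_equal(fit$intercept_ontogenetic, 4, tolerance = 1e-9)
  expect_equal(fit$intercept_crusted, 6, tolerance = 1e-9)

  single <- fit_d18O_co3(data.frame(
    d18Oc_permil = 4 - 0.0279 * co3[1:20], co3_umolkg = co3[1:20],
    crust_state = "ontogenetic"))
  expect_equal(single$slope, -0.0279, tolerance = 1e-10)
  expect_true(is.na(single$intercept_crusted))

  set.seed(9)
  noisy <- fit_d18O_co3(data.frame(
    d18Oc_permil = d18 + rnorm(40, 0, 0.1), co3_umolkg = co3,
    crust_state = grp))
  expect_lt(abs(noisy$slope - (-0.0279)), noisy$slope_se)

  expect_error(fit_d18O_co3(data.frame(
    d18Oc_permil = c(1, 2), co3_umolkg = c(100, 100),
    crust_state = "crusted")), "spread")
})

test_that("d18O-derived carbonate ion inverts the proxy line and flags range", {
  line <- oxy_carb_line(-0.0279, intercept_ontogenetic = 2,
                        intercept_crusted = 4)
  expect_warning(co3 <- co3_from_d18O(4, line, "crusted"), "outside")
  expect_equal(as.numeric(co3), 0)
  expect_true(attr(co3, "out_of_calibration"))
  expect_equal(as.numeric(co3_from_d18O(1, line, "crusted")), 3 / 0.0279,
               tolerance = 1e-10)
  expect_equal(as.numeric(co3_from_d18O(1, line, "crusted")), 107.5,
               tolerance = 0.05)
  # one slope-unit drop in d18O raises derived co3 by exactly one
  base <- as.numeric(co3_from_d18O(1, line, "crusted"))
  expect_equal(as.numeric(co3_from_d18O(1 - 0.0279, line, "crusted")),
               base + 1, tolerance = 1e-9)
  expect_error(co3_from_d18O(1, line, "unknown"), "intercept")
})

test_that("full chain on noiseless forward data recovers all generators to machine precision", {
  cfg <- noiseless_config(seed = 5)
  std <- standardized_set(cfg)
  model <- fit_calibration(std)
  expect_equal(model$power_law$p, TRUE_P, tolerance = 1e-6)
  expect_equal(model$power_law$q, TRUE_Q, tolerance = 1e-8)
  expect_equal(model$exp_law$a, cfg$exp_law$a, tolerance = 1e-8)
  expect_equal(model$exp_law$b, cfg$exp_law$b, tolerance = 1e-8)
  expect_equal(model$oxy_line$slope, TRUE_OXY_SLOPE, tolerance = 1e-10)
  expect_equal(model$oxy_line$intercept_crusted -
                 model$oxy_line$intercept_ontogenetic, 2, tolerance = 1e-9)
})

test_that("calibration laws are monotone over their working ranges", {
  law <- mgca_exp_law(0.372, 0.0936)
  plaw <- mgca_power_law(3227.95, -1.53)
  tt <- seq(-2, 16, by = 0.25)
  expect_true(all(diff(predict_mgca(tt, law)) > 0))
  co3 <- seq(50, 240, by = 2)
  expect_true(all(diff(suppressWarnings(co3_sensitivity(co3, plaw))) < 0))
  # correction undoes a forward overprint for every (T, co3) combination
  grid <- expand.grid(T = seq(-2, 16, by = 3), co3 = seq(50, 220, by = 30))
  fwd <- predict_mgca(grid$T, law) * co3_sensitivity(grid$co3, plaw)
  expect_equal(correct_mgca(fwd, grid$co3, plaw), predict_mgca(grid$T, law),
               tolerance = 1e-12)
})

test_that("nonlinear-fit 95% CIs cover generating values at the nominal rate", {
  # response-noise-only experiment isolates the fitting machinery
  set.seed(2024)
  tt <- seq(-2, 16, length.out = 80)
  truth <- 0.372 * exp(0.0936 * tt)
  hits <- vapply(seq_len(500), function(i) {
    fit <- fit_temp_calibration(
      data.frame(mgca_corr = truth + rnorm(80, 0, 0.1), temp_C = tt))
    abs(fit$b - 0.0936) < fit$b_se # 2-sigma = 95% CI half-width
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("tidy and glance expose coefficients in broom shape", {
  law <- mgca_exp_law(0.372, 0.0936, a_se = 0.014, b_se = 0.0045,
                      n = 235L, r2 = 0.90)
  td <- tidy(law)
  expect_equal(td$term, c("a", "b"))
  expect_equal(td$estimate, c(0.372, 0.0936))
  expect_equal(glance(law)$r.squared, 0.90)
  expect_equal(tidy(mgca_power_law(3227.95, -1.53))$estimate[2], -1.53)
  line <- oxy_carb_line(-0.0279, 4, 6)
  expect_equal(tidy(line)$estimate[1], -0.0279)
})
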