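make_truth_model <- function(cfg) {
  calibration_model(cfg$exp_law, cfg$power_law, cfg$oxy_line)
}

glacial_history <- function() {
  data.frame(age_ka = c(1, 4, 7, 10, 16, 19, 22, 25),
             sst_C = c(12, 12, 12, 12, 2, 2, 2, 2),
             rsl_m = c(0, 0, 0, 0, -120, -120, -120, -120))
}

test_that("running mean shrinks at endpoints and preserves constants", {
  expect_equal(running_mean(c(1, 2, 3)), c(1.5, 2, 2.5))
  expect_equal(running_mean(rep(4, 6)), rep(4, 6))
  expect_equal(running_mean(c(0, 3, 0, 3, 0))[2:4], c(1, 2, 1))
  expect_equal(running_mean(c(0, 3, 0, 3, 0)), c(1.5, 1, 2, 1, 1.5))
  expect_equal(running_mean(c(1, NA, 3)), c(1, 2, 3))
  expect_error(running_mean(1:5, window = 4), "odd")
})

test_that("noiseless downcore records round-trip to the true SST history", {
  cfg <- noiseless_config(seed = 14)
  sim <- simulate_downcore(cfg, glacial_history())
  out <- reconstruct_sst(sim$record, make_truth_model(cfg), sim$curve)
  expect_equal(out$sst_C, glacial_history()$sst_C, tolerance = 1e-8)
  expect_equal(out$co3_umolkg, surface_co3_at(glacial_history()$sst_C),
               tolerance = 1e-8)
  # intermediate columns retained
  expect_true(all(c("d18Oc_corr_permil", "mgca_adj_mmolmol", "mgca_corr",
                    "sst_smooth3") %in% names(out)))
})

test_that("skipping the sea-level correction biases glacial rows by the predicted amount", {
  cfg <- noiseless_config(seed = 15)
  sim <- simulate_downcore(cfg, glacial_history())
  model <- make_truth_model(cfg)
  with_corr <- reconstruct_sst(sim$record, model, sim$curve)
  without <- reconstruct_sst(sim$record, model, curve = NULL)
  glac <- glacial_history()$rsl_m < 0
  # ablation oracle, composed independently of the pipeline: uncorrected d18O
  # is heavier by 1.32 permil, so derived co3 is lower by 1.32/0.0279, the
  # sensitivity higher, and the inferred temperature colder
  d_co3 <- 1.32 / 0.0279
  co3_true <- surface_co3_at(2)
  dT <- (-1.53) * (log(co3_true - d_co3) - log(co3_true)) / cfg$exp_law$b
  expect_equal(without$sst_C[glac], with_corr$sst_C[glac] - dT,
               tolerance = 1e-6)
  expect_equal(without$sst_C[!glac], with_corr$sst_C[!glac], tolerance = 1e-9)
})

test_that("empty records return empty series without error", {
  cfg <- noiseless_config()
  empty <- tibble::tibble(core_id = character(), age_ka = numeric(),
                          mgca_mmolmol = numeric(), d18Oc_permil = numeric(),
                          cleaning = character(), crust_state = character())
  out <- reconstruct_sst(empty, make_truth_model(cfg))
  expect_equal(nrow(out), 0)
  expect_true("sst_C" %in% names(out))
})

test_that("reconstruction demands a d18O proxy line and flags out-of-range co3", {
  cfg <- noiseless_config(seed = 16)
  sim <- simulate_downcore(cfg, glacial_history())
  no_line <- calibration_model(cfg$exp_law, cfg$power_law, oxy_line = NULL)
  expect_error(reconstruct_sst(sim$record, no_line, sim$curve), "proxy")

  rec <- sim$record
  rec$d18Oc_permil[1] <- 7.5 # heavier than the crusted intercept: co3 <= 0
  expect_warning(out <- reconstruct_sst(rec, make_truth_model(cfg), sim$curve),
                 "outside")
  expect_true(out$out_of_calibration[1])
  expect_true(is.na(out$sst_C[1]))
  expect_false(any(out$out_of_calibration[-1]))
})

test_that("carbonate-ion correction cools glacial rows and steepens Delta-SST", {
  cfg <- noiseless_config(seed = 17)
  sim <- simulate_downcore(cfg, glacial_history())
  model <- make_truth_model(cfg)
  corrected <- reconstruct_sst(sim$record, model, sim$curve)
  # "uncorrected" route: invert the prediction law on measured Mg/Ca alone
  uncorrected <- invert_temperature(sim$record$mgca_mmolmol, mgca_pred_law())
  glac <- glacial_history()$rsl_m < 0
  expect_true(all(corrected$sst_C[glac] < uncorrected[glac]))
  d_corr <- mean(corrected$sst_C[!glac]) - mean(corrected$sst_C[glac])
  d_unc <- mean(uncorrected[!glac]) - mean(uncorrected[glac])
  expect_gte(d_corr, d_unc)
  expect_equal(d_corr, 10, tolerance = 1e-6)
})

test_that("window statistics aggregate means, spreads and pairwise differences", {
  cfg <- noiseless_config(seed = 18)
  sim <- simulate_downcore(cfg, glacial_history())
  out <- reconstruct_sst(sim$record, make_truth_model(cfg), sim$curve)
  st <- interval_stats(out, list(interglacial = c(0, 12), glacial = c(14, 26)))
  expect_equal(st$windows$n, c(4L, 4L))
  expect_equal(st$windows$sst_mean, c(12, 2), tolerance = 1e-8)
  expect_equal(st$pairs$delta_sst, 10, tolerance = 1e-8)

  one <- interval_stats(out, list(p1 = c(0, 2), p2 = c(24, 26)))
  expect_equal(one$windows$n, c(1L, 1L))
  expect_equal(one$windows$sst_mean, c(12, 2), tolerance = 1e-8)

  same <- interval_stats(out, list(a = c(0, 12), b = c(0, 12)))
  expect_equal(same$pairs$delta_sst, 0)
  expect_error(interval_stats(out, list(hole = c(40, 50))), "hole")
  expect_error(interval_stats(out, list(c(0, 10))), "named")
})

test_that("reconstruction is deterministic and independent of row order", {
  cfg <- default_config(seed = 19)
  sim <- simulate_downcore(cfg, glacial_history())
  model <- make_truth_model(cfg)
  a <- reconstruct_sst(sim$record, model, sim$curve)
  b <- reconstruct_sst(sim$record, model, sim$curve)
  expect_identical(a$sst_C, b$sst_C)
  shuffled <- sim$record[c(5, 1, 8, 2, 7, 3, 6, 4), ]
  c <- reconstruct_sst(shuffled, model, sim$curve)
  expect_equal(c$sst_C[order(c(5, 1, 8, 2, 7, 3, 6, 4))], a$sst_C,
               tolerance = 1e-12)
})

test_that("ensemble-backed reconstruction yields nested, ordered intervals", {
  cfg <- default_config(seed = 23)
  cal <- standardized_set(cfg)
  ens <- mc_calibration_ensemble(cal, uncertainty_spec(n_draws = 200, seed = 2))
  sim <- simulate_downcore(noiseless_config(seed = 24), glacial_history())
  out <- reconstruct_sst(sim$record, make_truth_model(cfg), sim$curve,
                         ensemble = ens,
                         spec = uncertainty_spec(n_draws = 200, seed = 3))
  ok <- is.finite(out$sst_C)
  expect_true(all(out$sst_lo95[ok] <= out$sst_C[ok]))
  expect_true(all(out$sst_C[ok] <= out$sst_hi95[ok]))
})
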