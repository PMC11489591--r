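# Shared fixtures: forward-model configs used across the suite.

# All observation 2-sigmas zero: samples fall exactly on the generating
# surfaces and Monte Carlo draws collapse onto the point fit.
zero_noise_spec <- function(n_draws = 100, seed = NULL) {
  uncertainty_spec(d18O_2s = 0, co3_2s = 0, mgca_corr_2s = 0, temp_2s = 0,
                   n_draws = n_draws, seed = seed)
}

# Self-consistent noiseless generator: the corrected law equals the
# normalization law, so the full chain is an exact identity (the published
# corrected law and prediction law differ slightly and only coexist as fits
# to scattered data).
noiseless_config <- function(n_samples = 60, seed = NULL, ...) {
  forward_config(n_samples = n_samples, exp_law = mgca_exp_law(0.4, 0.09),
                 noise = zero_noise_spec(), ctd_temp_2s = 0, seed = seed, ...)
}

default_config <- function(seed = NULL, ...) forward_config(seed = seed, ...)

# Standardised (crusted-reference) calibration table from a config.
standardized_set <- function(cfg) {
  standardize_samples(simulate_calibration_set(cfg), cfg$cfg,
                      adjust_d18O = FALSE)
}

# The generating truth used throughout.
TRUE_A <- 0.372
TRUE_B <- 0.0936
TRUE_P <- 3227.95
TRUE_Q <- -1.53
TRUE_OXY_SLOPE <- -0.0279

`%||%` <- function(a, b) if (is.null(a)) b else a
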