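#' Forward-model configuration for synthetic proxy data
#'
#' The proxy-system forward model generating calibration sets, water-column
#' profiles and downcore records with known truth. Defaults mirror the
#' published central calibration: corrected law 0.372 * exp(0.0936 T),
#' carbonate-ion sensitivity 3227.95 * [CO3]^-1.53, d18O proxy slope
#' -0.0279 permil per umol/kg with a 2 permil crust offset, temperatures
#' uniform on -2 to 16 C and carbonate ion uniform on 50-220 umol/kg, and
#' the stated 2-sigma observation noise (d18O 0.2 permil, [CO3] 20 umol/kg,
#' corrected Mg/Ca 0.2 mmol/mol, temperature 2.8 C). The oxygen-isotope
#' intercepts (4.0 ontogenetic, 6.0 crusted, permil VPDB) are synthetic
#' placeholders chosen to give realistic calcite d18O of roughly 0-5 permil
#' across the carbonate-ion range; they are not published values.
#'
#' @param n_samples Calibration-set size (>= 10; default 235).
#' @param temp_range,co3_range Sampling intervals for true temperature (C)
#'   and carbonate ion (umol/kg).
#' @param exp_law,power_law,oxy_line Generating laws.
#' @param noise An [uncertainty_spec()] holding the observation 2-sigmas.
#' @param tow_fraction Fraction of samples assigned to the tow (ontogenetic)
#'   population (default 0.5).
#' @param ctd_temp_2s 2-sigma temperature uncertainty for tow samples whose
#'   temperature comes from a paired CTD cast (default 0.2 C).
#' @param coretop_temp_2s Per-sample 2-sigma temperature uncertainties cycled
#'   across core-top samples; the default scales the configured `temp_2s` by
#'   (1, 4/7, 2/7), i.e. (2.8, 1.6, 0.8) C under the standard spec -
#'   depth-estimated, climatology-matched and assemblage-paired core-top
#'   populations respectively.
#' @param cfg A [correction_config()] whose crust/cleaning constants act in
#'   the forward direction.
#' @param seed Integer seed.
#' @return An object of class `forward_config`.
#' @export
forward_config <- function(n_samples = 235,
                           temp_range = c(-2, 16),
                           co3_range = c(50, 220),
                           exp_law = mgca_exp_law(0.372, 0.0936),
                           power_law = mgca_power_law(3227.95, -1.53),
                           oxy_line = oxy_carb_line(-0.0279,
                                                    intercept_ontogenetic = 4.0,
                                                    intercept_crusted = 6.0),
                           noise = uncertainty_spec(),
                           tow_fraction = 0.5,
                           ctd_temp_2s = 0.2,
                           coretop_temp_2s = noise$temp_2s * c(1, 4 / 7, 2 / 7),
                           cfg = correction_config(),
                           seed = NULL) {
  if (n_samples < 10) abort("forward_config(): n_samples must be >= 10")
  if (diff(temp_range) <= 0 || diff(co3_range) <= 0) {
    abort("forward_config(): ranges must be non-degenerate")
  }
  stopifnot(inherits(exp_law, "exp_law"), inherits(power_law, "power_law"),
            inherits(oxy_line, "oxy_carb_line"),
            inherits(noise, "uncertainty_spec"),
            inherits(cfg, "correction_config"))
  structure(list(n_samples = as.integer(n_samples), temp_range = temp_range,
                 co3_range = co3_range, exp_law = exp_law,
                 power_law = power_law, oxy_line = oxy_line, noise = noise,
                 tow_fraction = tow_fraction, ctd_temp_2s = ctd_temp_2s,
                 coretop_temp_2s = coretop_temp_2s,
                 cfg = cfg, seed = seed),
            class = "forward_config")
}

# Noise on the corrected-Mg/Ca scale mapped forward through the sensitivity;
# truncated so measured Mg/Ca stays positive.
forward_mgca <- function(true_t, true_co3, cfg) {
  sens <- cfg$power_law$p * true_co3^cfg$power_law$q
  corr_true <- predict_mgca(true_t, cfg$exp_law)
  n <- length(true_t)
  eps <- draw_noise(n, cfg$noise$mgca_corr_2s, cfg$noise$distribution)
  corr <- redraw_until(corr_true + eps, corr_true, function(x) x > 0,
                       function(b) b + draw_noise(length(b),
                                                  cfg$noise$mgca_corr_2s,
                                                  cfg$noise$distribution))
  as.numeric(corr) * sens
}

#' Simulate a synthetic calibration dataset
#'
#' Draws the *reported* (assigned) temperature and carbonate ion
#' independently and uniformly over the configured ranges, mimicking the
#' design spread of a field calibration set. The true calcification
#' environment scatters around those assigned values with the stated
#' 2-sigma uncertainties (the Berkson structure appropriate to
#' depth-assignment error: the hydrographic assignment is the anchor, the
#' habitat deviates from it), and shell chemistry is forward-modelled from
#' the true values: Mg/Ca from the generating exponential and power laws
#' with corrected-scale noise, calcite d18O from the proxy line with
#' analytical noise. Tow vs core-top populations receive the crust offsets
#' in the forward direction (tow Mg/Ca higher by the crust fraction, tow
#' d18O lighter by the crust offset). Columns prefixed `true_` hold the
#' hidden truth for parameter-recovery tests.
#'
#' @param cfg A [forward_config()].
#' @return A tibble of as-measured samples: `sample_id`, `source`,
#'   `crust_state`, `cleaning`, `mgca_mmolmol`, `d18Oc_permil`, `temp_C`,
#'   `co3_umolkg` (the last two being the assigned environmental values used
#'   in fitting), plus `true_temp_C`, `true_co3_umolkg`, `true_mgca_corr`.
#' @export
simulate_calibration_set <- function(cfg = forward_config()) {
  stopifnot(inherits(cfg, "forward_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples
  obs_t <- runif(n, cfg$temp_range[1], cfg$temp_range[2])
  obs_co3 <- runif(n, cfg$co3_range[1], cfg$co3_range[2])
  tow <- seq_len(n) <= round(cfg$tow_fraction * n)

  # per-sample temperature uncertainty: CTD-paired tows vs the core-top
  # populations (depth-estimated / climatology-matched / assemblage-paired)
  temp_2s <- rep(cfg$ctd_temp_2s, n)
  temp_2s[!tow] <- rep_len(cfg$coretop_temp_2s, sum(!tow))
  # unit draw scaled per-sample so each keeps its own 2-sigma
  true_t <- obs_t + draw_noise(n, 1, cfg$noise$distribution) * temp_2s
  true_co3 <- obs_co3 + draw_noise(n, cfg$noise$co3_2s, cfg$noise$distribution)
  true_co3 <- as.numeric(
    redraw_until(true_co3, obs_co3, function(x) x > 0,
                 function(b) b + draw_noise(length(b), cfg$noise$co3_2s,
                                            cfg$noise$distribution)))

  # crusted-reference measured Mg/Ca, then undo the crust dilution for tows
  mgca <- forward_mgca(true_t, true_co3, cfg)
  mgca[tow] <- mgca[tow] / (1 - cfg$cfg$crust_mgca_fraction)

  intercept <- ifelse(tow, cfg$oxy_line$intercept_ontogenetic,
                      cfg$oxy_line$intercept_crusted)
  d18 <- intercept + cfg$oxy_line$slope * true_co3 +
    draw_noise(n, cfg$noise$d18O_2s, cfg$noise$distribution)

  tibble(
    sample_id = sprintf("syn%04d", seq_len(n)),
    source = ifelse(tow, "tow", "coretop"),
    crust_state = ifelse(tow, "ontogenetic", "crusted"),
    cleaning = "oxidative",
    mgca_mmolmol = mgca,
    d18Oc_permil = d18,
    temp_C = obs_t,
    co3_umolkg = obs_co3,
    temp_2s = temp_2s,
    true_temp_C = true_t,
    true_co3_umolkg = true_co3,
    true_mgca_corr = predict_mgca(true_t, cfg$exp_law)
  )
}

#' Modern surface-water carbonate ion paired with temperature
#'
#' The covariation used for "typical sample" scenarios and downcore forward
#' modelling: [CO3] = 100 + 8 T umol/kg, anchoring ~100 umol/kg at 0 C
#' (Nordic Seas / Labrador Sea surface waters) and ~220 umol/kg at 15 C
#' (temperate North Atlantic).
#'
#' @param temperature Degrees C (vectorized).
#' @return Carbonate-ion concentration, umol/kg.
#' @export
surface_co3_at <- function(temperature) 100 + 8 * temperature

#' Forward-model a single noiseless observation at a true temperature
#'
#' Builds the exact (noise-free) measured Mg/Ca and crusted calcite d18O a
#' sample calcifying at the given temperature would carry under the
#' generating laws and the [surface_co3_at()] temperature - carbonate-ion
#' pairing. Used to anchor Monte Carlo uncertainty checks at stated true
#' temperatures.
#'
#' @param temperature True calcification temperature, degrees C.
#' @param cfg A [forward_config()].
#' @return A one-row tibble: `temp_C`, `co3_umolkg`, `mgca_mmolmol`,
#'   `d18Oc_permil` (crusted reference).
#' @export
typical_sample <- function(temperature, cfg = forward_config()) {
  co3 <- surface_co3_at(temperature)
  sens <- cfg$power_law$p * co3^cfg$power_law$q
  tibble(
    temp_C = temperature,
    co3_umolkg = co3,
    mgca_mmolmol = predict_mgca(temperature, cfg$exp_law) * sens,
    d18Oc_permil = cfg$oxy_line$intercept_crusted + cfg$oxy_line$slope * co3
  )
}

#' Simulate a water-column profile with known equilibrium calcite d18O
#'
#' Builds a smooth 0-400 m profile (exponentially relaxing temperature and
#' salinity, alkalinity/DIC consistent with a chosen surface carbonate-ion
#' level), its equilibrium calcite d18O curve, and a planted sample at a
#' known calcification depth for round-trip depth-inference tests. A
#' non-monotone variant plants a mid-depth temperature inversion so the
#' equilibrium curve crosses a given value more than once.
#'
#' @param cfg A [forward_config()] (seed and noise are honoured).
#' @param surface_temp,deep_temp Surface and deep asymptote temperatures, C.
#' @param planted_depth Depth (m) whose equilibrium d18O is returned as the
#'   planted measurement.
#' @param non_monotone Insert a temperature inversion (default FALSE).
#' @return A list: `profile` (tibble), `equilibrium` (tibble), `truth`
#'   (list with `depth_m`, `d18Oc_permil`).
#' @export
simulate_profile <- function(cfg = forward_config(), surface_temp = 6,
                             deep_temp = 0, planted_depth = 50,
                             non_monotone = FALSE) {
  stopifnot(inherits(cfg, "forward_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  z <- c(0, 10, 20, 30, 50, 75, 100, 150, 200, 250, 300, 350, 400)
  temp <- deep_temp + (surface_temp - deep_temp) * exp(-z / 120)
  if (non_monotone) {
    temp <- temp + 2.5 * exp(-((z - 150) / 40)^2) # warm intrusion
  }
  sal <- 35 - 0.8 * exp(-z / 60)
  d18Osw <- 0.5 * sal - 17.25
  alk <- 2250 + 0.25 * z
  dic <- alk - 130 - 0.1 * z
  profile <- tibble(
    station_id = "SYN01", lat = 60, lon = -30, date = "2020-07-15",
    depth_m = z, temp_C = temp, sal = sal,
    alk_umolkg = alk, dic_umolkg = dic,
    d18Osw_permil = d18Osw, co3_umolkg = NA_real_
  )
  profile <- profile_carbonate(profile)
  eq <- equilibrium_profile(profile)
  truth_d18 <- approx(eq$depth_m, eq$d18Oc_eq_permil, xout = planted_depth)$y
  list(profile = profile, equilibrium = eq,
       truth = list(depth_m = planted_depth, d18Oc_permil = truth_d18))
}

#' Simulate a downcore paired Mg/Ca - d18O record with known truth
#'
#' Forward-models the paired proxies for a prescribed SST history: carbonate
#' ion follows [surface_co3_at()] around each true SST, measured Mg/Ca
#' carries the carbonate-ion overprint, and recorded calcite d18O combines
#' the crusted proxy line with the ice-volume term (-rsl/10 * sl_coeff, so
#' glacial d18O is enriched). Observation noise follows the config; set all
#' 2-sigmas to zero for exact round-trip tests.
#'
#' @param cfg A [forward_config()].
#' @param sst_history A tibble with `age_ka`, `sst_C` and `rsl_m` (relative
#'   sea level, m, negative at glacials).
#' @return A list: `record` (downcore tibble ready for [reconstruct_sst()]),
#'   `truth` (the history), `curve` (matching sea-level curve).
#' @export
simulate_downcore <- function(cfg = forward_config(), sst_history) {
  stopifnot(inherits(cfg, "forward_config"), is.data.frame(sst_history))
  need <- c("age_ka", "sst_C", "rsl_m")
  miss <- setdiff(need, names(sst_history))
  if (length(miss)) {
    abort(paste0("simulate_downcore(): sst_history missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(sst_history) == 0) abort("simulate_downcore(): empty sst_history")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- nrow(sst_history)
  true_t <- sst_history$sst_C
  true_co3 <- surface_co3_at(true_t)
  mgca <- forward_mgca(true_t, true_co3, cfg)
  d18 <- cfg$oxy_line$intercept_crusted + cfg$oxy_line$slope * true_co3 -
    sst_history$rsl_m / 10 * cfg$cfg$sl_coeff +
    draw_noise(n, cfg$noise$d18O_2s, cfg$noise$distribution)
  record <- tibble(
    core_id = "SYNCORE", age_ka = sst_history$age_ka,
    mgca_mmolmol = mgca, d18Oc_permil = d18,
    cleaning = "oxidative", crust_state = "crusted"
  )
  if (is.unsorted(sst_history$age_ka, strictly = TRUE)) {
    abort("simulate_downcore(): sst_history ages must be strictly increasing")
  }
  pad <- 0.05 * max(diff(range(sst_history$age_ka)), 1)
  curve <- tibble(age_ka = c(min(sst_history$age_ka) - pad,
                             sst_history$age_ka,
                             max(sst_history$age_ka) + pad),
                  rsl_m = c(sst_history$rsl_m[1], sst_history$rsl_m,
                            sst_history$rsl_m[n]))
  list(record = record,
       truth = as_tibble(sst_history)[c("age_ka", "sst_C", "rsl_m")],
       curve = curve)
}
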