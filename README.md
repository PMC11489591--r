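# co3therm

Carbonate-ion corrected Mg/Ca paleothermometry for the polar planktonic
foraminifer *Neogloboquadrina pachyderma*.

Mg/Ca in foraminiferal calcite rises exponentially with temperature and is
a standard sea-surface temperature (SST) proxy, but in *N. pachyderma* the
seawater carbonate-ion concentration [CO₃²⁻] leaves a strong non-thermal
overprint: at low [CO₃²⁻], Mg/Ca rises far above the thermal expectation,
so uncorrected records look too warm exactly where glacial oceans were
coldest. `co3therm` is for paleoceanographers who want to apply (or test)
the correction scheme on paired Mg/Ca–δ¹⁸O records: it quantifies the
overprint, removes it, derives the necessary [CO₃²⁻] for fossil samples
from the shells' own oxygen isotopes, and propagates all stated
uncertainties by Monte Carlo.

The core mathematics:

* temperature-only prediction `Mg/Ca_pred = 0.4·exp(0.09·T)` and
  normalisation `Mg/Ca_norm = Mg/Ca_meas / Mg/Ca_pred(T)`;
* carbonate-ion sensitivity `S([CO₃²⁻]) = p·[CO₃²⁻]^q`
  (central 3227.95·[CO₃²⁻]^−1.53), with `Mg/Ca_corr = Mg/Ca_meas / S`;
* corrected calibration `Mg/Ca_corr = a·exp(b·T)`
  (central 0.372·exp(0.0936·T)), inverted as `T = ln(Mg/Ca_corr/a)/b`;
* oxygen-isotope [CO₃²⁻] proxy: δ¹⁸O_c = intercept − 0.0279·[CO₃²⁻], with
  ontogenetic and crusted calcite sharing the slope but offset by ~2 ‰.

Around that core the package provides a seawater carbonate-system solver
(ALK/DIC → [CO₃²⁻], pH, Ω_calcite; Lueker/Dickson/Millero constants),
equilibrium-calcite δ¹⁸O profiles and calcification-depth inference, the
fixed pre-processing corrections (crust 15 % / +2 ‰, reductive cleaning
+10–15 %, ice-volume 0.11 ‰ per 10 m of sea level), a 1000-draw Monte
Carlo uncertainty engine, a downcore reconstruction pipeline, and a seeded
proxy-system forward model for synthetic data with known truth. See the
methods vignette (`vignettes/carbonate-ion-correction.Rmd`) for the science
and every numerical choice.

## Worked example

Fit the full calibration on a synthetic 235-sample set carrying the stated
observation noise, then reconstruct a downcore record:

```r
library(co3therm)

cfg     <- forward_config(seed = 7)            # generator = published laws
samples <- simulate_calibration_set(cfg)
std     <- standardize_samples(samples, adjust_d18O = FALSE)
model   <- fit_calibration(std)
model
#> Calibration model
#>   corrected:  Mg/Ca = 0.374 * exp(0.09345 T)  [2s: a 0.0266, b 0.00592]  n = 235, r2 = 0.846
#>   sensitivity: S([CO3]) = 2775.82 * [CO3]^-1.501  [2s: p 1.05e+03, q 0.072]  n = 235, r2 = 0.823
#>   oxy proxy:   d18O_c = intercept -0.02758 * [CO3]
#>   intercepts: ontogenetic 3.954, crusted 5.953 (n = 235)
```

The chain recovers the generating laws (0.372, 0.0936, −1.53, −0.0279)
within their fitted 95 % intervals. Reconstructing a glacial–interglacial
record forward-modelled at known SSTs:

```r
prep <- derive_co3_for_crusted(std, model$oxy_line)
ens  <- mc_calibration_ensemble(prep, uncertainty_spec(seed = 1))

hist <- data.frame(age_ka = seq(0, 24, by = 3),
                   sst_C  = c(10, 10, 9, 7, 4, 2, 2, 2, 2),
                   rsl_m  = c(0, 0, -10, -40, -80, -120, -120, -120, -120))
sim    <- simulate_downcore(forward_config(seed = 9), hist)
series <- reconstruct_sst(sim$record, model, sim$curve,
                          ensemble = ens, spec = uncertainty_spec(seed = 2))
dplyr::select(tibble::as_tibble(series), age_ka, co3_umolkg, sst_C, sst_lo95, sst_hi95)
#>   age_ka co3_umolkg sst_C sst_lo95 sst_hi95
#> 1      0       182.  9.23     8.93    10.2
#> 2      3       176.  8.64     8.32     9.68
#> ...
#> 8     21       116.  2.05     1.51     3.72
#> 9     24       125.  2.72     2.20     4.21

interval_stats(series, list(holocene = c(0, 6), glacial = c(15, 24)))$pairs
#>   window_a window_b delta_sst delta_2s
#> 1 holocene glacial       7.07    0.680
```

The record was generated with a Holocene mean of 9.7 °C and a glacial mean
of 2 °C (ΔSST 7.7 °C); the pipeline — cleaning adjustment, ice-volume δ¹⁸O
correction, δ¹⁸O-derived [CO₃²⁻], sensitivity division, inversion — returns
7.07 ± 0.68 °C. `plot_calibration()`, `plot_sst_series()` and `autoplot()`
methods draw the standard figures.

A thin command line (`inst/cli/co3therm.R`) wraps the same functions:
`calibrate`, `depth`, `reconstruct`, `simulate`, each with `--seed`,
`--config`, `--out`.

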