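---
title: "Correcting polar Mg/Ca paleothermometry for the carbonate-ion overprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting polar Mg/Ca paleothermometry for the carbonate-ion overprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co3therm)
```

## The problem

The Mg/Ca ratio of foraminiferal calcite rises exponentially with
calcification temperature and is one of the workhorse sea-surface
temperature (SST) proxies. In the polar planktonic foraminifer
*Neogloboquadrina pachyderma* the thermal signal is, however, strongly
overprinted by the carbonate-ion concentration of the water the shell grew
in: at low [CO~3~^2-^] the organism's Mg-exclusion machinery becomes
inefficient and measured Mg/Ca rises far above the thermal expectation.
Uncorrected, this overprint masquerades as warmth exactly where glacial
oceans were coldest, and glacial-interglacial temperature amplitudes are
systematically understated.

`co3therm` implements a correction scheme that quantifies the overprint,
removes it, and — because fossil samples come with no water-column
chemistry — derives the needed [CO~3~^2-^] from the shells' own oxygen
isotopes.

## The model

Three empirical laws, fitted in sequence, carry the scheme:

1. **Temperature-only prediction.**
   $\mathrm{Mg/Ca}_{pred} = 0.4\,e^{0.09\,T}$ (mmol/mol, $T$ in °C), the
   neogloboquadrinid sensitivity assumed shared between *N. incompta* and
   *N. pachyderma*. Measured values are normalised against it:
   $\mathrm{Mg/Ca}_{norm} = \mathrm{Mg/Ca}_{meas}/\mathrm{Mg/Ca}_{pred}(T)$.

2. **Carbonate-ion sensitivity.** The normalised values follow a power law
   in carbonate ion,
   $S([\mathrm{CO_3^{2-}}]) = p\,[\mathrm{CO_3^{2-}}]^{q}$ with $q < 0$
   (central values $p = 3227.95$, $q = -1.53$). Dividing the measurement by
   $S$ removes the non-thermal component:
   $\mathrm{Mg/Ca}_{corr} = \mathrm{Mg/Ca}_{meas}/S$.

3. **Corrected calibration.** The corrected values obey
   $\mathrm{Mg/Ca}_{corr} = a\,e^{b\,T}$ (central values $a = 0.372 \pm
   0.014$, $b = 0.0936 \pm 0.0045$, 2$\sigma$), inverted for temperature as
   $T = \ln(\mathrm{Mg/Ca}_{corr}/a)/b$.

The independent [CO~3~^2-^] proxy is the calcite oxygen isotope ratio:
$\delta^{18}O_c$ falls linearly with carbonate ion at a common slope of
$-0.0279$ permil per µmol/kg for ontogenetic (tow) and crusted (core-top)
calcite, the two populations offset by ~2 permil (crust heavier). Solving
that line for [CO~3~^2-^] turns every paired Mg/Ca–$\delta^{18}O_c$
measurement into a self-contained SST estimate.

### Identifiability and the no-effect anchor

Only the product $a \cdot p$ is constrained by measured Mg/Ca: any factor
moved from the sensitivity's level into the calibration's pre-exponential
leaves every prediction unchanged. The package resolves this with a
physically motivated convention: a correction factor must leave Mg/Ca
untouched where the effect it corrects is absent, and the carbonate-ion
effect vanishes near 200 µmol/kg. `fit_calibration()` therefore anchors the
fitted sensitivity to $S = 1$ at `co3_no_effect()` $= 3227.95^{1/1.53} =
196.5$ µmol/kg — the value at which the central sensitivity itself equals
unity. Without the anchor, the arbitrary level of the prediction law leaks
into $a$ (for a uniform $-2$ to $16$ °C design it would pin $a$ at
$0.4\,e^{-0.0036\,\bar T} = 0.390$ regardless of the data). The standalone
`fit_co3_sensitivity()` keeps a free level by default.

A related subtlety: the prediction law $0.4\,e^{0.09T}$ and the corrected
law $0.372\,e^{0.0936T}$ are mutually inconsistent as exact surfaces — they
coexist only as fits to scattered data. Noiseless identity tests in the
package therefore use a self-consistent generator (corrected law equal to
the prediction law) where the full chain is an exact round trip; the noisy
default generator keeps the published central laws.

### Estimator choices

* The sensitivity's scatter is multiplicative (a roughly constant
  coefficient of variation), so its default estimator is ordinary least
  squares in log-log space; natural-scale nonlinear least squares is
  available (`scale = "natural"`) but is markedly less stable for the
  exponent at realistic noise.
* The corrected calibration's scatter is absolute (±0.2 mmol/mol, 2σ,
  regardless of level), so its default estimator is natural-scale nonlinear
  least squares initialised from the log-linear fit. Inside the Monte Carlo
  slope ensemble the per-draw refits use the log-linear form, which spreads
  leverage evenly along the temperature axis and reproduces the published
  coefficient uncertainties (±0.014 / ±0.0045 at 2σ for n = 235).
* r² is reported on the natural scale in all cases.

## Pre-processing corrections

All fixed adjustments live in `correction_config()` and are applied exactly
once per sample (a bookkeeping guard raises on re-application):

| adjustment | default | reason |
|---|---|---|
| tow Mg/Ca × (1 − 0.15) | 15 % | gametogenic crust dilutes whole-test Mg/Ca; tow (uncrusted) material is adjusted down to the sedimentary reference |
| tow δ¹⁸O + 2 permil | 2 permil | crust calcite is isotopically heavier |
| reductive-cleaning Mg/Ca × (1 + 0.15) | 10–15 % | reductive cleaning strips Mg; compensated when pooling with oxidatively cleaned data |
| δ¹⁸O + rsl/10 × 0.11 permil | 0.11 permil per 10 m | removes the whole-ocean ice-volume δ¹⁸O~sw~ signal before δ¹⁸O is read as a carbonate-ion proxy (at −120 m this subtracts 1.32 permil) |
| vital effect | 0 | no systematic disequilibrium offset by default; configurable per dataset |

The cleaning fraction defaults to the top of the published 10–15 % range
and is configurable per record, since which datasets received which offset
is not recorded.

## Calcification depths

Core-top samples are tied to hydrography by matching their measured
$\delta^{18}O_c$ to the depth profile of equilibrium calcite
$\delta^{18}O$, computed from the quadratic paleotemperature form
$T = 16.9 - 4.38\,\Delta + 0.10\,\Delta^2$ (the Shackleton refit of the
O'Neil inorganic-calcite experiments; pluggable through
`paleotemp_equations`) with the 0.27 permil VSMOW-to-VPDB adjustment.
Seawater $\delta^{18}O$ comes per level from the profile or from a
site-specific salinity mixing line. Matching returns the **shallowest**
crossing — consistent with the species' shallow-habitat ecology — and
reports the number of crossings rather than ever averaging them; depths
below 300 m are flagged as suspect (usually a profile warmer than the
calcification environment), and values with no crossing return
`matched = FALSE` rather than an error, since fossil material may
legitimately fall outside the modern water column. The search range is
0–400 m.

## The carbonate-system solver

`solve_carbonate()` computes [CO~3~^2-^], pH (total scale) and calcite
saturation from alkalinity/DIC pairs with the de-facto standard constant
set of CO2SYS-family tools (Lueker et al. 2000 K1/K2, Dickson 1990 boric
acid and bisulfate, Dickson & Riley 1979 fluoride, Millero 1995 water and
pressure corrections, Uppström 1974 boron, Mucci 1983 calcite solubility),
root-bracketing pH in [6, 9.5] to 10⁻⁸ pH units. Nutrient alkalinity is not
modelled (sub-percent effect in the target waters). The constant set is the
package's documented choice; a `solver` argument provides an adapter seam
for swapping in an external implementation. The test suite pins the solver
against an independently coded reference implementation over ALK 2200–2400,
DIC 1900–2250 µmol/kg, S 30–35, T −1–20 °C, requiring agreement within 1 %.

## Uncertainty propagation

All uncertainties are propagated by seeded Monte Carlo
(`mc_calibration_ensemble()`, default 1000 draws), never analytically.
The input 2σ values (`uncertainty_spec()`): δ¹⁸O 0.2 permil, hydrographic
[CO~3~^2-^] 20 µmol/kg, corrected Mg/Ca 0.2 mmol/mol (treated as absolute on
the corrected value; a relative mode exists because the published unit is
ambiguous), and per-sample temperature uncertainties — 0.2 °C for CTD-paired
tows and 2.8 / 1.6 / 0.8 °C for the three core-top populations
(depth-estimated, climatology-matched, assemblage-paired).

The ensemble has two stages, mirroring how the scheme chains its
uncertainties: a sensitivity stage (jitter carbonate ion and temperature,
refit the power law) and a calibration stage (jitter the centrally
corrected Mg/Ca — whose ±0.2 already subsumes the carbonate-ion propagation
— and temperature, refit the exponential law). Refitting jointly per draw
carries the coefficient error covariance empirically. Medians are the
central estimates; 2σ is the 2.5–97.5 percentile half-width; a prediction
interval can add residual scatter in quadrature for single new
observations.

`temperature_with_uncertainty()` composes, per draw, the calibration
coefficient uncertainty with the δ¹⁸O-derived carbonate-ion term (δ¹⁸O
noise mapped through the proxy line). Mg/Ca measurement noise and draw-wise
sensitivity laws are optional switches, off by default: the corrected-Mg/Ca
uncertainty already carries those terms into the coefficient draws, and the
published composition is calibration plus carbonate-ion only.

Perturbations are independent Gaussians at the stated 2σ by default;
a uniform-within-±2σ mode is available since the published wording does not
fix the distribution. Non-positive perturbed values are redrawn (truncated
sampling) and counted.

## The synthetic forward model

`forward_config()` / `simulate_calibration_set()` generate calibration sets
with known truth: 235 samples, assigned temperature uniform on −2–16 °C and
assigned carbonate ion uniform on 50–220 µmol/kg (independently — the
design spread of a field compilation), half tow / half core-top with the
crust offsets applied in the forward direction. Observation noise follows
the Berkson structure appropriate to depth-assignment uncertainty: the
assigned (reported) values anchor the design and the true calcification
environment scatters around them with the stated 2σ, so fits on reported
values are nearly unbiased — under the classical alternative (true values
uniform, reported = true + noise) the stated 2.8 °C temperature noise alone
attenuates the fitted exponent by ~19 %, and no estimator could recover the
published coefficients. Mg/Ca noise is additive on the corrected scale
(N(0, 0.1), i.e. ±0.2 at 2σ) and mapped through the sensitivity, making the
published corrected-Mg/Ca uncertainty literally true after correction.

For single-sample scenarios and downcore forward modelling, carbonate ion
covaries with temperature as `surface_co3_at()` $= 100 + 8T$ µmol/kg,
anchoring ~100 µmol/kg at 0 °C (Nordic Seas / Labrador Sea surface waters)
and ~220 µmol/kg at 15 °C (temperate North Atlantic). `simulate_downcore()`
adds the ice-volume δ¹⁸O term (−rsl/10 × 0.11 permil) so the full
reconstruction pipeline can be exercised end to end against known truth.

What the generator does **not** emulate: seasonality and flux weighting of
the calcifying population, sea-ice habitats, dissolution at the seafloor,
varying crust fractions, age-model error, and any covariance between
temperature and carbonate ion in the calibration set (deliberately absent
there, present only in the downcore scenarios). Passing tests demonstrate
the mathematics and its implementation under the stated statistical
conditions, not robustness of the proxy to those unmodelled processes.

## Numerical choices and degenerate inputs

* pH root-bracketing tolerance 10⁻⁸ in [6, 9.5]; no root → explicit error
  naming the inputs.
* Fits refuse degenerate designs (identical carbonate ion, ≤ 2 °C
  temperature span, identical salinities) with specific errors.
* Derived carbonate ion outside (0, 350) µmol/kg is flagged
  `out_of_calibration`, computed anyway, and counted — downcore rows are
  never silently dropped. Sensitivity evaluation above 250 µmol/kg warns.
* The running mean (window 3 by default) shrinks at the series ends rather
  than truncating, and drops NAs within the window.
* Monte Carlo draws that fail to fit are excluded and counted; more than
  5 % failures aborts with diagnostics.
* All randomness flows from user-supplied seeds; equal seeds give bitwise
  identical outputs.

## Problem sizes

The test suite runs calibration sets of n = 235 (the published compilation
size), Monte Carlo ensembles of 250–1000 draws, 500-repetition coverage
experiments, and a ~60-case carbonate-solver reference grid; the whole
suite completes in about two minutes on a single core. The acceptance
script refits one 235-sample set and one 1000-draw ensemble (~20 s).

## Known limitations

* The oxygen-isotope proxy intercepts are not published; the synthetic
  defaults (4.0 / 6.0 permil VPDB) give realistic calcite values over the
  calibration range but real applications must fit or supply intercepts
  from their own calibration data.
* The correction chain inherits the prediction-law convention; comparing
  coefficients across studies requires the same normalisation and the same
  level anchor.
* The δ¹⁸O route assumes the ice-volume correction and the crust state are
  known; misassigned crust state shifts derived carbonate ion by ~72
  µmol/kg (2 permil / 0.0279).
* Below ~50 µmol/kg the sensitivity is an extrapolation; the package flags
  but does not refuse such values.
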