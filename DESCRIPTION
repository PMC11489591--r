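Package: co3therm
Title: Carbonate-Ion Corrected Mg/Ca Paleothermometry for Polar Foraminifera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibration and correction toolkit for Mg/Ca paleothermometry in
    the polar planktonic foraminifer Neogloboquadrina pachyderma. Isolates the
    seawater carbonate-ion overprint on Mg/Ca from temperature, uses calcite
    oxygen isotopes as an independent carbonate-ion proxy, solves the seawater
    carbonate system from alkalinity and dissolved inorganic carbon, infers
    apparent calcification depths from equilibrium-calcite oxygen-isotope
    profiles, and reconstructs polar sea-surface temperatures from paired
    Mg/Ca and d18O downcore records with Monte-Carlo-propagated uncertainties.
    Includes a seeded proxy-system forward model for generating synthetic
    calibration sets, water-column profiles, and downcore records with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
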