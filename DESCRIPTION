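Package: domwheel
Title: Composition Wheels for Dissolved Organic Matter Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes concentration-independent dissolved organic matter (DOM)
    composition metrics from UV-Vis absorbance spectra (Naperian absorption
    coefficients, E2:E3 and E4:E6 ratios, SUVA and specific absorption
    coefficients, exponential spectral slopes and the slope ratio), derives
    dissolved organic nitrogen and the molar DOC:DON ratio from chemistry, and
    carries LC-OCD size-exclusion fractions alongside. Screens metrics by
    their contribution to the first two principal components to select four
    quasi-independent wheel axes, then builds min-max-normalized four-axis
    polygon "Composition Wheels" with polygon geometry, end-member template
    classification, degradation-direction annotations, and deterministic SVG /
    ggplot2 rendering. Includes a synthetic data generator emulating
    groundwater-like and photolyzed-like DOM end members so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
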