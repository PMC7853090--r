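Package: dielphage
Title: Single-Cell Polony Infection Assays and Diel Cyanophage Mortality Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts single-cell polony assay counts into corrected percent
    infection with bootstrap uncertainty, tests for diel (24-h) periodicity in
    infection and abundance time series, and translates instantaneous infection
    of Prochlorococcus by T4-like and T7-like cyanophages into daily mortality,
    encounter-rate, and phage-turnover estimates. Includes a synthetic campaign
    generator with a ground-truth channel so every pipeline stage can be
    validated by parameter recovery without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
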