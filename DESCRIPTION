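Package: sinusvent
Title: Xenon Dual-Energy CT Sinus Ventilation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies paranasal sinus ventilation from dynamic xenon-enhanced
    dual-energy CT series. Encodes laminar/pulsating gas-delivery protocols,
    provides a synthetic dual-energy head phantom with first-order compartmental
    xenon exchange, computes voxel-wise xenon enhancement maps, extracts per-ROI
    time-density curves, normalizes them to fractional xenon concentration
    against the input-nostril reference, and fits first-order exponential
    wash-in/wash-out models to recover the characteristic ventilation time
    constant tau per sinus. Includes an end-to-end simulate/analyze pipeline
    with YAML configuration and reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
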