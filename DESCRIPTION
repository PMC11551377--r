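Package: sedgeflux
Title: Q10 Temperature-Response Fitting and MEGAN-Style Isoprene Emission
    Modelling for Sedges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the temperature sensitivity of biogenic
    isoprene emission and its consequences during heat waves. Converts raw
    leaf-chamber records (mixing-ratio difference, chamber flow, leaf area)
    into area-based emission rates, fits the exponential Q10 temperature
    response in log space with confidence intervals, and drives a leaf-scale
    MEGANv2.1-style emission model (light and temperature activity factors
    with 24-h/240-h acclimation) with either the default MEGAN temperature
    response or a fitted exponential response. Includes generators for
    synthetic chamber series and diurnal meteorological forcing with a
    heat-wave block, period segmentation and summary statistics (means,
    maxima, percent change, cross-species ratios), and a reproducible
    pipeline runner with CSV/YAML/JSON interfaces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
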