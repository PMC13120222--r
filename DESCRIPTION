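Package: vocflux
Title: Leaf VOC Fluxes and In Vivo Isoprene Precursor Kinetics from
    PTR-TOF-MS Cuvette Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies leaf-level volatile organic compound (VOC) emission
    fluxes from proton-transfer-reaction time-of-flight mass spectrometry
    (PTR-TOF-MS) channel time series recorded in a dynamic leaf cuvette, and
    infers in vivo isoprene precursor kinetics from post-illumination decay
    transients.  Provides the cuvette mass balance with empty-chamber blank
    correction, an m/z channel registry mapping ions to compounds and six
    biosynthetic VOC groups, estimation of the dimethylallyl diphosphate
    (DMADP) pool size by integrating the isoprene decay curve and of the
    apparent isoprene synthase rate constant from the initial decay rate,
    treatment-level statistics (four-parameter logistic temperature-response
    fits, substrate-control regressions with configurable temperature
    exclusion, per-temperature pooled-variance t-tests), and a forward
    leaf-chamber simulator for validating the whole chain by parameter
    recovery across a temperature x CO2 factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
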