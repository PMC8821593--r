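Package: somitempo
Title: Morphogen-Gradient Somite Positioning, Temperature Scaling and
    RT-qPCR Delta-Ct Analysis for Zebrafish Somitogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative clock-and-wavefront analysis of zebrafish
    somitogenesis. Implements a closed-form exponentially decaying Fgf8
    morphogen field whose spatial gradient, thresholded at each tick of the
    segmentation clock, places somite boundaries; critical-slowing-down
    temperature laws under which every developmental rate is proportional to
    (T - Tc); a delta-Ct RT-qPCR pipeline with chi-square-weighted linear
    fits, multi-temperature collapse onto somite stage, gene classification
    and reference-gene stability scoring; seeded synthetic-data generators
    for Ct tables, kymograph traces and rate-versus-temperature tables; and
    delimited-text readers/writers plus scenario configuration.
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
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
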