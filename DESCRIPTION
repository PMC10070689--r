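Package: vascmorph
Title: Design-Based Stereology and Electron-Microscopy Morphometry of
    Spinal Cord Microvessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based stereological estimators of microvessel numerical
    density, boundary (surface) density, areal density and surface-to-volume
    ratio from binary vessel-profile masks of spinal cord sections, with
    lesion-cavity exclusion; orthogonal-thickness morphometry of capillary
    basement membranes and intercellular clefts from electron-microscopy
    contour traces; hierarchical aggregation of field estimates over
    sections and animals with two-way ANOVA/Tukey and Kruskal-Wallis/Dunn
    comparisons; and a synthetic vessel-scene and cohort generator with
    exact geometric ground truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
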