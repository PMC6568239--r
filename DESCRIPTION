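Package: stmapr
Title: Spatio-Temporal Mapping and Classification of Intestinal Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gastrointestinal motility from time-lapse recordings of
    tubular organs. Converts binary segmentation masks of an intestine into
    calibrated diameter matrices (kymographs), renders normalized gray-scale
    and binary spatio-temporal maps, detects contractions as local diameter
    minima with similar-diameter extension, groups contraction cells into
    events by connectivity, classifies events into standing contractions,
    ripples and slow propagating contractions from their propagating distance
    and the linearity of position-versus-time regression, and summarizes
    per-segment frequencies, directionality and parameter distributions.
    Includes the before/after treatment statistics used to assess hormonal
    effects (log2 after/before ratios with one-sample t-tests, quartile
    categorization, Kruskal-Wallis with Dunn post-hoc, ANOVA with Tukey) and a
    synthetic kymograph generator with ground-truth events for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
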