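Package: rangegap
Title: Ensemble Species Distribution Models, Protected-Area Effectiveness
    and Gap Analysis on Gridded Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for climate-change conservation assessment
    of range-restricted taxa. Generates synthetic spatially autocorrelated
    climate landscapes, virtual species and protected areas; reduces climate
    layers to principal-component axes fitted on the present scenario and
    projected onto futures with the present-fit coefficients; fits
    presence/pseudo-absence distribution models per taxon with geographically
    structured (checkerboard) or k-fold validation and averages above-average
    algorithms into an ensemble; binarizes suitability at the
    Jaccard-maximizing threshold, applies land-cover masks and stacks ranges
    into richness maps; tests each protected area's richness capture against
    a translation-randomization null model; and scores per-taxon
    representation against area-scaled protection targets across nested
    protected-area scenarios.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
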