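Package: imcprofiler
Title: Single-Cell Drug-Response Profiling for Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for in vitro drug-profiling
    experiments acquired by Imaging Mass Cytometry (IMC). Reads and writes
    multichannel ion-count TIFF stacks and 16-bit label masks, segments
    nuclei and whole cells with a two-stage primary/secondary object
    strategy, extracts per-cell morphology and mean marker intensities,
    normalizes by percentile-clipped z-scores, compares treatment
    conditions with rank-based tests, embeds single cells with t-SNE,
    classifies nuclear phenotypes with a from-scratch Fast Gentle Boosting
    stump classifier, and summarizes treatment similarity through pairwise
    Pearson correlation, complete-linkage clustering, and thresholded
    correlation networks. A bundled synthetic-data generator emulates
    drug-treated MCF-7 monolayers with ground-truth masks and planted
    effect sizes so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    digest,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
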