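Package: neutrack
Title: Tracking-by-Detection of Migrating Neutrophils in Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tracking-by-detection toolkit for highly motile cells in
    fluorescence time-lapse microscopy. Provides image pre-processing
    (maximum intensity projection, percentile contrast stretch, median
    denoising, Gaussian smoothing), a deterministic reference segmenter with
    instance-level evaluation metrics (IoU, F1, under/over-segmentation
    counts), overlap-based score matrices between adjacent frames, and four
    trajectory-linkage algorithms: greedy frame-to-frame association,
    Hungarian assignment, basic Viterbi dynamic programming, and an extended
    Viterbi linker that resolves cell merge/split events and appearance/
    disappearance using occupancy constraints with a geometrically
    discounted merge threshold. Includes tracking-quality metrics (track and
    object purity, falsely identified tracker/object rates, average track
    length), nonparametric cross-method comparison (Kruskal-Wallis with
    Dunn's post-hoc and Benjamini-Hochberg correction), cell-migration
    statistics (net displacement, meandering index, mean speed), and a
    synthetic time-lapse simulator that generates image sequences with
    ground-truth masks and trajectories exhibiting persistent migration,
    appearance, disappearance, merging and splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
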