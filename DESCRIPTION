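Package: rbcdeform
Title: Morphometry, Deformability and Classification of Red Blood Cells in
    Paired Compression Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale analysis of red-blood-cell (RBC) fields
    imaged before and after gentle mechanical compression: a seeded synthetic
    scene generator with per-cell ground truth, a segmentation chain
    (grayscale, contrast rescale, thresholding, hole filling, connected
    components, stacked-cell removal), per-cell shape descriptors (mean
    diameter, Feret axis ratio, circularity) and population summaries, a
    paired-frame deformability index Dr = sqrt(Sd/Sud) with optimal cell
    matching, a fused image-embedding plus parameter-vector classifier, and
    the method-comparison statistics used to validate such devices
    (Bland-Altman, Passing-Bablok, ROC with Youden threshold, mountain plot).
License: MIT
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
    png,
    tiff,
    EBImage,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
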