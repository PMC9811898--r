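Package: fragmeth
Title: Fragment-Level DNA Methylation Analysis: Block Segmentation,
    Cell-Type Markers and Methylome Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for fragment-level whole-genome bisulfite sequencing
    (WGBS) analysis. Segments the genome into homogeneous methylation blocks
    by multichannel dynamic programming over a pseudocount-regularized
    Bernoulli likelihood, discovers cell-type-specific differentially
    methylated markers by one-vs-all quantile contrasts, classifies
    individual sequenced fragments as mostly-unmethylated (U), mixed (X) or
    mostly-methylated (M), builds a markers-by-cell-types reference atlas of
    U-fragment proportions, and infers the cell-type composition of a mixed
    methylome (for example, cell-free DNA) by non-negative least squares.
    Includes a synthetic fragment-level methylome generator and an in-silico
    spike-in benchmark for detection-limit studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
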