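Package: salamandr
Title: Pheromone Discovery in De Novo Transcriptomes of Salamander
    Courtship Glands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy, fully tested re-implementation of the bespoke stages of
    a de novo courtship-gland transcriptome pipeline: FASTQ quality trimming
    and read filtering, digital normalization by median k-mer coverage,
    six-frame open reading frame extraction with a minimum-length filter,
    Smith-Waterman homology filtering with Karlin-Altschul E-values, a
    grammar-based classifier for three-finger-domain (TFD) pheromone
    precursors (alpha/beta sodefrin precursor-like factor, preprosodefrin,
    plethodontid modulating factor, axolotl antifreeze protein), and TPM
    quantification with an EM resolver for multi-mapping reads and bootstrap
    confidence intervals. Ships a read/transcript simulator that produces
    grammar-conformant precursor pools with a ground-truth manifest, so the
    whole pipeline is exercised end-to-end against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
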