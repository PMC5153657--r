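Package: circaging
Title: Circular RNA Detection, Quantification and Aging Differential
    Accumulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying circular RNA (circRNA)
    accumulation in aging tissues from total RNA-seq. Provides a synthetic
    study generator with known ground truth (toy genome, gene models,
    age-structured circular and linear transcript abundances, paired-end
    reads with sequencing errors and PCR duplicates), de novo back-spliced
    junction discovery by split-anchor alignment, junction-scaffold read
    quantification with duplicate removal and expression filters, TPM/FPKM
    normalization with old-versus-young differential tests and a global
    distribution-shift test, circular-versus-linear host-gene independence
    analysis, genomic feature classification of circRNA loci, and conserved
    microRNA seed-site scanning restricted to circRNA exons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
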