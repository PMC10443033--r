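Package: evolvamp
Title: Amplicon Deep-Sequencing Analysis of CRISPR-Guided Directional Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies targeted in vivo mutagenesis from paired-end amplicon
    deep sequencing. Implements merging of perfectly overlapping read pairs,
    glocal alignment of merged reads to a single amplicon reference, allele
    pileups, per-position mutation-frequency profiles with parental background
    subtraction and flooring, read-level diversity analysis (unique-read
    tallies, Hamming/edit-distance indel removal, occurrence and parental
    filters, transition/transversion spectra), and reversion-assay statistics.
    Ships a synthetic-read generator that emulates the directional mutational
    footprint of a nickase-guided error-prone DNA polymerase, so the whole
    pipeline can be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
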