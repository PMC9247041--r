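Package: peachlnc
Title: Discovery and Characterization of Long Noncoding RNAs in Fruit Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A transcript-level pipeline for genome-wide identification and
    characterization of long noncoding RNAs (lncRNAs) from assembled
    strand-specific RNA-seq transcripts. Classifies candidate transcripts
    against a reference annotation by positional class codes, filters to
    confident lncRNAs with a coding-potential consensus (longest ORF, Fickett
    TESTCODE, hexamer log-likelihood, protein-motif scan), calls stage-specific
    differentially expressed lncRNAs with a negative-binomial Wald test and
    Benjamini-Hochberg correction, predicts cis targets by genomic proximity
    and trans targets by nearest-neighbor RNA-RNA duplex energy, assembles
    competing-endogenous-RNA (ceRNA) networks from plant-rule miRNA sites,
    and assesses sequence and positional (synteny-based) conservation against
    a second genome. Ships a fully truth-labeled synthetic-data generator so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
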