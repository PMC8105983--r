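Package: qsmine
Title: Mining Acyl-Homoserine-Lactone Quorum-Sensing Genes in Bacterial
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects LuxI-family autoinducer synthases and LuxR-family
    transcriptional regulators in draft bacterial genome assemblies using
    position-specific log-odds profiles built from packaged seed
    alignments, validates candidates by domain architecture and by
    conserved-residue consensus in TraR/TraI reference numbering
    (including a residue-consensus rescue for synthases lacking the
    conserved-site evidence), classifies ligand-binding-domain
    substitution patterns, and calls each validated luxR paired or solo
    using a 10 kbp gene-neighborhood window.  Includes a deterministic
    synthetic-genome simulator that plants optionally mutated family
    members with ground-truth annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
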