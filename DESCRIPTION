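Package: nanoclone
Title: Clonality and IGHV Mutational Status from Nanopore IGH Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls the clonotypic immunoglobulin heavy-chain variable (IGHV)
    gene(s) from noisy long-read IGH amplicon sequencing data, builds and
    polishes per-clone consensus sequences, assigns germline V/D/J genes
    locally, computes V-region germline identity, and classifies somatic
    hypermutation (SHM) status by the 2 percent identity rule used in chronic
    lymphocytic leukemia diagnostics. Includes a ground-truthed read simulator
    (VDJ recombination, SHM, nanopore-style substitution/insertion/deletion
    errors) and a synthetic germline mini-locus so the whole pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    rtracklayer,
    rlang,
    ggplot2,
    withr,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
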