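# Regenerates the packaged synthetic mini-locus under inst/extdata/.
# Run from the package root: Rscript data-raw/make_locus_fixture.R
library(nanoclone)

db <- build_fixture_db(n_v = 8, seed = 42)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_germline_db(db,
                  "inst/extdata/synthetic_ighlocus.fasta",
                  "inst/extdata/synthetic_ighlocus.bed")
cat("wrote", nrow(db$genes), "genes;",
    nchar(db$contig_seq), "bp contig\n")
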