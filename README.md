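# nanoclone

Clonality and IGHV mutational status from nanopore IGH amplicon reads.

## The problem

In chronic lymphocytic leukemia (CLL), the somatic hypermutation (SHM) load
of the clonotypic immunoglobulin heavy-chain variable (IGHV) gene is a key
prognostic marker. The standard readout is the **germline identity** of the
rearranged V gene: with `n_m` matching positions out of `n` aligned columns,

```
identity% = 100 * n_m / n        (indel bases each count one column)

identity% >= 98.00  ->  unmutated   (ERIC 2% rule)
identity% <  98.00  ->  mutated
97.00 <= identity% < 98.00  ->  flagged "borderline"
```

Nanopore sequencing of IGH FR1&rarr;J amplicons (~0.5 kb) makes the assay
cheap and fast, but its ~10% per-read error rate is fifty times the signal.
`nanoclone` closes that gap in three deterministic stages:

1. **Clonality** — local alignment of reads to a germline mini-locus
   (Smith–Waterman, match +2 / mismatch −4 / gap open −4 / gap extend −2),
   mean per-V-gene coverage, and a clonal call for every V gene at or above
   the coverage threshold (default **500X**, inclusive).
2. **Consensus** — per-clone read partitioning by normalized edit distance
   under an escalating tolerance schedule (0.05 &rarr; 0.20), a
   supporting-read filter (default 20), star alignment to a medoid read with
   per-column majority calls, and iterative realign-and-recall polishing.
3. **Annotation** — local germline V/D/J assignment, V-region identity,
   productivity (reading frame V&rarr;J and no in-frame stop codon), and the
   2% classification with borderline flagging.

A ground-truthed simulator (VDJ recombination with trimming and
N-additions, SHM, nanopore-style substitution/insertion/deletion errors)
plus a synthetic germline mini-locus make the whole pipeline testable with
no external data. See `vignettes/nanoclone-methods.Rmd` for the methods in
detail.

## Worked example

```r
library(nanoclone)

db <- build_fixture_db(8, seed = 42)        # synthetic IGH mini-locus
vg <- db_genes(db, "V"); dg <- db_genes(db, "D"); jg <- db_genes(db, "J")

# one clone, 3% SHM, 1000 reads at ~10% read error
spec <- productive_clone_spec(db, vg$name[3], dg$name[1], jg$name[1],
                              shm_rate = 0.03)
sam <- simulate_sample(db, list(spec), 1000, error_model(), rng_seed = 7)
sam$clones$v_identity_true
#> [1] 98.98305

rep <- run_sample(sam$reads, db, pipeline_config(), sample_id = "demo")
rep
#> <sample_report> demo - 1000 reads - status: unmutated 
#>   clonal V genes: IGHV2-1 
#>   IGHV2-1.1: unmutated (identity 98.98%)
```

Reading the output: the coverage peak identified `IGHV2-1` as the
clonotypic V gene (the simulated truth); the polished consensus of its 1000
supporting reads matched the germline at 98.98% — within 0.01 points of the
simulated truth, despite every individual read carrying ~10% errors — and
98.98 &ge; 98.00 classifies the clone unmutated. With `outdir=` set,
`run_sample()` writes `depth.tsv`, `clonal_calls.tsv`, `consensus.fasta`,
`annotation.tsv` (AIRR-style columns), `shm.tsv` and `sample_report.tsv`,
plus an optional clonality plot and SAM export.

A command-line front end is installed as `exec/nanoclone` with subcommands
`simulate`, `run`, `batch` and `fixture-db` (exit codes: 0 success, 2
no-result, 1 crash).

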