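---
title: "Methods: clonality and IGHV mutational status from nanopore IGH amplicons"
author: "nanoclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality and IGHV mutational status from nanopore IGH amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoclone)
```

## The problem

In chronic lymphocytic leukemia (CLL) the somatic hypermutation (SHM) load of
the clonotypic immunoglobulin heavy-chain variable (IGHV) gene is a standard
prognostic marker: a rearranged V gene with **at least 98% identity** to its
closest germline gene is called *unmutated* (worse prognosis), below 98%
*mutated*. Identities in the band **[97.00, 98.00)** are flagged *borderline*
because the call is least reliable there, though they are still classed
mutated.

Nanopore sequencing of IGH FR1&rarr;J amplicons (roughly 0.5 kb) makes this
assay cheap and fast, but the raw per-read error rate (~10%) is far above the
2% signal being measured. The package therefore works at the level of
*clones*, not reads:

1. **Clonality.** Reads are locally aligned to a germline locus; per-V-gene
   mean coverage is computed; V genes at or above a coverage threshold
   (default **500X**) are called clonotypic.
2. **Consensus.** The reads supporting each clonal V gene are partitioned by
   pairwise edit distance under an escalating tolerance schedule, filtered by
   supporting-read count, assembled by star alignment to a medoid read, and
   polished by iterative realign-and-recall until byte-stable.
3. **Annotation.** Each polished consensus is assigned germline V, D and J
   genes by local alignment, its V-region germline identity is computed, its
   productivity (reading frame V&rarr;J, no in-frame stop) is determined, and
   the 2% rule is applied.

A ground-truthed simulator generates clonal amplicon read sets with known
V/D/J genes, SHM load, productivity and read-of-origin, so every stage can be
validated without patient material.

## The germline reference

`load_germline_db()` reads a FASTA contig plus a BED of gene intervals (name
field `GENE|SEGMENT`, score column carrying the reading-frame offset for V
and J genes). The same database serves both read mapping and V/D/J
assignment. This is a deliberate unification: pipelines that map against a
genome but annotate against a separately curated germline directory can
report inconsistent gene labels between the two stages purely because the
references differ; a single database removes that failure mode by
construction.

Conventions: coordinates are 0-based half-open (BED) everywhere internally
and 1-based only in human-readable output; all genes are on the + strand and
minus-strand BED records are rejected at load (strand handling would double
the surface of every downstream contract for no benefit in an amplicon
assay); allele-level (`*01`) resolution is out of scope.

`build_fixture_db()` generates a synthetic stand-in for the IGH locus: 295-nt
V genes arranged in families of two, a 50-nt J gene (frame offset 2) and 2+
short D genes (10-30 nt) on one ~30 kb contig. Family members differ at 2 x 15
interior positions (~90% identity) and families derive from a common ancestor
via 25 further substitutions (~74% identity across families). These bands
were chosen to reproduce the practical difficulty of the real locus — reads
disperse between same-family genes during alignment — while keeping distinct
genes unambiguous at the consensus level. V genes are kept stop-free in
frame 0 and the J gene in its own frame so productive rearrangements exist.
The packaged copy under `inst/extdata/` is the seed-42, 8-V instance
(regenerated by `data-raw/make_locus_fixture.R`); it is synthetic and is not
derived from any real germline repertoire.

## The simulator

`recombine()` builds an amplicon from the V frame start (emulating an FR1
amplicon): trimmed V + N1 + doubly-trimmed D + N2 + trimmed J, recording the
junction layout. `apply_shm()` mutates the V span with per-base Bernoulli
substitutions (never to the same base); `simulate_reads()` applies i.i.d.
per-base substitution/insertion/deletion errors (defaults 3%/3%/4%, the ~10%
total of the targeted flowcell generation) and emits about half of the reads
reverse-complemented. `simulate_sample()` apportions reads to clones by
largest-remainder rounding of their abundances and writes FASTQ plus truth
tables.

Deliberate simplifications, and what they imply for the tests: SHM is
substitution-only and uniform (real SHM has hotspots and occasional indels);
read errors are context-free (no homopolymer bias); base qualities are
constant placeholders (quality filtering is assumed to happen upstream at
basecalling, and the pipeline never reads them); truncated reads and PCR
chimeras are not simulated. Passing the validation suites therefore
demonstrates correctness of the *algorithms* under calibrated noise, not
robustness to every artefact of real flowcells.

One extension exists for validation design: `clone_spec(shm_exact = TRUE)`
places exactly `round(rate x span)` mutations instead of a Bernoulli draw.
The classification suite uses it because a 3%-rate Bernoulli clone has a
non-trivial chance of drawing fewer than 2% mutations, in which case its
*true* status is unmutated and a "rate 3% must classify mutated" check would
be probing the random number generator, not the classifier. Validation
panels are built from samples whose status is known by construction; the
exact-count mode mirrors that.

## Stage 1: clonality

Alignment uses full Smith-Waterman dynamic programming with affine gaps
(match +2, mismatch -4, gap open -4, gap extend -2; a gap of length L costs
open + L x extend), implemented in C++ and verified against a brute-force R
implementation and against `Biostrings::pairwiseAlignment`. These penalties
are steep enough that, at ~10% read error, local alignments stop at gene
boundaries instead of bleeding into the junction. A score floor of 40 (a
20-bp perfect match) discards unalignable reads. Because aligning every read
against every gene is wasteful, an 11-mer pre-screen picks the read strand
and shortlists the top 3 candidate V genes; the full aligner then decides
among candidates. Only the single best alignment per read is kept —
secondary alignments would double-count coverage.

Depth of a V gene is *mean per-base coverage over its interval* (total
aligned bases inside the interval / gene length); the overlapping-read count
is reported but not used for calling, because mean coverage is robust to
partial overlaps. The clonal call is `depth >= threshold` with an inclusive
boundary (a gene at exactly 500X passes). Read selection for consensus
building takes every read whose alignment overlaps the gene interval by at
least 50% of the gene length, reverse-complementing minus-strand reads into
pipeline orientation.

D and J genes are never called from coverage: the J is shared by all clones
of a sample and D genes are too short to attract reliable alignments; their
identification is deferred entirely to the annotation stage.

## Stage 2: consensus

The tolerance schedule (default 0.05, 0.10, 0.15, 0.20 per-base divergence)
reproduces an "escalate until it assembles" strategy: at each tolerance,
reads are partitioned by greedy centroid clustering (a read joins the
nearest partition whose centroid is within 2 x tolerance normalized edit
distance, else seeds a new partition; reads are processed longest-first with
ties by read id, so the procedure is deterministic without any seed).
Partitions below `min_support` (default 20 reads) are dropped; escalation
stops at the first tolerance producing at least one surviving partition.
Two reads of the same clone at 10% error sit ~0.17-0.19 apart, so the 0.05
level fails and 0.10 succeeds — by design, genuinely cleaner data assembles
at a stricter tolerance.

Each surviving partition is assembled by **star alignment to a medoid
read** (the medoid is estimated from the first 30 reads in processing
order): all reads are locally aligned to the medoid and every column is
called by majority (ties go to the alphabetically earliest base; a gap must
strictly beat every base to delete a column; an insertion column is emitted
when more than half of the junction-covering reads insert there, taking the
most frequent inserted string). This star-alignment/majority design is the
package's deliberate replacement for an overlap-layout assembler plus a
signal-level polisher: it is desk-scale, exactly reproducible, and auditable
column by column. Partial-order alignment would be the natural upgrade path.

Two boundary rules deal with the known weakness of local alignment at
sequence extremities, where deletions can never be voted: scaffold end
columns with coverage below 25% of the median are trimmed, and conversely
the consensus is extended beyond its ends one base at a time wherever more
than half of the boundary-covering reads carry the same soft-clipped base at
that offset. Finally, partitions whose denoised drafts land within a 0.03
normalized edit distance of each other are collapsed into one record (read
stragglers of a single clone otherwise surface as spurious subclones);
genuinely distinct rearrangements differ by far more than 3% after
denoising, while subclones below that divergence are declared out of
resolution.

Polishing (`polish()`) re-aligns the supporting reads to the current
consensus and re-calls all columns, iterating until the sequence is
byte-identical between iterations or `max_polish_iter` (default 5) is
reached. Every failure is a record with a machine-readable reason
(`cluster_below_min_support`, `no_partition_reached_min_support`), so a
sample with a clonal coverage peak but no consensus is an auditable outcome,
never a silent drop.

## Stage 3: annotation

`assign_v()` aligns every germline V gene to the consensus; the highest
score wins, with ties broken by higher identity and then gene name. The
winning alignment defines the V-region span. One correction is applied
after the winner is chosen: local alignment drops terminal segments whose
mismatch density exceeds 1/3, so a clone with SHM mutations in its last few
V bases would have them silently trimmed and its identity inflated by up to
~1 point. The winning alignment is therefore extended gap-free toward the
germline boundaries, by at most 5 bases per end — the scale of typical
exonucleolytic V trimming, so that for 3'-trimmed rearrangements the
correction cannot reach far into the junction. `assign_dj()` finds the best J
downstream of that span, then searches D between the V end and the J start;
a D is called only when at least 10 nt of a D gene align at 80% identity or
better — D segments are short and heavily trimmed, so anything looser
produces junk calls, and the D call never affects SHM status. The junction
is the consensus substring from the last V-aligned base through the first
J-aligned base, inclusive.

V-region identity is `100 x matches / (matches + mismatches + inserted +
deleted bases)`, reported to two decimals. Counting each indel base in the
denominator is a choice (`identity_mode = "subs_only"` gives the
alternative); on a polished consensus indels are rare, so the two conventions
differ only in pathological cases.

Productivity: the codon phase established by the V alignment is propagated
colinearly to the J start and compared with the J gene's own frame offset
(`frame_ok`), and the consensus is scanned for in-frame stop codons from the
V frame start through the end of the aligned J (`stop_free`). Indels inside
the V alignment make the propagation approximate; at consensus accuracy this
is immaterial. `productive = frame_ok AND stop_free`.

`classify_shm()` is a pure function: identity >= 98.00 &rarr; unmutated;
< 98.00 &rarr; mutated; borderline flag on [97.00, 98.00). Its boundary
behaviour is pinned by unit tests at 97.00, 97.80, 97.99 and 98.00.

## Sample-level reporting

A sample's status aggregates its *productive* clones only: one status if
they agree, `discordant-multiclonal` if they disagree (the package never
silently picks a clone — discordance is flagged for human review, which is
how such conflicts are resolved in practice, by orthogonal PCR),
`no clonal rearrangement` if no gene reaches the coverage threshold, and
`no result` if no productive consensus could be annotated. Batch runs
tolerate per-sample failures and tabulate them. The analysis path contains
no randomness, so rerunning a sample byte-reproduces every report file.

## Problem sizes used in the validation suites

The packaged suites simulate at the conditions the pipeline targets:
1000 reads per clone and ~10% read error for the identity-recovery grid
(SHM rates 0/1/2/3/5%, ten replicates per rate) and for the classification,
threshold and dual-rearrangement suites; 500 reads for the
consensus-exactness suite (20 replicates); 200 random instances for the
aligner-vs-brute-force oracle. The identity-recovery suite requires
reported and true identity to agree within ±0.5 percentage points, with the
2% classification threshold and the [97, 98) borderline band fixed
throughout.

## Known limitations

* SHM hotspots, SHM indels and homopolymer-biased sequencing errors are not
  modelled; real-data identity error may exceed the simulated ±0.5 pp.
* Subclones closer than ~3% overall divergence collapse into one consensus.
* No allele-level germline resolution, CDR1/2 delineation, or stereotypic
  subset assignment.
* Minus-strand germline annotation is unsupported by design.
* The aligner is exact dynamic programming; for much larger loci (full
  chromosome mapping) a seed-and-extend mapper would be required.
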