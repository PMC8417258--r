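#' Alignment parameters
#'
#' Scoring for the local aligner used throughout: match +2, mismatch -4,
#' gap open -4, gap extend -2 (a gap of length L costs open + L x extend), a
#' minimum reportable score (`score_floor`), and the k-mer pre-screen used to
#' shortlist candidate genes and pick the read strand before running full
#' dynamic programming.
#'
#' The defaults are tuned for ~10%-error long reads: mismatch/gap penalties
#' steep enough that local alignments do not bleed across gene boundaries,
#' and a floor of 40 (equivalent to a 20-bp perfect match) to discard junk.
#'
#' @param match,mismatch,gap_open,gap_ext alignment scores (mismatch and gap
#'   parameters are negative).
#' @param score_floor minimum alignment score to report.
#' @param kmer k-mer size of the candidate pre-screen.
#' @param max_candidates number of top candidate genes given to the full
#'   aligner per read (`Inf` = all genes).
#' @return an `align_params` list.
#' @export
align_params <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                         gap_ext = -2L, score_floor = 40L, kmer = 11L,
                         max_candidates = 3L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_ext < 0,
            score_floor > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext),
                 score_floor = as.integer(score_floor),
                 kmer = as.integer(kmer), max_candidates = max_candidates),
            class = "align_params")
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic programming over query x reference. Coordinates in the result
#' are 0-based half-open; the CIGAR uses `= X I D` with `I` consuming query
#' and `D` consuming reference.
#'
#' @param query,ref DNA strings.
#' @param params an [align_params()].
#' @return list with `score`, `q_start`, `q_end`, `r_start`, `r_end`,
#'   `cigar`, edit-operation counts, and `identity`
#'   (matches / aligned columns, indel bases each counting one column).
#' @export
sw_align <- function(query, ref, params = align_params()) {
  a <- sw_align_cpp(query, ref, params$match, params$mismatch,
                    -params$gap_open, -params$gap_ext)
  ncol <- a$n_match + a$n_mismatch + a$n_ins + a$n_del
  a$identity <- if (ncol > 0) a$n_match / ncol else 0
  a
}

#' Align reads to the germline V genes of a locus
#'
#' Stage-1 mapping. Each read is strand-resolved and shortlisted against
#' candidate V genes by shared k-mers, then locally aligned to each candidate
#' with full Smith-Waterman; the single best alignment per read is kept
#' (ties: higher identity, then gene name). Reads whose best score is below
#' `score_floor` are dropped. Secondary alignments are never reported, so
#' depth is never double-counted.
#'
#' @param reads data.frame with `read_id` and `seq` (as from [read_fastq()]).
#' @param db a `germline_db`.
#' @param params an [align_params()].
#' @return data.frame of read alignments with contig coordinates (0-based
#'   half-open), strand, score, CIGAR, edit-operation counts, mapped query
#'   fraction and identity. Zero rows (with a warning) for an empty read set.
#' @export
align_reads <- function(reads, db, params = align_params()) {
  empty <- data.frame(
    read_id = character(), gene = character(), contig = character(),
    r_start = integer(), r_end = integer(), strand = character(),
    score = integer(), cigar = character(), q_start = integer(),
    q_end = integer(), q_len = integer(), n_match = integer(),
    n_mismatch = integer(), n_ins = integer(), n_del = integer(),
    mapped_frac = numeric(), identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0) {
    warning("empty read set: no alignments")
    return(empty)
  }
  vg <- db_genes(db, "V")
  if (nrow(vg) == 0) stop("germline database has no V genes")

  fwd <- reads$seq
  rev <- revcomp(fwd)
  hits_f <- kmer_hits_cpp(fwd, vg$sequence, params$kmer)
  hits_r <- kmer_hits_cpp(rev, vg$sequence, params$kmer)

  n <- nrow(reads)
  gi_v <- integer(n); strand_v <- character(n); hit <- logical(n)
  aln_v <- vector("list", n)
  for (i in seq_len(n)) {
    hf <- hits_f[i, ]; hr <- hits_r[i, ]
    strands <- if (sum(hf) > sum(hr)) "+" else if (sum(hr) > sum(hf)) "-" else c("+", "-")
    best <- NULL
    for (st in strands) {
      qseq <- if (st == "+") fwd[i] else rev[i]
      h <- if (st == "+") hf else hr
      cand <- if (max(h) == 0) seq_len(nrow(vg)) else {
        nc <- min(length(h), params$max_candidates)
        order(-h, vg$name)[seq_len(nc)]
      }
      for (ci in cand) {
        a <- sw_align(qseq, vg$sequence[ci], params)
        if (a$score < params$score_floor) next
        better <- is.null(best) ||
          a$score > best$a$score ||
          (a$score == best$a$score && a$identity > best$a$identity) ||
          (a$score == best$a$score && a$identity == best$a$identity &&
             vg$name[ci] < vg$name[best$gi])
        if (better) best <- list(a = a, gi = ci, strand = st)
      }
    }
    if (is.null(best)) next
    hit[i] <- TRUE
    gi_v[i] <- best$gi
    strand_v[i] <- best$strand
    aln_v[[i]] <- best$a
  }
  if (!any(hit)) return(empty)
  w <- which(hit)
  get_i <- function(fld) vapply(aln_v[w], `[[`, integer(1), fld)
  get_n <- function(fld) vapply(aln_v[w], `[[`, numeric(1), fld)
  qlen <- nchar(fwd[w])
  q_start <- get_i("q_start"); q_end <- get_i("q_end")
  data.frame(
    read_id = reads$read_id[w], gene = vg$name[gi_v[w]],
    contig = db$contig_id,
    r_start = vg$start[gi_v[w]] + get_i("r_start"),
    r_end = vg$start[gi_v[w]] + get_i("r_end"),
    strand = strand_v[w], score = get_i("score"),
    cigar = vapply(aln_v[w], `[[`, character(1), "cigar"),
    q_start = q_start, q_end = q_end, q_len = qlen,
    n_match = get_i("n_match"), n_mismatch = get_i("n_mismatch"),
    n_ins = get_i("n_ins"), n_del = get_i("n_del"),
    mapped_frac = (q_end - q_start) / qlen,
    identity = get_n("identity"), stringsAsFactors = FALSE)
}

#' Export read alignments as SAM
#'
#' Minimal single-reference SAM: one line per aligned read, CIGAR rebuilt
#' from the stored edit operations with soft clips for unaligned read ends;
#' minus-strand reads are written reverse-complemented with flag 16.
#'
#' @param alignments data.frame from [align_reads()].
#' @param reads the read data.frame the alignments came from.
#' @param db the `germline_db` aligned against.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", db$contig_id,
                       nchar(db$contig_seq))), con)
  seqs <- stats::setNames(reads$seq, reads$read_id)
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    seq <- seqs[[al$read_id]]
    if (al$strand == "-") seq <- revcomp(seq)
    lead <- al$q_start
    trail <- al$q_len - al$q_end
    cig <- gsub("([0-9]+)[=X]", "\\1M", al$cigar)
    # merge adjacent M runs
    while (grepl("([0-9]+)M([0-9]+)M", cig)) {
      m <- regmatches(cig, regexec("([0-9]+)M([0-9]+)M", cig))[[1]]
      cig <- sub("[0-9]+M[0-9]+M",
                 paste0(as.integer(m[2]) + as.integer(m[3]), "M"), cig)
    }
    if (lead > 0) cig <- paste0(lead, "S", cig)
    if (trail > 0) cig <- paste0(cig, trail, "S")
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       al$read_id, ifelse(al$strand == "-", 16L, 0L),
                       al$contig, al$r_start + 1L, cig, seq), con)
  }
  invisible(path)
}
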