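#' @title Germline gene database
#'
#' @description
#' The reference bundle for the pipeline: a synthetic mini-locus contig plus a
#' set of V/D/J germline genes located on it. It stands in for both the genome
#' reference used for read mapping and the germline directory used for V/D/J
#' assignment, deliberately unifying the two so that clonality calls and
#' annotation calls can never disagree because of reference differences.
#'
#' Coordinates are 0-based half-open (BED convention) everywhere internally;
#' 1-based coordinates appear only in human-readable reports. All genes are on
#' the + strand; minus-strand BED records are rejected at load.
#'
#' @name germline_db
NULL

new_germline_db <- function(contig_id, contig_seq, genes, version = "unversioned") {
  stopifnot(is.character(contig_id), is.character(contig_seq),
            is.data.frame(genes))
  needed <- c("name", "segment", "start", "end", "frame_offset", "family", "sequence")
  if (!all(needed %in% names(genes))) {
    stop("genes table must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(genes$name)) {
    stop("duplicate gene name in germline database: ",
         paste(unique(genes$name[duplicated(genes$name)]), collapse = ", "))
  }
  if (!all(genes$segment %in% c("V", "D", "J"))) {
    stop("gene segment must be one of V, D, J")
  }
  clen <- nchar(contig_seq)
  if (any(genes$start < 0) || any(genes$end > clen)) {
    stop("gene interval out of contig bounds (contig length ", clen, ")")
  }
  if (any(genes$end - genes$start != nchar(genes$sequence))) {
    stop("gene interval length does not match sequence length")
  }
  if (nrow(genes) > 0 && any(nchar(genes$sequence) == 0)) stop("empty gene sequence")
  # same-segment intervals must not overlap
  for (seg in c("V", "D", "J")) {
    g <- genes[genes$segment == seg, , drop = FALSE]
    if (nrow(g) > 1) {
      g <- g[order(g$start), ]
      if (any(g$start[-1] < g$end[-nrow(g)])) {
        stop("overlapping ", seg, " gene intervals")
      }
    }
  }
  # sequences must be re-locatable in the contig
  if (nrow(genes) > 0) {
    sub <- substring(contig_seq, genes$start + 1L, genes$end)
    bad <- sub != genes$sequence
    if (any(bad)) {
      stop("gene sequence does not match contig at its interval: ",
           paste(genes$name[bad], collapse = ", "))
    }
  }
  structure(
    list(contig_id = contig_id, contig_seq = contig_seq,
         genes = genes, version = version),
    class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  cat("<germline_db> version:", x$version, "\n")
  cat("  contig:", x$contig_id, sprintf("(%d bp)", nchar(x$contig_seq)), "\n")
  tab <- table(factor(x$genes$segment, levels = c("V", "D", "J")))
  cat(sprintf("  genes: %d V, %d D, %d J\n", tab["V"], tab["D"], tab["J"]))
  invisible(x)
}

#' Subset genes of a germline database by segment type
#'
#' @param db a `germline_db`.
#' @param segment "V", "D" or "J" (or NULL for all genes).
#' @return the genes data.frame, subset and ordered by name.
#' @export
db_genes <- function(db, segment = NULL) {
  g <- db$genes
  if (!is.null(segment)) g <- g[g$segment == segment, , drop = FALSE]
  g[order(g$name), , drop = FALSE]
}

#' Look up a single gene by name
#'
#' @param db a `germline_db`.
#' @param name gene identifier.
#' @return a one-row data.frame.
#' @export
db_gene <- function(db, name) {
  g <- db$genes[db$genes$name == name, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene name: ", name)
  g
}

#' Load a germline database from FASTA + BED
#'
#' The FASTA must contain the mini-locus contig named in the BED; the BED name
#' field carries `"GENE|SEGMENT"` and the BED score column carries the
#' reading-frame offset (0-2) for V and J genes (ignored for D). Gene
#' sequences are taken from the contig at the stated intervals; any per-gene
#' FASTA records present are checked against them.
#'
#' @param fasta_path FASTA with the contig (and optionally per-gene records).
#' @param bed_path BED6 file of gene intervals.
#' @param version database version string (logged on load).
#' @return a `germline_db`.
#' @export
load_germline_db <- function(fasta_path, bed_path, version = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("no sequences in FASTA: ", fasta_path)
  fa_names <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)

  bed_lines <- readLines(bed_path, warn = FALSE)
  if (all(!nzchar(trimws(bed_lines)))) {
    bed <- GenomicRanges::GRanges()
  } else {
    bed <- tryCatch(rtracklayer::import(bed_path, format = "BED"),
                    error = function(e) stop("failed to parse BED ", bed_path,
                                             ": ", conditionMessage(e)))
  }
  if (length(bed) == 0) {
    warning("empty BED: loading germline database with 0 genes")
    contig_id <- fa_names[1]
    db <- new_germline_db(contig_id, as.character(seqs[[1]]),
                          data.frame(name = character(), segment = character(),
                                     start = integer(), end = integer(),
                                     frame_offset = integer(), family = character(),
                                     sequence = character(),
                                     stringsAsFactors = FALSE),
                          version = version %||% "unversioned")
    message("loaded germline db version ", db$version, " (0 genes)")
    return(db)
  }

  contig_ids <- unique(as.character(GenomicRanges::seqnames(bed)))
  if (length(contig_ids) != 1) stop("BED must reference exactly one contig")
  contig_id <- contig_ids[1]
  if (!contig_id %in% fa_names) {
    stop("contig '", contig_id, "' named in BED is missing from FASTA")
  }
  contig_seq <- as.character(seqs[[match(contig_id, fa_names)]])

  strands <- as.character(BiocGenerics::strand(bed))
  if (any(strands == "-")) {
    stop("minus-strand germline genes are not supported")
  }
  labels <- bed$name
  parts <- strsplit(labels, "|", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("BED name field must be 'GENE|SEGMENT' (got: ",
         labels[which(lengths(parts) < 2)[1]], ")")
  }
  gname <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(gname)) {
    stop("duplicate gene name in BED: ",
         paste(unique(gname[duplicated(gname)]), collapse = ", "))
  }
  seg <- vapply(parts, `[`, character(1), 2L)
  score <- if (!is.null(bed$score)) as.integer(bed$score) else rep(0L, length(bed))
  start0 <- GenomicRanges::start(bed) - 1L
  end0 <- GenomicRanges::end(bed)
  if (any(start0 < 0) || any(end0 > nchar(contig_seq))) {
    stop("BED interval outside contig bounds")
  }
  genes <- data.frame(
    name = gname, segment = seg, start = start0, end = end0,
    frame_offset = ifelse(seg == "D", NA_integer_, score),
    family = sub("-.*$", "", gname),
    sequence = substring(contig_seq, start0 + 1L, end0),
    stringsAsFactors = FALSE)

  # cross-check optional per-gene FASTA records
  extra <- intersect(fa_names, genes$name)
  for (nm in extra) {
    fs <- as.character(seqs[[match(nm, fa_names)]])
    if (fs != genes$sequence[genes$name == nm]) {
      stop("per-gene FASTA record disagrees with contig for ", nm)
    }
  }

  db <- new_germline_db(contig_id, contig_seq, genes,
                        version = version %||% "unversioned")
  message("loaded germline db version ", db$version, " (",
          nrow(genes), " genes)")
  db
}

#' Write a germline database to FASTA + BED
#'
#' Inverse of [load_germline_db()]: the FASTA contains the contig followed by
#' one record per gene; the BED name field is `"GENE|SEGMENT"` and the score
#' column holds the frame offset.
#'
#' @param db a `germline_db`.
#' @param fasta_path,bed_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_germline_db <- function(db, fasta_path, bed_path) {
  ss <- Biostrings::DNAStringSet(c(db$contig_seq, db$genes$sequence))
  names(ss) <- c(db$contig_id, db$genes$name)
  Biostrings::writeXStringSet(ss, fasta_path)
  g <- db$genes
  gr <- GenomicRanges::GRanges(
    seqnames = db$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = "+",
    name = paste(g$name, g$segment, sep = "|"),
    score = ifelse(is.na(g$frame_offset), 0L, g$frame_offset))
  rtracklayer::export(gr, bed_path, format = "BED")
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Path to the packaged synthetic mini-locus fixture
#'
#' @param which "fasta" or "bed".
#' @return file path under the installed package.
#' @export
fixture_db_path <- function(which = c("fasta", "bed")) {
  which <- match.arg(which)
  fn <- c(fasta = "synthetic_ighlocus.fasta", bed = "synthetic_ighlocus.bed")[[which]]
  system.file("extdata", fn, package = "nanoclone", mustWork = TRUE)
}

# mutate `k` interior positions of a sequence, avoiding creation of stop
# codons in the frame anchored at 0-based offset `anchor`; positions sampled
# from `pool` (1-based), excluding `exclude`
mutate_positions <- function(seq, k, pool, anchor = 0L, exclude = integer()) {
  chars <- strsplit(seq, "")[[1]]
  pool <- setdiff(pool, exclude)
  pos <- sort(sample(pool, k))
  for (p in pos) {
    old <- chars[p]
    cands <- sample(setdiff(BASES, old))
    for (nb in cands) {
      trial <- chars
      trial[p] <- nb
      ci <- (p - 1L - anchor) %/% 3L
      cstart <- anchor + ci * 3L + 1L
      if (cstart < 1 || cstart + 2 > length(trial)) { chars <- trial; break }
      codon <- paste(trial[cstart:(cstart + 2L)], collapse = "")
      if (!codon %in% STOP_CODONS) { chars <- trial; break }
    }
  }
  list(seq = paste(chars, collapse = ""), positions = pos)
}

#' Build a deterministic synthetic germline database
#'
#' Generates a mini-locus emulating the salient structure of the IGH locus:
#' V genes of 295 nt organised in families of two (within-family identity
#' around 90%, across families around 74%, so that read dispersion between
#' similar genes of the same family is exercised), short D genes (10-30 nt)
#' and a 50-nt J gene, laid out on one ~30 kb contig with intergenic spacers.
#' V genes are stop-free in their reading frame (offset 0) and the J gene in
#' its own (offset 2), so that simulated rearrangements can be productive.
#'
#' @param n_v number of V genes (>= 2).
#' @param seed RNG seed; the result is byte-identical for a fixed seed.
#' @param n_d number of D genes (>= 2).
#' @param n_j number of J genes (>= 1).
#' @return a `germline_db`.
#' @export
build_fixture_db <- function(n_v = 8, seed = 1, n_d = 3, n_j = 1) {
  if (n_v < 2) stop("n_v must be >= 2")
  if (n_d < 2) stop("n_d must be >= 2")
  if (n_j < 1) stop("n_j must be >= 1")
  withr::with_seed(seed, {
    v_len <- 295L
    n_codons <- v_len %/% 3L  # 98 codons cover 294 nt; last base unconstrained
    root <- paste0(paste(sample(ALLOWED_CODONS, n_codons, replace = TRUE),
                         collapse = ""),
                   sample(BASES, 1))
    pool <- 7:(v_len - 6L)  # keep both ends intact for clean alignment anchoring

    n_fam <- ceiling(n_v / 2)
    v_seqs <- character(0); v_names <- character(0)
    for (f in seq_len(n_fam)) {
      fam_anc <- mutate_positions(root, 25L, pool)$seq
      m1 <- mutate_positions(fam_anc, 15L, pool)
      v_seqs <- c(v_seqs, m1$seq)
      v_names <- c(v_names, sprintf("IGHV%d-1", f))
      if (length(v_seqs) < n_v) {
        m2 <- mutate_positions(fam_anc, 15L, pool, exclude = m1$positions)
        v_seqs <- c(v_seqs, m2$seq)
        v_names <- c(v_names, sprintf("IGHV%d-2", f))
      }
      if (length(v_seqs) >= n_v) break
    }

    d_lens <- c(15L, sample(10:30, n_d - 1L, replace = TRUE))
    d_seqs <- vapply(d_lens, random_dna, character(1))
    d_names <- sprintf("IGHD%d-%d", seq_len(n_d), d_lens)

    j_seqs <- vapply(seq_len(n_j), function(i) {
      paste0(random_dna(2L),
             paste(sample(ALLOWED_CODONS, 16L, replace = TRUE), collapse = ""))
    }, character(1))
    j_names <- sprintf("IGHJ%d", seq_len(n_j))

    all_names <- c(v_names, d_names, j_names)
    all_seqs <- c(v_seqs, d_seqs, j_seqs)
    all_segs <- c(rep("V", length(v_seqs)), rep("D", n_d), rep("J", n_j))
    all_frames <- c(rep(0L, length(v_seqs)), rep(NA_integer_, n_d), rep(2L, n_j))

    spacer_len <- 1500L
    pieces <- character(0)
    starts <- integer(length(all_seqs)); ends <- integer(length(all_seqs))
    at <- 0L
    for (i in seq_along(all_seqs)) {
      sp <- random_dna(spacer_len)
      pieces <- c(pieces, sp, all_seqs[i])
      at <- at + spacer_len
      starts[i] <- at
      at <- at + nchar(all_seqs[i])
      ends[i] <- at
    }
    if (at < 30000L) pieces <- c(pieces, random_dna(30000L - at))
    contig <- paste(pieces, collapse = "")

    genes <- data.frame(
      name = all_names, segment = all_segs,
      start = starts, end = ends,
      frame_offset = all_frames,
      family = sub("-.*$", "", all_names),
      sequence = all_seqs, stringsAsFactors = FALSE)

    new_germline_db("IGH_minilocus", contig, genes,
                    version = sprintf("fixture-nv%d-seed%d", n_v, seed))
  })
}
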