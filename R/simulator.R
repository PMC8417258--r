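#' @title Ground-truthed IGH amplicon read simulator
#'
#' @description
#' Emulates the input of the pipeline: clonal FR1->J amplicon read sets of
#' roughly 0.5 kb, produced by VDJ recombination with exonuclease trimming and
#' untemplated N-additions, somatic hypermutation of the V region, and
#' nanopore-style per-base substitution/insertion/deletion read errors.
#' Every sample comes with a truth table (clone sequences, true V/D/J genes,
#' true V-region identity, productivity, and a read-to-clone map) so pipeline
#' output can be scored exactly.
#'
#' SHM is substitution-only and uniform over the V region; read errors are
#' i.i.d. and context-free (no homopolymer awareness); base qualities are
#' constant placeholders. These are deliberate simplifications: they are
#' sufficient to exercise coverage-based clonality calling, consensus
#' polishing, and the 2% identity rule.
#'
#' @name simulator
NULL

#' Specify one clone of a simulated sample
#'
#' @param v_name,d_name,j_name germline gene names (must exist in the db).
#' @param shm_rate per-base substitution probability applied to the V region
#'   (0 to 0.2).
#' @param v_trim,d_trim_left,d_trim_right,j_trim non-negative exonuclease
#'   trimming lengths.
#' @param n1,n2 untemplated junction insertions (DNA strings); `NULL` means
#'   "draw a random 0-6 nt insertion" at recombination time.
#' @param shm_exact if TRUE the clone carries exactly
#'   `round(shm_rate * span)` mutations at random positions instead of a
#'   Bernoulli draw per base; used for validation clones whose true
#'   mutational status must be known by construction.
#' @param abundance fraction of the sample's reads from this clone.
#' @param force_unproductive if TRUE, the junction is frame-shifted until the
#'   rearrangement is unproductive.
#' @return a `clone_spec` list.
#' @export
clone_spec <- function(v_name, d_name, j_name, shm_rate = 0,
                       v_trim = 0L, d_trim_left = 0L, d_trim_right = 0L,
                       j_trim = 0L, n1 = "", n2 = "", shm_exact = FALSE,
                       abundance = 1, force_unproductive = FALSE) {
  if (shm_rate < 0 || shm_rate > 0.2) stop("shm_rate must be in [0, 0.2]")
  if (any(c(v_trim, d_trim_left, d_trim_right, j_trim) < 0)) {
    stop("trim lengths must be non-negative")
  }
  if (abundance <= 0 || abundance > 1) stop("abundance must be in (0, 1]")
  for (s in c(n1, n2)) {
    if (!is.null(s) && nchar(s) > 0 && !grepl("^[ACGT]+$", s)) {
      stop("N-addition strings must be over ACGT")
    }
  }
  structure(list(v_name = v_name, d_name = d_name, j_name = j_name,
                 shm_rate = shm_rate, v_trim = as.integer(v_trim),
                 d_trim_left = as.integer(d_trim_left),
                 d_trim_right = as.integer(d_trim_right),
                 j_trim = as.integer(j_trim), n1 = n1, n2 = n2,
                 shm_exact = isTRUE(shm_exact), abundance = abundance,
                 force_unproductive = isTRUE(force_unproductive)),
            class = "clone_spec")
}

#' Nanopore-style read error model
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in
#'   \[0, 0.15\], summing to < 0.3. The default (3% / 3% / 4%) gives the
#'   roughly 10% total error typical of the flowcell generation the pipeline
#'   targets.
#' @return an `error_model` list.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.03, del_rate = 0.04) {
  r <- c(sub_rate, ins_rate, del_rate)
  if (any(r < 0) || any(r > 0.15)) stop("error rates must be in [0, 0.15]")
  if (sum(r) >= 0.3) stop("total error rate must be < 0.3")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

# --- internals operating on the current RNG stream ---------------------------

.recombine_rng <- function(db, spec) {
  vg <- db_gene(db, spec$v_name)
  dg <- db_gene(db, spec$d_name)
  jg <- db_gene(db, spec$j_name)
  if (vg$segment != "V" || dg$segment != "D" || jg$segment != "J") {
    stop("clone_spec genes must be a V, a D and a J gene")
  }
  f_v <- vg$frame_offset
  f_j <- jg$frame_offset
  v_full <- substring(vg$sequence, f_v + 1L)     # amplicon starts at V frame start
  if (spec$v_trim >= nchar(v_full)) stop("v_trim >= usable V length")
  v_part <- substring(v_full, 1L, nchar(v_full) - spec$v_trim)
  if (spec$d_trim_left + spec$d_trim_right >= nchar(dg$sequence)) {
    stop("D trims remove the whole D gene")
  }
  d_part <- substring(dg$sequence, spec$d_trim_left + 1L,
                      nchar(dg$sequence) - spec$d_trim_right)
  if (spec$j_trim >= nchar(jg$sequence)) stop("j_trim >= J length")
  j_part <- substring(jg$sequence, spec$j_trim + 1L)

  n1 <- spec$n1 %||% random_dna(sample(0:6, 1))
  n2 <- spec$n2 %||% random_dna(sample(0:6, 1))

  build <- function(n1) {
    seq <- paste0(v_part, n1, d_part, n2, j_part)
    j_start0 <- nchar(v_part) + nchar(n1) + nchar(d_part) + nchar(n2)
    frame_ok <- (j_start0 %% 3L) == ((spec$j_trim - f_j) %% 3L)
    stop_free <- !has_inframe_stop(seq, 0L, nchar(seq))
    list(seq = seq, j_start0 = j_start0, n1 = n1,
         frame_ok = frame_ok, stop_free = stop_free,
         productive = frame_ok && stop_free)
  }
  b <- build(n1)
  if (spec$force_unproductive && b$productive) {
    b <- build(paste0(n1, "A"))  # frameshift breaks the reading frame
    stopifnot(!b$productive)
  }
  list(seq = b$seq,
       meta = list(v_name = spec$v_name, d_name = spec$d_name,
                   j_name = spec$j_name,
                   v_span = c(0L, nchar(v_part)),
                   n1 = b$n1, n2 = n2, d_part = d_part,
                   j_start0 = b$j_start0, j_trim = spec$j_trim,
                   f_j = f_j,
                   frame_ok = b$frame_ok, stop_free = b$stop_free,
                   productive = b$productive))
}

.apply_shm_rng <- function(sequence, v_span, shm_rate, exact = FALSE) {
  span_len <- v_span[2] - v_span[1]
  rel <- if (exact) {
    sort(sample.int(span_len, round(shm_rate * span_len)))
  } else {
    which(runif(span_len) < shm_rate)
  }
  chars <- strsplit(sequence, "")[[1]]
  pos0 <- integer(0)
  for (r in rel) {
    p <- v_span[1] + r          # 1-based index into sequence
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
    pos0 <- c(pos0, p - 1L)
  }
  list(seq = paste(chars, collapse = ""), positions = pos0)
}

# substitution lookup: row = original base index, columns = the 3 alternatives
SUB_ALTS <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))

.simulate_read_rng <- function(tchars, tidx, em) {
  L <- length(tchars)
  u_del <- runif(L); u_sub <- runif(L); u_ins <- runif(L)
  kept <- u_del >= em$del_rate
  ch <- tchars[kept]
  subm <- which(u_sub[kept] < em$sub_rate)
  if (length(subm)) {
    ch[subm] <- SUB_ALTS[cbind(tidx[kept][subm],
                               sample.int(3L, length(subm), replace = TRUE))]
  }
  insm <- u_ins[kept] < em$ins_rate
  if (any(insm)) {
    ch[insm] <- paste0(ch[insm], sample(BASES, sum(insm), replace = TRUE))
  }
  paste(ch, collapse = "")
}

.simulate_reads_rng <- function(template, n_reads, em, id_prefix = "read") {
  tchars <- strsplit(template, "")[[1]]
  tidx <- match(tchars, BASES)
  seqs <- character(n_reads)
  is_rc <- logical(n_reads)
  for (i in seq_len(n_reads)) {
    seqs[i] <- .simulate_read_rng(tchars, tidx, em)
    is_rc[i] <- runif(1) < 0.5
  }
  if (any(is_rc)) seqs[is_rc] <- revcomp(seqs[is_rc])
  data.frame(read_id = sprintf("%s_%06d", id_prefix, seq_len(n_reads)),
             seq = seqs, revcomp = is_rc, stringsAsFactors = FALSE)
}

#' Construct a frame-consistent, productive clone specification
#'
#' Chooses an N1 length that keeps the V reading frame congruent into J
#' (with `j_trim = 2`) and tries a fixed pool of N1 strings until the
#' rearranged junction is free of in-frame stop codons, so the resulting
#' clone is productive by construction (unless `force_unproductive`).
#'
#' @param db a `germline_db`.
#' @param v_name,d_name,j_name germline gene names.
#' @param shm_rate,shm_exact,abundance,force_unproductive passed to
#'   [clone_spec()].
#' @return a `clone_spec`.
#' @export
productive_clone_spec <- function(db, v_name, d_name, j_name, shm_rate = 0,
                                  shm_exact = FALSE, abundance = 1,
                                  force_unproductive = FALSE) {
  vg <- db_gene(db, v_name); dg <- db_gene(db, d_name)
  jg <- db_gene(db, j_name)
  j_trim <- 2L
  v_part <- nchar(vg$sequence) - vg$frame_offset
  pre <- v_part + nchar(dg$sequence) + 2L           # + n2 ("TT")
  needed <- (j_trim - jg$frame_offset) %% 3L
  n1_len <- ((needed - pre) %% 3L) + 3L
  for (cand in c("ACGAC", "ACCGT", "GCACA", "CAGGC", "GGACC", "CTCAG",
                 "TCCTG", "CACCA")) {
    sp <- clone_spec(v_name, d_name, j_name, shm_rate = shm_rate,
                     j_trim = j_trim, n1 = substr(cand, 1, n1_len), n2 = "TT",
                     shm_exact = shm_exact, abundance = abundance,
                     force_unproductive = force_unproductive)
    if (force_unproductive || recombine(db, sp, 1)$meta$productive) return(sp)
  }
  stop("no productive junction found for ", v_name, "/", d_name, "/", j_name)
}

# --- public, seeded operations ----------------------------------------------

#' Recombine a V, D and J gene into a clonal amplicon sequence
#'
#' The amplicon runs from the V gene's reading-frame start (emulating an FR1
#' amplicon) through trimmed V, the N1 insertion, the doubly trimmed D, the N2
#' insertion, and the trimmed J. Junction layout and a productivity call
#' (frame congruence from V into J plus an in-frame stop scan) are returned as
#' metadata.
#'
#' @param db a `germline_db`.
#' @param spec a [clone_spec()].
#' @param rng_seed seed; only consumed when `n1`/`n2` are `NULL` (random
#'   N-additions).
#' @return list with `seq` and `meta` (junction layout, productivity).
#' @export
recombine <- function(db, spec, rng_seed = 1L) {
  withr::with_seed(rng_seed, .recombine_rng(db, spec))
}

#' Apply somatic hypermutation to the V region of a sequence
#'
#' Per-base Bernoulli substitutions (never to the same base), confined to
#' `v_span`; the number of mutations is Binomial(span length, `shm_rate`).
#'
#' @param sequence DNA string.
#' @param v_span 0-based half-open span of the V region within `sequence`.
#' @param shm_rate per-base substitution probability.
#' @param rng_seed seed.
#' @param exact if TRUE, place exactly `round(shm_rate * span)` mutations.
#' @return list with `seq` (mutated) and `positions` (0-based mutated sites).
#' @export
apply_shm <- function(sequence, v_span, shm_rate, rng_seed = 1L,
                      exact = FALSE) {
  if (v_span[1] < 0 || v_span[2] > nchar(sequence) || v_span[1] > v_span[2]) {
    stop("v_span outside sequence")
  }
  withr::with_seed(rng_seed,
                   .apply_shm_rng(sequence, v_span, shm_rate, exact = exact))
}

#' Simulate noisy reads from a template
#'
#' Each read is the template passed through i.i.d. per-base substitution,
#' insertion and deletion; about half the reads are emitted
#' reverse-complemented (recorded in the `revcomp` column). Qualities are
#' placeholders, written as a constant character when exported to FASTQ.
#'
#' @param template DNA string.
#' @param n_reads number of reads (>= 1).
#' @param em an [error_model()].
#' @param rng_seed seed.
#' @param id_prefix prefix for read identifiers.
#' @return data.frame with `read_id`, `seq`, `revcomp`.
#' @export
simulate_reads <- function(template, n_reads, em = error_model(),
                           rng_seed = 1L, id_prefix = "read") {
  if (n_reads < 1) stop("n_reads must be >= 1")
  withr::with_seed(rng_seed,
                   .simulate_reads_rng(template, n_reads, em, id_prefix))
}

#' Simulate a complete clonal amplicon sample with ground truth
#'
#' Per-clone read counts are the largest-remainder rounding of
#' `abundance * total_reads`. The truth tables record, per clone, the
#' post-SHM template, the true V/D/J genes, the true V-region identity
#' (100 x (1 - mutated fraction of the V span)), the productivity call, and a
#' read-to-clone map.
#'
#' @param db a `germline_db`.
#' @param clone_specs list of [clone_spec()]; abundances must sum to 1.
#' @param total_reads total reads across clones.
#' @param em an [error_model()].
#' @param rng_seed seed; the whole sample is byte-reproducible per seed.
#' @param fastq_path if non-NULL, reads are written there as FASTQ.
#' @param truth_prefix if non-NULL, truth tables are written to
#'   `<prefix>_clones.tsv` and `<prefix>_readmap.tsv`.
#' @return list with `reads` (data.frame), `clones` (truth table),
#'   `read_map`, and the paths written (or NULL).
#' @export
simulate_sample <- function(db, clone_specs, total_reads, em = error_model(),
                            rng_seed = 1L, fastq_path = NULL,
                            truth_prefix = NULL) {
  if (inherits(clone_specs, "clone_spec")) clone_specs <- list(clone_specs)
  ab <- vapply(clone_specs, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-9) {
    stop("clone abundances must sum to 1 (got ", sum(ab), ")")
  }
  base <- floor(ab * total_reads)
  rem <- total_reads - sum(base)
  if (rem > 0) {
    frac <- ab * total_reads - base
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  counts <- as.integer(base)

  withr::with_seed(rng_seed, {
    all_reads <- list(); clone_rows <- list(); map_rows <- list()
    for (i in seq_along(clone_specs)) {
      spec <- clone_specs[[i]]
      cid <- sprintf("clone%02d", i)
      rr <- .recombine_rng(db, spec)
      mut <- .apply_shm_rng(rr$seq, rr$meta$v_span, spec$shm_rate,
                            exact = isTRUE(spec$shm_exact))
      template <- mut$seq
      # productivity is a property of the clone's actual (post-SHM) sequence
      stop_free <- !has_inframe_stop(template, 0L, nchar(template))
      productive <- rr$meta$frame_ok && stop_free
      v_len <- rr$meta$v_span[2] - rr$meta$v_span[1]
      n_mut <- length(mut$positions)
      reads <- if (counts[i] > 0) {
        .simulate_reads_rng(template, counts[i], em,
                            id_prefix = paste0(cid, "_r"))
      } else {
        data.frame(read_id = character(), seq = character(),
                   revcomp = logical(), stringsAsFactors = FALSE)
      }
      all_reads[[i]] <- reads
      clone_rows[[i]] <- data.frame(
        clone_id = cid, v_name = spec$v_name, d_name = spec$d_name,
        j_name = spec$j_name, shm_rate = spec$shm_rate,
        n_mut = n_mut, v_len = v_len,
        v_identity_true = 100 * (1 - n_mut / v_len),
        frame_ok = rr$meta$frame_ok, stop_free = stop_free,
        productive = productive, n_reads = counts[i],
        abundance = spec$abundance, sequence = template,
        mut_positions = paste(mut$positions, collapse = ","),
        stringsAsFactors = FALSE)
      if (nrow(reads) > 0) {
        map_rows[[i]] <- data.frame(read_id = reads$read_id, clone_id = cid,
                                    stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, all_reads)
    clones <- do.call(rbind, clone_rows)
    read_map <- do.call(rbind, map_rows)

    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    truth_paths <- NULL
    if (!is.null(truth_prefix)) {
      cp <- paste0(truth_prefix, "_clones.tsv")
      rp <- paste0(truth_prefix, "_readmap.tsv")
      write.table(clones, cp, sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(read_map, rp, sep = "\t", quote = FALSE, row.names = FALSE)
      truth_paths <- c(clones = cp, read_map = rp)
    }
    list(reads = reads, clones = clones, read_map = read_map,
         fastq_path = fastq_path, truth_paths = truth_paths)
  })
}
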