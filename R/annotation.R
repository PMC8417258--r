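#' @title Local germline V/D/J annotation and SHM classification
#'
#' @description
#' Stage 3 of the pipeline, a local stand-in for a germline-directory query
#' service: each polished consensus is aligned against every germline V gene
#' (best score wins; ties by identity then name), J is assigned downstream of
#' the V span, D is searched in the junction window and only called when at
#' least 10 nt of a D gene align at >= 80% identity, productivity is the
#' conjunction of reading-frame congruence from V into J and absence of
#' in-frame stop codons, and mutational status follows the 2% rule:
#' V-region germline identity >= 98.00% is unmutated, below is mutated, with
#' a borderline flag on \[97.00, 98.00).
#'
#' The identity denominator includes indel bases (each inserted or deleted
#' base counts one aligned column); the substitutions-only alternative is
#' available via `identity_mode`.
#'
#' @name annotation
NULL

#' Assign the closest germline V gene to a consensus
#'
#' @param consensus consensus DNA string.
#' @param db a `germline_db`.
#' @param params an [align_params()].
#' @param end_extend after the winning gene is chosen, its local alignment
#'   is extended gap-free toward the germline boundaries by up to this many
#'   bases per end (where the consensus has flanking sequence). Local
#'   alignment trims extremities whose mismatch density exceeds 1/3, which
#'   would silently drop terminal SHM mutations and inflate identity; the
#'   cap keeps the correction from reaching far into the junction when the
#'   V gene was 3'-trimmed during recombination.
#' @return list with `v_call` (NA if best score is below the floor), the
#'   winning alignment (`v_start`/`v_end` = V-region span on the consensus,
#'   0-based half-open; `g_start`/`g_end` = span on the germline gene),
#'   `score`, edit-operation counts and unrounded `identity`.
#' @export
assign_v <- function(consensus, db, params = align_params(),
                     end_extend = 5L) {
  vg <- db_genes(db, "V")
  best <- NULL
  for (i in seq_len(nrow(vg))) {
    a <- sw_align(vg$sequence[i], consensus, params)
    if (a$score < params$score_floor) next
    better <- is.null(best) ||
      a$score > best$score ||
      (a$score == best$score && a$identity > best$identity) ||
      (a$score == best$score && a$identity == best$identity &&
         vg$name[i] < best$v_call)
    if (better) {
      best <- list(v_call = vg$name[i], score = a$score,
                   identity = a$identity,
                   v_start = a$r_start, v_end = a$r_end,
                   g_start = a$q_start, g_end = a$q_end,
                   cigar = a$cigar, n_match = a$n_match,
                   n_mismatch = a$n_mismatch, n_ins = a$n_ins,
                   n_del = a$n_del,
                   frame_offset = vg$frame_offset[i])
    }
  }
  if (is.null(best)) {
    return(list(v_call = NA_character_, score = 0, identity = NA_real_))
  }
  # gap-free end extension of the winning alignment (does not affect which
  # gene won; the score reported stays the SW optimum)
  gseq <- vg$sequence[vg$name == best$v_call]
  clen <- nchar(consensus); glen <- nchar(gseq)
  k5 <- min(best$g_start, best$v_start, end_extend)
  if (k5 > 0) {
    gg <- substring(gseq, best$g_start - k5 + 1, best$g_start)
    cc <- substring(consensus, best$v_start - k5 + 1, best$v_start)
    eq <- strsplit(gg, "")[[1]] == strsplit(cc, "")[[1]]
    best$n_match <- best$n_match + sum(eq)
    best$n_mismatch <- best$n_mismatch + sum(!eq)
    best$g_start <- best$g_start - k5
    best$v_start <- best$v_start - k5
  }
  k3 <- min(glen - best$g_end, clen - best$v_end, end_extend)
  if (k3 > 0) {
    gg <- substring(gseq, best$g_end + 1, best$g_end + k3)
    cc <- substring(consensus, best$v_end + 1, best$v_end + k3)
    eq <- strsplit(gg, "")[[1]] == strsplit(cc, "")[[1]]
    best$n_match <- best$n_match + sum(eq)
    best$n_mismatch <- best$n_mismatch + sum(!eq)
    best$g_end <- best$g_end + k3
    best$v_end <- best$v_end + k3
  }
  ncol <- best$n_match + best$n_mismatch + best$n_ins + best$n_del
  best$identity <- best$n_match / ncol
  best
}

#' Assign J and (optionally) D downstream of the V region
#'
#' J is the best local alignment of any germline J gene within the region
#' downstream of the V span. D is searched between the V end and the J
#' start, and called only when the alignment covers at least `d_min_len`
#' bases of a D gene at `d_min_identity` or better; the D call never affects
#' SHM status. The junction is the consensus substring from the last
#' V-aligned base through the first J-aligned base, inclusive.
#'
#' @param consensus consensus DNA string.
#' @param v result of [assign_v()] (with a non-NA `v_call`).
#' @param db a `germline_db`.
#' @param params an [align_params()].
#' @param d_min_len,d_min_identity D-call acceptance rule.
#' @param j_score_floor minimum J alignment score.
#' @return list with `j_call` (NA if no J above the floor), `d_call` (NA
#'   when absent), J span on the consensus, `j_gstart` (0-based start of the
#'   alignment on the germline J), `j_frame_offset` and `junction`.
#' @export
assign_dj <- function(consensus, v, db, params = align_params(),
                      d_min_len = 10L, d_min_identity = 0.8,
                      j_score_floor = 30L) {
  if (is.na(v$v_call)) stop("assign_dj requires an assigned V")
  down0 <- v$v_end  # 0-based offset of the downstream region
  downstream <- substring(consensus, down0 + 1L)
  jg <- db_genes(db, "J")
  bestj <- NULL
  for (i in seq_len(nrow(jg))) {
    a <- sw_align(jg$sequence[i], downstream, params)
    if (a$score < j_score_floor) next
    better <- is.null(bestj) ||
      a$score > bestj$score ||
      (a$score == bestj$score && a$identity > bestj$identity) ||
      (a$score == bestj$score && a$identity == bestj$identity &&
         jg$name[i] < bestj$j_call)
    if (better) {
      bestj <- list(j_call = jg$name[i], score = a$score,
                    identity = a$identity,
                    j_start = down0 + a$r_start, j_end = down0 + a$r_end,
                    j_gstart = a$q_start, j_gend = a$q_end,
                    j_frame_offset = jg$frame_offset[i])
    }
  }
  if (is.null(bestj)) {
    return(list(j_call = NA_character_, d_call = NA_character_,
                junction = NA_character_))
  }

  # D: searched between the V end and the J start
  dwin <- substring(consensus, down0 + 1L, bestj$j_start)
  bestd <- NULL
  if (nchar(dwin) >= d_min_len) {
    dg <- db_genes(db, "D")
    for (i in seq_len(nrow(dg))) {
      a <- sw_align(dg$sequence[i], dwin, params)
      dcov <- a$q_end - a$q_start
      if (dcov < d_min_len || a$identity < d_min_identity) next
      better <- is.null(bestd) || a$score > bestd$score ||
        (a$score == bestd$score && dg$name[i] < bestd$d_call)
      if (better) bestd <- list(d_call = dg$name[i], score = a$score,
                                identity = a$identity, d_cov = dcov)
    }
  }

  junction <- substring(consensus, v$v_end, bestj$j_start + 1L)
  c(bestj,
    list(d_call = if (is.null(bestd)) NA_character_ else bestd$d_call,
         d_identity = if (is.null(bestd)) NA_real_ else bestd$identity,
         junction = junction))
}

#' V-region germline identity percentage
#'
#' `100 * matches / (matches + mismatches + inserted + deleted bases)` over
#' the aligned V region, reported to two decimals. With
#' `identity_mode = "subs_only"` indel bases are excluded from the
#' denominator.
#'
#' @param v result of [assign_v()].
#' @param identity_mode "indel" (default) or "subs_only".
#' @return numeric identity percentage, rounded to 2 decimals.
#' @export
compute_identity <- function(v, identity_mode = c("indel", "subs_only")) {
  identity_mode <- match.arg(identity_mode)
  if (is.na(v$v_call)) return(NA_real_)
  den <- v$n_match + v$n_mismatch
  if (identity_mode == "indel") den <- den + v$n_ins + v$n_del
  round(100 * v$n_match / den, 2)
}

#' Productivity of a rearrangement
#'
#' `frame_ok` holds when the V reading frame, propagated through the junction
#' into J, is congruent with the J gene's own frame offset; `stop_free` holds
#' when no in-frame stop codon occurs from the V frame start through the end
#' of the aligned J. `productive = frame_ok AND stop_free`.
#'
#' @param consensus consensus DNA string.
#' @param v result of [assign_v()].
#' @param dj result of [assign_dj()] (with a non-NA `j_call`).
#' @return list with `frame_ok`, `stop_free`, `productive`.
#' @export
check_productivity <- function(consensus, v, dj) {
  if (is.na(v$v_call) || is.na(dj$j_call)) {
    stop("productivity requires assigned V and J")
  }
  f_v <- v$frame_offset
  f_j <- dj$j_frame_offset
  # codon phase of a consensus position, propagated colinearly from the V
  # alignment start (indels within V make this approximate)
  phase_at_j <- (dj$j_start - v$v_start + (v$g_start - f_v)) %% 3
  needed <- (dj$j_gstart - f_j) %% 3
  frame_ok <- phase_at_j == needed
  # anchor: first phase-0 consensus position at/after the V start
  anchor <- v$v_start + ((3 - ((v$g_start - f_v) %% 3)) %% 3)
  stop_free <- !has_inframe_stop(consensus, anchor, dj$j_end)
  list(frame_ok = frame_ok, stop_free = stop_free,
       productive = frame_ok && stop_free)
}

#' Classify SHM status from V-region identity
#'
#' The 2% rule: identity >= 98.00% is unmutated, below is mutated. The
#' borderline flag marks \[97.00, 98.00), where classification is least
#' reliable; borderline cases are still classed mutated.
#'
#' @param v_identity_pct identity percentage in \[0, 100\].
#' @return list with `status` ("unmutated"/"mutated"), `borderline`, and the
#'   input identity.
#' @export
classify_shm <- function(v_identity_pct) {
  if (is.na(v_identity_pct) || v_identity_pct < 0 || v_identity_pct > 100) {
    stop("v_identity_pct must be in [0, 100]")
  }
  status <- if (v_identity_pct >= 98.00) "unmutated" else "mutated"
  borderline <- v_identity_pct >= 97.00 && v_identity_pct < 98.00
  list(status = status, borderline = borderline,
       v_identity_pct = v_identity_pct)
}

#' Annotate one consensus record
#'
#' Runs [assign_v()], [assign_dj()], [compute_identity()],
#' [check_productivity()] and [classify_shm()] and collects the result as a
#' one-row AIRR-style annotation table.
#'
#' @param record one-row consensus record with `status == "ok"`.
#' @param db a `germline_db`.
#' @param params an [align_params()].
#' @param identity_mode see [compute_identity()].
#' @param d_min_len,d_min_identity see [assign_dj()].
#' @return one-row data.frame with `clone_id`, `v_call`, `d_call`, `j_call`,
#'   `v_identity`, `junction`, `frame_ok`, `stop_free`, `productive`,
#'   `shm_status`, `borderline`, `annot_status`.
#' @export
annotate_consensus <- function(record, db, params = align_params(),
                               identity_mode = "indel",
                               d_min_len = 10L, d_min_identity = 0.8) {
  stopifnot(nrow(record) == 1, record$status == "ok")
  base <- data.frame(
    clone_id = record$clone_id, v_call = NA_character_,
    d_call = NA_character_, j_call = NA_character_,
    v_identity = NA_real_, junction = NA_character_,
    frame_ok = NA, stop_free = NA, productive = NA,
    shm_status = NA_character_, borderline = NA,
    annot_status = "ok", stringsAsFactors = FALSE)
  v <- assign_v(record$sequence, db, params)
  if (is.na(v$v_call)) {
    base$annot_status <- "no_v_assigned"
    return(base)
  }
  base$v_call <- v$v_call
  base$v_identity <- compute_identity(v, identity_mode)
  dj <- assign_dj(record$sequence, v, db, params,
                  d_min_len = d_min_len, d_min_identity = d_min_identity)
  if (is.na(dj$j_call)) {
    base$annot_status <- "no_j_assigned"  # excluded from SHM reporting
    return(base)
  }
  base$d_call <- dj$d_call
  base$j_call <- dj$j_call
  base$junction <- dj$junction
  pr <- check_productivity(record$sequence, v, dj)
  base$frame_ok <- pr$frame_ok
  base$stop_free <- pr$stop_free
  base$productive <- pr$productive
  shm <- classify_shm(base$v_identity)
  base$shm_status <- shm$status
  base$borderline <- shm$borderline
  base
}
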