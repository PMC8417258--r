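#' @title Consensus building with an escalating error-tolerance schedule
#'
#' @description
#' Stage 2 of the pipeline. Reads selected for one clonal V gene are
#' partitioned by greedy centroid clustering on normalized edit distance at
#' the current tolerance; partitions below the supporting-read minimum are
#' dropped; each surviving partition is assembled by star alignment of its
#' reads to a medoid read with per-column majority calls. The tolerance
#' starts low and is escalated along the schedule until at least one draft is
#' produced or the schedule is exhausted (earliest-success rule). Drafts are
#' then polished by iterative realign-and-recall until byte-identical between
#' iterations.
#'
#' Every failure is recorded with a machine-readable reason
#' (`cluster_below_min_support`, `no_partition_reached_min_support`) so that
#' "no consensus despite a clonal gene" outcomes are auditable rather than
#' silent.
#'
#' @name consensus
NULL

#' Validate a tolerance schedule
#'
#' @param x numeric vector of per-base divergence values, strictly
#'   increasing, all in (0, 0.5).
#' @return `x`, validated.
#' @export
tolerance_schedule <- function(x = c(0.05, 0.10, 0.15, 0.20)) {
  if (length(x) == 0) stop("tolerance schedule must be non-empty")
  if (any(x <= 0) || any(x >= 0.5)) stop("tolerances must be in (0, 0.5)")
  if (any(diff(x) <= 0)) stop("tolerance schedule must be strictly increasing")
  x
}

# normalized edit distance with a banded computation; Inf when above cap
norm_edit_dist <- function(a, b, cap) {
  maxlen <- max(nchar(a), nchar(b))
  if (maxlen == 0) return(0)
  md <- as.integer(ceiling(cap * maxlen)) + 1L
  d <- banded_edit_cpp(a, b, md)
  if (d > md) Inf else d / maxlen
}

#' Partition cluster reads by greedy centroid clustering
#'
#' Reads are processed sorted by length descending (ties by read id); a read
#' joins the nearest existing partition whose centroid is within
#' `2 * tolerance` normalized edit distance, otherwise it seeds a new
#' partition (up to `max_partitions`; reads beyond that are left
#' unassigned). Deterministic given the input.
#'
#' @param cluster a `read_cluster` from [select_reads()].
#' @param tolerance per-base divergence tolerance.
#' @param max_partitions cap on the number of partitions.
#' @return list with `partitions` (list of integer index vectors into the
#'   cluster), `centroids` (index of each partition's seed read) and
#'   `unassigned`.
#' @export
subcluster <- function(cluster, tolerance, max_partitions = 12L) {
  n <- length(cluster$seq)
  if (n == 0) stop("empty read cluster")
  ord <- order(-nchar(cluster$seq), cluster$read_id)
  centroids <- integer(0)
  assign <- integer(n)  # 0 = unassigned
  for (i in ord) {
    if (length(centroids) == 0) {
      centroids <- i; assign[i] <- 1L
      next
    }
    d <- vapply(centroids,
                function(ci) norm_edit_dist(cluster$seq[i], cluster$seq[ci],
                                            2 * tolerance),
                numeric(1))
    best <- which.min(d)
    if (is.finite(d[best]) && d[best] <= 2 * tolerance) {
      assign[i] <- best
    } else if (length(centroids) < max_partitions) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    }
  }
  parts <- lapply(seq_along(centroids), function(k) {
    idx <- which(assign == k)
    idx[order(match(idx, ord))]
  })
  list(partitions = parts, centroids = centroids,
       unassigned = which(assign == 0L))
}

# medoid of a partition, estimated from its first `cap` reads in processing
# order; ties go to the earliest read
partition_medoid <- function(seqs, cap = 30L) {
  m <- min(length(seqs), cap)
  if (m == 1) return(1L)
  sub <- seqs[seq_len(m)]
  dm <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- norm_edit_dist(sub[i], sub[j], 0.45)
      if (!is.finite(d)) d <- 0.5
      dm[i, j] <- dm[j, i] <- d
    }
  }
  which.min(rowSums(dm))
}

# one realign-and-recall pass: majority base per scaffold column (ties to the
# alphabetically earliest base; a gap must strictly beat every base to delete
# the column), plus insertion columns supported by > min_ins_frac of the
# reads covering the junction. Scaffold end columns with coverage below
# end_trim_frac of the median are dropped: local alignments cannot vote
# deletions at the extremities, so spurious scaffold ends would otherwise
# persist at near-zero coverage.
call_columns <- function(scaffold, pass, min_ins_frac = 0.5,
                         end_trim_frac = 0.25) {
  L <- nchar(scaffold)
  counts <- pass$counts
  cov <- as.integer(pass$cov)
  base_idx <- max.col(t(counts[1:4, , drop = FALSE]), ties.method = "first")
  base_cnt <- counts[cbind(base_idx, seq_len(L))]
  gap_cnt <- counts[5, ]
  scaff_chars <- strsplit(scaffold, "")[[1]]
  base_chr <- BASES[base_idx]
  base_chr[cov == 0] <- scaff_chars[cov == 0]
  deleted <- gap_cnt > base_cnt & cov > 0
  ins_prefix <- character(L)
  if (L > 1) {
    p <- seq_len(L - 1)  # 0-based junction positions (before base p)
    jc <- pmin(cov[p], cov[p + 1])
    ib <- as.character(pass$ins_best)[p + 1]
    do_ins <- pass$ins_any[p + 1] > min_ins_frac * jc & jc > 0 & nzchar(ib)
    ins_prefix[p[do_ins] + 1] <- ib[do_ins]
  }
  keep <- seq_len(L)
  if (any(cov > 0)) {
    thr <- end_trim_frac * stats::median(cov[cov > 0])
    solid <- which(cov >= thr)
    if (length(solid) > 0) keep <- solid[1]:solid[length(solid)]
  }
  ins_prefix[keep[1]] <- ""  # no insertion ahead of the first kept column
  body <- paste(paste0(ins_prefix[keep], ifelse(deleted[keep], "", base_chr[keep])),
                collapse = "")
  # regrow scaffold ends from soft-clipped read ends: a base beyond the
  # boundary is added when more than half of the boundary-covering reads
  # carry it at that offset
  prefix <- ""
  if (keep[1] == 1 && cov[1] > 0) {
    ext <- character(0)
    for (d in seq_len(ncol(pass$pre))) {
      bi <- which.max(pass$pre[, d])
      if (pass$pre[bi, d] > 0.5 * cov[1]) ext <- c(BASES[bi], ext) else break
    }
    prefix <- paste(ext, collapse = "")
  }
  suffix <- ""
  if (keep[length(keep)] == L && cov[L] > 0) {
    ext <- character(0)
    for (d in seq_len(ncol(pass$suf))) {
      bi <- which.max(pass$suf[, d])
      if (pass$suf[bi, d] > 0.5 * cov[L]) ext <- c(ext, BASES[bi]) else break
    }
    suffix <- paste(ext, collapse = "")
  }
  paste0(prefix, body, suffix)
}

empty_consensus_record <- function(gene, status, reason, support, tolerance) {
  data.frame(clone_id = paste0(gene, ".0"), gene = gene, sequence = "",
             support = support, tolerance = tolerance, polish_iters = 0L,
             converged = NA, status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' Build draft consensus sequences for a read cluster
#'
#' Implements the escalating-tolerance assembly contract: for each tolerance
#' in ascending order, partition the reads, drop partitions with fewer than
#' `min_support` reads, and assemble one draft per surviving partition;
#' escalation stops at the first tolerance that yields at least one draft.
#' If no tolerance succeeds a single failure record is returned whose
#' `status`/`reason` state which filter was responsible.
#'
#' @param cluster a `read_cluster`.
#' @param schedule a [tolerance_schedule()].
#' @param min_support minimum supporting reads per consensus (>= 2).
#' @param params an [align_params()].
#' @param max_partitions cap passed to [subcluster()].
#' @param merge_tol drafts within this normalized edit distance of each
#'   other are collapsed into one record (same-clone read partitions
#'   reconverge after denoising; genuinely distinct rearrangements stay
#'   apart).
#' @return data.frame of consensus records (`clone_id`, `gene`, `sequence`,
#'   `support`, `tolerance`, `polish_iters`, `converged`, `status`,
#'   `reason`), with a `partitions` attribute mapping ok clone ids to the
#'   read ids supporting them.
#' @export
build_consensus <- function(cluster, schedule = tolerance_schedule(),
                            min_support = 20L, params = align_params(),
                            max_partitions = 12L, merge_tol = 0.03) {
  if (length(cluster$seq) == 0) stop("empty read cluster")
  if (min_support < 2) stop("min_support must be >= 2")
  schedule <- tolerance_schedule(schedule)

  if (length(cluster$seq) < min_support) {
    return(empty_consensus_record(cluster$gene, "filtered_low_support",
                                  "cluster_below_min_support",
                                  length(cluster$seq), schedule[1]))
  }
  for (tol in schedule) {
    sc <- subcluster(cluster, tol, max_partitions)
    sizes <- lengths(sc$partitions)
    surv <- which(sizes >= min_support)
    if (length(surv) == 0) next
    surv <- surv[order(-sizes[surv], surv)]
    drafts <- character(length(surv))
    part_idx <- vector("list", length(surv))
    for (k in seq_along(surv)) {
      idx <- sc$partitions[[surv[k]]]
      seqs <- cluster$seq[idx]
      med <- partition_medoid(seqs)
      pass <- consensus_pass_cpp(seqs[med], seqs, params$match,
                                 params$mismatch, -params$gap_open,
                                 -params$gap_ext, params$score_floor)
      drafts[k] <- call_columns(seqs[med], pass)
      part_idx[[k]] <- idx
    }
    # drafts are denoised, so two partitions of the same clone converge to
    # near-identical sequences; collapse drafts within merge_tol of each
    # other (single linkage) into the largest partition's draft
    grp <- seq_along(drafts)
    if (length(drafts) > 1) {
      for (a in seq_len(length(drafts) - 1)) {
        for (b in (a + 1):length(drafts)) {
          if (norm_edit_dist(drafts[a], drafts[b], merge_tol) <= merge_tol) {
            grp[grp == grp[b]] <- grp[a]
          }
        }
      }
    }
    recs <- list(); parts <- list()
    k <- 0L
    for (g in unique(grp)) {
      k <- k + 1L
      members <- which(grp == g)            # first member has largest support
      idx <- sort(unlist(part_idx[members]))
      cid <- paste0(cluster$gene, ".", k)
      recs[[k]] <- data.frame(
        clone_id = cid, gene = cluster$gene,
        sequence = drafts[members[1]], support = length(idx),
        tolerance = tol, polish_iters = 0L, converged = NA,
        status = "ok", reason = "", stringsAsFactors = FALSE)
      parts[[cid]] <- cluster$read_id[idx]
    }
    out <- do.call(rbind, recs)
    o <- order(-out$support, out$clone_id)
    out <- out[o, , drop = FALSE]
    parts <- parts[out$clone_id]
    out$clone_id <- paste0(cluster$gene, ".", seq_len(nrow(out)))
    names(parts) <- out$clone_id
    rownames(out) <- NULL
    attr(out, "partitions") <- parts
    return(out)
  }
  empty_consensus_record(cluster$gene, "failed",
                         "no_partition_reached_min_support",
                         length(cluster$seq), schedule[length(schedule)])
}

#' Polish a draft consensus by iterative realign-and-recall
#'
#' All supporting reads are locally realigned to the current consensus and
#' every column is re-called (including insertion columns supported by more
#' than half of the covering reads); this repeats until the sequence is
#' byte-identical between iterations or `max_iter` is reached.
#'
#' @param record one-row consensus record with `status == "ok"`.
#' @param reads character vector of the supporting reads (pipeline
#'   orientation).
#' @param params an [align_params()].
#' @param max_iter maximum polishing iterations.
#' @return the updated record (`sequence`, `polish_iters`, `converged`).
#' @export
polish <- function(record, reads, params = align_params(), max_iter = 5L) {
  stopifnot(nrow(record) == 1)
  if (record$status != "ok") stop("can only polish an ok consensus record")
  cur <- record$sequence
  iters <- 0L
  converged <- FALSE
  while (iters < max_iter) {
    pass <- consensus_pass_cpp(cur, reads, params$match, params$mismatch,
                               -params$gap_open, -params$gap_ext,
                               params$score_floor)
    nxt <- call_columns(cur, pass)
    iters <- iters + 1L
    if (nxt == cur) { converged <- TRUE; break }
    cur <- nxt
  }
  record$sequence <- cur
  record$polish_iters <- iters
  record$converged <- converged
  record
}
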