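#' Per-V-gene coverage from read alignments
#'
#' Depth of a V gene is the mean per-base coverage over its interval: total
#' aligned bases falling inside the interval divided by gene length. The
#' number of overlapping reads is reported alongside but is not used for
#' clonality calling.
#'
#' @param alignments data.frame from [align_reads()].
#' @param db a `germline_db`.
#' @return data.frame with one row per V gene: `gene`, `depth`, `n_reads`.
#' @export
compute_depth <- function(alignments, db) {
  vg <- db_genes(db, "V")
  depth <- numeric(nrow(vg)); n_reads <- integer(nrow(vg))
  for (i in seq_len(nrow(vg))) {
    ov_start <- pmax(alignments$r_start, vg$start[i])
    ov_end <- pmin(alignments$r_end, vg$end[i])
    ov <- pmax(0L, ov_end - ov_start)
    depth[i] <- sum(ov) / (vg$end[i] - vg$start[i])
    n_reads[i] <- sum(ov > 0)
  }
  data.frame(gene = vg$name, depth = depth, n_reads = n_reads,
             stringsAsFactors = FALSE)
}

#' Call clonotypic V genes by coverage threshold
#'
#' A V gene is called clonal when its mean depth reaches the coverage
#' threshold (inclusive; default 500X). Output is sorted by depth descending
#' with deterministic ties broken by gene name.
#'
#' @param depth data.frame from [compute_depth()].
#' @param threshold coverage threshold (> 0).
#' @return data.frame `gene`, `depth`, `n_reads`, `passed`, `rank`.
#' @export
call_clonal_genes <- function(depth, threshold = 500) {
  if (threshold <= 0) stop("threshold must be > 0")
  o <- order(-depth$depth, depth$gene)
  out <- depth[o, , drop = FALSE]
  out$passed <- out$depth >= threshold
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the reads supporting one clonal V gene
#'
#' A read belongs to the cluster when its alignment overlaps the gene
#' interval by at least `min_overlap_frac` of the gene length (default 50%).
#' Cluster reads are stored in pipeline orientation: minus-strand reads are
#' reverse-complemented to the + strand.
#'
#' @param alignments data.frame from [align_reads()].
#' @param gene name of a V gene whose clonal call passed.
#' @param db a `germline_db`.
#' @param reads the read data.frame the alignments came from.
#' @param min_overlap_frac minimum overlap as a fraction of gene length.
#' @return a `read_cluster`: list with `gene`, `read_id`, `seq` (oriented),
#'   `n`.
#' @export
select_reads <- function(alignments, gene, db, reads, min_overlap_frac = 0.5) {
  g <- db_gene(db, gene)
  ov_start <- pmax(alignments$r_start, g$start)
  ov_end <- pmin(alignments$r_end, g$end)
  ov <- pmax(0L, ov_end - ov_start)
  keep <- ov >= min_overlap_frac * (g$end - g$start)
  sel <- alignments[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("internal consistency error: no reads selected for clonal gene ", gene)
  }
  idx <- match(sel$read_id, reads$read_id)
  seqs <- reads$seq[idx]
  minus <- sel$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  structure(list(gene = gene, read_id = sel$read_id, seq = seqs,
                 n = nrow(sel)),
            class = "read_cluster")
}

#' @export
print.read_cluster <- function(x, ...) {
  cat("<read_cluster>", x$gene, "-", x$n, "reads\n")
  invisible(x)
}

#' Clonality plot: per-V-gene depth bar chart
#'
#' @param depth data.frame from [compute_depth()].
#' @param threshold coverage threshold drawn as a dashed line.
#' @param sample_id optional title.
#' @return a ggplot object.
#' @export
plot_clonality <- function(depth, threshold = 500, sample_id = NULL) {
  ggplot2::ggplot(depth, ggplot2::aes(x = .data$gene, y = .data$depth)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "V gene", y = "mean depth (X)",
                  title = sample_id %||% "Clonality") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
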