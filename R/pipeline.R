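#' Pipeline configuration
#'
#' Collects every tunable of the three analysis stages. Defaults: coverage
#' threshold 500X (inclusive), tolerance schedule 0.05/0.10/0.15/0.20,
#' minimum 20 supporting reads per consensus, at most 5 polishing
#' iterations.
#'
#' @param coverage_threshold minimum mean depth for a clonal V-gene call.
#' @param tol_schedule see [tolerance_schedule()].
#' @param min_support minimum supporting reads per consensus.
#' @param max_polish_iter maximum polishing iterations.
#' @param align an [align_params()].
#' @param min_overlap_frac read-selection overlap rule (fraction of gene
#'   length).
#' @param max_partitions subclustering partition cap.
#' @param d_min_len,d_min_identity D-call acceptance rule.
#' @param identity_mode identity denominator convention
#'   ("indel"/"subs_only").
#' @param make_plot write a clonality plot per sample.
#' @param sam_export write a SAM of the stage-1 alignments.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(coverage_threshold = 500,
                            tol_schedule = tolerance_schedule(),
                            min_support = 20L, max_polish_iter = 5L,
                            align = align_params(),
                            min_overlap_frac = 0.5, max_partitions = 12L,
                            d_min_len = 10L, d_min_identity = 0.8,
                            identity_mode = "indel",
                            make_plot = FALSE, sam_export = FALSE) {
  if (coverage_threshold <= 0) stop("coverage_threshold must be > 0")
  if (min_support < 2) stop("min_support must be >= 2")
  if (max_polish_iter < 1) stop("max_polish_iter must be >= 1")
  structure(list(coverage_threshold = coverage_threshold,
                 tol_schedule = tolerance_schedule(tol_schedule),
                 min_support = as.integer(min_support),
                 max_polish_iter = as.integer(max_polish_iter),
                 align = align, min_overlap_frac = min_overlap_frac,
                 max_partitions = as.integer(max_partitions),
                 d_min_len = as.integer(d_min_len),
                 d_min_identity = d_min_identity,
                 identity_mode = identity_mode,
                 make_plot = isTRUE(make_plot),
                 sam_export = isTRUE(sam_export)),
            class = "pipeline_config")
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

#' Run the full pipeline on one sample
#'
#' Clonality (align, depth, threshold call), consensus (subcluster,
#' support-filter, assemble, polish) and annotation (V/D/J, identity,
#' productivity, SHM status) in order, with intermediate artifacts written
#' to `outdir` when given. Fully deterministic for fixed inputs and
#' configuration: the analysis path contains no randomness.
#'
#' The sample-level status is "unmutated"/"mutated" when all productive
#' clones agree, "discordant-multiclonal" when productive clones disagree
#' (flagged for human review rather than silently picking one), "no clonal
#' rearrangement" when no V gene reaches the coverage threshold, and
#' "no result" when no productive consensus could be annotated.
#'
#' @param fastq path to a FASTQ file (or a read data.frame).
#' @param db a `germline_db`.
#' @param config a [pipeline_config()].
#' @param sample_id sample identifier (defaults to the FASTQ basename).
#' @param outdir per-sample output directory (created; NULL = nothing
#'   written).
#' @return a `sample_report` list: `sample_id`, `n_reads`, `depth`, `calls`,
#'   `consensus`, `annotations`, `shm`, `status`.
#' @export
run_sample <- function(fastq, db, config = pipeline_config(),
                       sample_id = NULL, outdir = NULL) {
  if (is.character(fastq)) {
    sample_id <- sample_id %||%
      sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    reads <- read_fastq(fastq)
  } else {
    reads <- fastq
    sample_id <- sample_id %||% "sample"
  }

  empty_report <- function(status) {
    structure(list(sample_id = sample_id, n_reads = nrow(reads),
                   depth = NULL, calls = NULL,
                   consensus = NULL, annotations = NULL, shm = NULL,
                   status = status), class = "sample_report")
  }
  if (nrow(reads) == 0) {
    rep <- empty_report("no result")
    if (!is.null(outdir)) write_sample_report(rep, outdir)
    return(rep)
  }

  aln <- align_reads(reads, db, config$align)
  depth <- compute_depth(aln, db)
  calls <- call_clonal_genes(depth, config$coverage_threshold)

  rep <- structure(list(sample_id = sample_id, n_reads = nrow(reads),
                        depth = depth, calls = calls, consensus = NULL,
                        annotations = NULL, shm = NULL, status = NULL),
                   class = "sample_report")
  passed <- calls$gene[calls$passed]
  if (length(passed) == 0) {
    rep$status <- "no clonal rearrangement"
    if (!is.null(outdir)) write_sample_report(rep, outdir, aln, reads, db, config)
    return(rep)
  }

  cons_list <- list(); annot_list <- list()
  for (g in passed) {
    cl <- select_reads(aln, g, db, reads, config$min_overlap_frac)
    recs <- build_consensus(cl, config$tol_schedule, config$min_support,
                            config$align, config$max_partitions)
    parts <- attr(recs, "partitions")
    for (i in seq_len(nrow(recs))) {
      rec <- recs[i, , drop = FALSE]
      if (rec$status == "ok") {
        sup_ids <- parts[[rec$clone_id]]
        sup_seqs <- cl$seq[match(sup_ids, cl$read_id)]
        rec <- polish(rec, sup_seqs, config$align, config$max_polish_iter)
        annot_list[[length(annot_list) + 1L]] <-
          annotate_consensus(rec, db, config$align, config$identity_mode,
                             config$d_min_len, config$d_min_identity)
      }
      cons_list[[length(cons_list) + 1L]] <- rec
    }
  }
  rep$consensus <- do.call(rbind, cons_list)
  rep$annotations <- if (length(annot_list)) do.call(rbind, annot_list) else NULL

  if (!is.null(rep$annotations)) {
    sh <- rep$annotations[rep$annotations$annot_status == "ok", , drop = FALSE]
    if (nrow(sh) > 0) {
      rep$shm <- sh[, c("clone_id", "shm_status", "borderline", "v_identity")]
    }
  }

  prod <- if (is.null(rep$annotations)) NULL else
    rep$annotations[!is.na(rep$annotations$productive) &
                      rep$annotations$productive, , drop = FALSE]
  rep$status <- if (is.null(prod) || nrow(prod) == 0) {
    "no result"
  } else {
    st <- unique(prod$shm_status)
    if (length(st) == 1) st else "discordant-multiclonal"
  }

  if (!is.null(outdir)) write_sample_report(rep, outdir, aln, reads, db, config)
  rep
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report>", x$sample_id, "-", x$n_reads, "reads - status:",
      x$status, "\n")
  if (!is.null(x$calls)) {
    cat("  clonal V genes:",
        paste(x$calls$gene[x$calls$passed], collapse = ", "), "\n")
  }
  if (!is.null(x$shm)) {
    for (i in seq_len(nrow(x$shm))) {
      cat(sprintf("  %s: %s (identity %.2f%%%s)\n", x$shm$clone_id[i],
                  x$shm$shm_status[i], x$shm$v_identity[i],
                  if (x$shm$borderline[i]) ", borderline" else ""))
    }
  }
  invisible(x)
}

#' One row per clone, flat, for tabulated reports
#'
#' @param report a `sample_report`.
#' @return data.frame with one row per consensus record (or one NA row for
#'   sample-level failures).
#' @export
sample_report_rows <- function(report) {
  na_row <- data.frame(
    sample_id = report$sample_id, clone_id = NA_character_,
    v_call = NA_character_, d_call = NA_character_, j_call = NA_character_,
    support = NA_integer_, tolerance = NA_real_,
    consensus_status = NA_character_, consensus_reason = NA_character_,
    annot_status = NA_character_, v_identity = NA_real_,
    junction = NA_character_, productive = NA,
    shm_status = NA_character_, borderline = NA,
    sample_status = report$status, stringsAsFactors = FALSE)
  if (is.null(report$consensus)) return(na_row)
  rows <- list()
  for (i in seq_len(nrow(report$consensus))) {
    co <- report$consensus[i, ]
    an <- if (!is.null(report$annotations)) {
      report$annotations[report$annotations$clone_id == co$clone_id, ,
                         drop = FALSE]
    } else NULL
    has_an <- !is.null(an) && nrow(an) == 1
    rows[[i]] <- data.frame(
      sample_id = report$sample_id, clone_id = co$clone_id,
      v_call = if (has_an) an$v_call else NA_character_,
      d_call = if (has_an) an$d_call else NA_character_,
      j_call = if (has_an) an$j_call else NA_character_,
      support = co$support, tolerance = co$tolerance,
      consensus_status = co$status, consensus_reason = co$reason,
      annot_status = if (has_an) an$annot_status else NA_character_,
      v_identity = if (has_an) an$v_identity else NA_real_,
      junction = if (has_an) an$junction else NA_character_,
      productive = if (has_an) an$productive else NA,
      shm_status = if (has_an) an$shm_status else NA_character_,
      borderline = if (has_an) an$borderline else NA,
      sample_status = report$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

write_tsv_det <- function(df, path) {
  # deterministic text serialisation: fixed number formatting, no quoting
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    digits <- if (cn %in% c("v_identity", "depth")) {
      if (cn == "depth") 4L else 2L
    } else if (is.integer(df[[cn]])) NA_integer_ else 4L
    if (!is.na(digits)) df[[cn]] <- fmt_num(df[[cn]], digits)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_sample_report <- function(report, outdir, aln = NULL, reads = NULL,
                                db = NULL, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$depth)) {
    write_tsv_det(report$depth, file.path(outdir, "depth.tsv"))
  }
  if (!is.null(report$calls)) {
    write_tsv_det(report$calls, file.path(outdir, "clonal_calls.tsv"))
  }
  if (!is.null(report$consensus)) {
    co <- report$consensus
    write_tsv_det(co[, setdiff(names(co), "sequence")],
                  file.path(outdir, "consensus_records.tsv"))
    ok <- co[co$status == "ok", , drop = FALSE]
    if (nrow(ok) > 0) {
      ss <- Biostrings::DNAStringSet(ok$sequence)
      names(ss) <- sprintf("%s|%s|support=%d|tol=%.2f|%s", report$sample_id,
                           ok$clone_id, ok$support, ok$tolerance, ok$status)
      Biostrings::writeXStringSet(ss, file.path(outdir, "consensus.fasta"))
    }
  }
  if (!is.null(report$annotations)) {
    write_tsv_det(report$annotations, file.path(outdir, "annotation.tsv"))
  }
  if (!is.null(report$shm)) {
    write_tsv_det(report$shm, file.path(outdir, "shm.tsv"))
  }
  write_tsv_det(sample_report_rows(report),
                file.path(outdir, "sample_report.tsv"))
  if (!is.null(config) && config$sam_export && !is.null(aln) &&
        !is.null(reads) && !is.null(db)) {
    write_sam(aln, reads, db, file.path(outdir, "alignments.sam"))
  }
  if (!is.null(config) && config$make_plot && !is.null(report$depth)) {
    p <- plot_clonality(report$depth, config$coverage_threshold,
                        report$sample_id)
    tryCatch(
      ggplot2::ggsave(file.path(outdir, "clonality.png"), p,
                      width = 6, height = 4, dpi = 120),
      error = function(e) warning("could not write clonality plot: ",
                                  conditionMessage(e)))
  }
  invisible(outdir)
}

#' Run the pipeline on a batch of samples
#'
#' One sample failing (e.g. a missing FASTQ) never aborts the batch; its row
#' is tabulated as failed. Writes a combined per-clone table and a summary
#' of sample-status counts when `outdir` is given.
#'
#' @param sample_sheet data.frame with `sample_id`, `fastq_path` columns, or
#'   the path of such a CSV.
#' @param db a `germline_db`.
#' @param config a [pipeline_config()].
#' @param outdir batch output directory (per-sample subdirectories inside).
#' @return list with `reports` (per sample), `combined` (data.frame),
#'   `summary` (status counts).
#' @export
run_batch <- function(sample_sheet, db, config = pipeline_config(),
                      outdir = NULL) {
  if (is.character(sample_sheet)) {
    sample_sheet <- read.csv(sample_sheet, stringsAsFactors = FALSE)
  }
  if (nrow(sample_sheet) == 0) stop("empty sample sheet")
  if (!all(c("sample_id", "fastq_path") %in% names(sample_sheet))) {
    stop("sample sheet needs columns sample_id, fastq_path")
  }
  reports <- list(); rows <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    sid <- sample_sheet$sample_id[i]
    fq <- sample_sheet$fastq_path[i]
    sdir <- if (is.null(outdir)) NULL else file.path(outdir, sid)
    res <- tryCatch(
      run_sample(fq, db, config, sample_id = sid, outdir = sdir),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        sample_id = sid, clone_id = NA_character_, v_call = NA_character_,
        d_call = NA_character_, j_call = NA_character_,
        support = NA_integer_, tolerance = NA_real_,
        consensus_status = NA_character_, consensus_reason = NA_character_,
        annot_status = NA_character_, v_identity = NA_real_,
        junction = NA_character_, productive = NA,
        shm_status = NA_character_, borderline = NA,
        sample_status = paste0("failed: ", conditionMessage(res)),
        stringsAsFactors = FALSE)
      reports[[sid]] <- res
    } else {
      reports[[sid]] <- res
      rows[[i]] <- sample_report_rows(res)
    }
  }
  combined <- do.call(rbind, rows)
  per_sample <- vapply(reports, function(r) {
    if (inherits(r, "error")) "failed" else r$status
  }, character(1))
  summary <- as.data.frame(table(status = per_sample),
                           stringsAsFactors = FALSE)
  names(summary) <- c("status", "n_samples")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_det(combined, file.path(outdir, "combined_report.tsv"))
    write_tsv_det(summary, file.path(outdir, "batch_summary.tsv"))
  }
  list(reports = reports, combined = combined, summary = summary)
}
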