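#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file into a data frame
#'
#' Sequence-only import; base qualities are ignored throughout the pipeline
#' (quality filtering is assumed to have happened upstream, at basecalling).
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(read_id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  data.frame(read_id = ids, seq = as.character(ss),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ with placeholder qualities
#'
#' @param reads data.frame with `read_id` and `seq` columns.
#' @param path output path.
#' @param qual_char single character used for every base quality.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(qual_char, nchar(reads$seq)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

# random DNA of length n using the current RNG stream
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# in-frame stop scan: frame anchor at 0-based offset `anchor` of `seq`
has_inframe_stop <- function(seq, anchor = 0L, end0 = nchar(seq)) {
  starts <- seq.int(anchor, by = 3L, length.out = max(0L, (end0 - anchor) %/% 3L))
  if (length(starts) == 0L) return(FALSE)
  codons <- substring(seq, starts + 1L, starts + 3L)
  any(codons %in% STOP_CODONS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
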