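#' Read amino-acid sequences from a FASTA file
#'
#' Thin wrapper around Biostrings that returns a plain named character vector
#' and enforces the canonical 20-letter amino-acid alphabet. Multi-line
#' (wrapped) records are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (names = record ids, values = sequences);
#'   empty vector for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_scfv("no such file: ", path, class = "io_error")
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    # the reader drops invalid characters with a warning; treat as fatal so
    # sequences are never silently altered
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop_scfv("non-amino-acid characters in ", path, class = "parse_error")
      }
      invokeRestart("muffleWarning")
    })
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set) %||% character(0))
  ok <- aa_alphabet()
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]), ok)
    if (length(bad)) {
      stop_scfv("record '", names(seqs)[i], "' contains non-amino-acid letters: ",
                paste(bad, collapse = ", "), class = "parse_error")
    }
  }
  seqs
}

#' Write amino-acid sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(unname(seqs))
  names(set) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a replicated affinity assay table
#'
#' Reads the tab-delimited assay dialect produced by
#' [generate_training_data()] / [write_assay_tsv()]: columns `id`,
#' `sequence`, then one column per replicate (`rep1`, `rep2`, ...). Empty
#' cells denote measurements beyond the detection limit (missing).
#'
#' @param path Path to a TSV file.
#' @return A data frame with `id`, `sequence` and numeric replicate columns
#'   (`NA` = missing).
#' @export
read_assay_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  req <- c("id", "sequence")
  if (!all(req %in% names(df))) {
    stop_scfv("assay table must have 'id' and 'sequence' columns",
              class = "parse_error")
  }
  df
}

#' Write a replicated affinity assay table
#'
#' @param df Data frame with `id`, `sequence` and replicate columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assay_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
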