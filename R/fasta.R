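# FASTA input/output (parsing delegated to Biostrings)

#' Read DNA sequences from a FASTA file
#'
#' Multi-line records are supported; bases are uppercased; each record must
#' use the A/C/G/T/N alphabet, otherwise an error naming the offending
#' record is raised. An empty file yields an empty tibble.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `desc` (full header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: '%s'.", path), class = "mosaictr_io_error")
  }
  empty <- tibble(id = character(), desc = character(), seq = character())
  if (file.size(path) == 0L) return(empty)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) return(empty)
  desc <- names(x)
  ids <- sub("\\s.*$", "", desc)
  seqs <- toupper(as.character(x))
  bad <- !nzchar(seqs) | grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(
      sprintf("record '%s' is empty or contains non-A/C/G/T/N letters.",
              ids[which(bad)[1]]),
      class = "mosaictr_alphabet_error"
    )
  }
  tibble(id = unname(ids), desc = unname(desc), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param data Data frame with sequence and id columns (see [read_fasta()]).
#' @param path Output path.
#' @param seq_col,id_col Column names.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, seq_col = "seq", id_col = "id") {
  if (!is.data.frame(data) || !all(c(seq_col, id_col) %in% names(data))) {
    abort("`data` must contain the id and seq columns.",
          class = "mosaictr_type_error")
  }
  x <- Biostrings::BStringSet(setNames(as.character(data[[seq_col]]),
                                       as.character(data[[id_col]])))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
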