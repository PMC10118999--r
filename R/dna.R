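#' Validate a DNA sequence
#'
#' Checks that `seq` is a single non-empty string over the alphabet
#' A/C/G/T (optionally N) and returns it uppercased. All coordinates used
#' throughout the package are 0-based half-open intervals `[b, e)`, the BED
#' convention.
#'
#' @param seq A length-1 character vector.
#' @return The validated, uppercased sequence as a plain character scalar.
#' @examples
#' dna_string("acgtACGT")
#' @export
dna_string <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort("`seq` must be a single non-NA character string.",
          class = "mosaictr_type_error")
  }
  s <- toupper(seq)
  if (!nzchar(s)) {
    abort("`seq` must not be empty.", class = "mosaictr_empty_sequence")
  }
  if (grepl("[^ACGTN]", s)) {
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    abort(
      sprintf("`seq` contains a letter outside A/C/G/T/N: '%s'.", bad),
      class = "mosaictr_alphabet_error"
    )
  }
  s
}

# validate a unit set: distinct, non-empty DNA strings (order is meaningful:
# it records selection order)
check_units <- function(units, allow_empty = TRUE) {
  units <- as.character(units)
  if (length(units) == 0L) {
    if (!allow_empty) {
      abort("the unit set must contain at least one unit.",
            class = "mosaictr_empty_unit_set")
    }
    return(character(0))
  }
  if (anyNA(units) || any(!nzchar(units))) {
    abort("units must be non-empty strings.", class = "mosaictr_type_error")
  }
  units <- toupper(units)
  if (any(grepl("[^ACGTN]", units))) {
    abort("units must be DNA strings over A/C/G/T/N.",
          class = "mosaictr_alphabet_error")
  }
  if (anyDuplicated(units)) {
    abort("units must be distinct.", class = "mosaictr_duplicate_units")
  }
  units
}
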