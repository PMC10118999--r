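#' Suffix array, LCP array and LEN array of a DNA sequence
#'
#' Builds the suffix array of `seq`, the LCP array of adjacent suffix-array
#' entries, and the LEN array, where `len_arr[i + 1]` (position `i`, 0-based)
#' is the length of the longest substring starting at `i` that occurs at
#' least twice in `seq`. `LEN[i]` is the maximum LCP of suffix `i` with
#' either of its suffix-array neighbours; the first and last suffix-array
#' entries use their single neighbour.
#'
#' @param seq DNA sequence (see [dna_string()]).
#' @return A list with integer vectors `sa` (0-based start positions of the
#'   lexicographically sorted suffixes), `lcp` (length `n - 1`;
#'   `lcp[i]` is the longest common prefix of suffixes `sa[i]` and
#'   `sa[i + 1]`) and `len_arr` (length `n`, indexed by position + 1).
#' @examples
#' suffix_structures("AAA")  # sa 2,1,0; lcp 1,2; len_arr 2,2,1
#' @export
suffix_structures <- function(seq) {
  s <- dna_string(seq)
  r <- cpp_suffix_structures(s)
  list(sa = as.integer(r$sa), lcp = as.integer(r$lcp),
       len_arr = as.integer(r$len))
}

#' Border array (Morris-Pratt failure function) of a suffix
#'
#' For the suffix starting at 0-based position `start`, returns the vector
#' `ol` with `ol[k]` the length of the longest proper border of its length-k
#' prefix (the longest `l < k` with `seq[start, start+l) ==
#' seq[start+k-l, start+k)`). A substring `seq[start, start+k)` is
#' non-self-overlapping (borderless) iff `ol[k] == 0`.
#'
#' @param seq DNA sequence.
#' @param start 0-based start position, `0 <= start < n`.
#' @return Integer vector of length `n - start`.
#' @examples
#' overlap_array("AAAG", 0)  # 0 1 2 0: AAAG itself is borderless
#' @export
overlap_array <- function(seq, start) {
  s <- dna_string(seq)
  n <- nchar(s)
  if (!is.numeric(start) || length(start) != 1L || is.na(start) ||
      start != trunc(start) || start < 0 || start >= n) {
    abort(sprintf("`start` must be an integer in [0, %d).", n),
          class = "mosaictr_index_error")
  }
  as.integer(cpp_border_array(substr(s, start + 1L, n)))
}

#' Enumerate candidate repeat units
#'
#' Enumerates every substring of `seq` that is *repetitive* (occurs at least
#' twice, possibly overlapping) and *non-self-overlapping* (has no nonempty
#' proper border), up to length `max_len`. These are the only substrings
#' eligible as repeat units: borderlessness picks a single representative
#' among the rotations of a unit and rules out strings that are themselves
#' exact tandem repeats. Substrings containing N are excluded. Candidates
#' are deduplicated by text; the reported span is the leftmost occurrence.
#'
#' @param seq DNA sequence.
#' @param max_len Maximum unit length in bases (default 100).
#' @return A tibble with columns `text`, `start`, `end` (0-based half-open
#'   witness span) and `length`, sorted by length then text.
#' @examples
#' enumerate_units("ACCGACCGACCG")
#' @export
enumerate_units <- function(seq, max_len = 100) {
  s <- dna_string(seq)
  if (!is.numeric(max_len) || length(max_len) != 1L || is.na(max_len) ||
      max_len < 1) {
    abort("`max_len` must be a positive number.",
          class = "mosaictr_argument_error")
  }
  r <- cpp_enumerate_units(s, as.integer(max_len))
  out <- tibble(
    text = as.character(r$text),
    start = as.integer(r$start),
    length = nchar(as.character(r$text))
  )
  out$end <- out$start + out$length
  out <- out[order(out$length, out$text), c("text", "start", "end", "length")]
  tibble::remove_rownames(out)
}

#' Compression ratio of the non-self-overlapping substring census
#'
#' Counts the distinct substrings of `seq` of length at most `theta`
#' (`w_all`) and, among them, the candidate units — substrings that are
#' both repetitive (at least two occurrences) and non-self-overlapping
#' (`w_nsop`). Their ratio measures how strongly the unit eligibility
#' rules compress the space of units to be considered relative to all
#' substrings; on tandem-repeat sequences it is typically a few percent.
#'
#' @param seq DNA sequence.
#' @param theta Maximum substring length in bases (default 20).
#' @return A one-row tibble with columns `w_all`, `w_nsop`, `theta`, `ratio`.
#' @examples
#' compression_ratio("AAAA")  # 4 distinct substrings, only "A" borderless
#' @export
compression_ratio <- function(seq, theta = 20) {
  s <- dna_string(seq)
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 1) {
    abort("`theta` must be a positive number.",
          class = "mosaictr_argument_error")
  }
  r <- cpp_substring_counts(s, as.integer(theta))
  tibble(
    w_all = r$w_all, w_nsop = r$w_nsop, theta = as.integer(theta),
    ratio = r$w_nsop / r$w_all
  )
}
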