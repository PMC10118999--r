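# error-tolerant decomposition against a unit set

#' Error-tolerant decomposition by wraparound dynamic programming
#'
#' Aligns `seq` against the language of unit-copy concatenations
#' `(u1|...|uk)*` minimising total Levenshtein distance (unit costs: match
#' 0, mismatch/insertion/deletion 1), i.e. approximate regular-expression
#' matching. The DP keeps one row block per unit with free transitions from
#' the end of any unit to the start of any unit; the first and last copies
#' may be partial (the alignment may enter a unit mid-way at the start of
#' `seq` and exit mid-way at its end, at no structural cost), modelling the
#' `s (u)^k p` form of a tandem repeat. Runtime is O(n * sum |u|).
#' Traceback ties prefer continuing the current unit over switching, and
#' earlier-listed units otherwise.
#'
#' @param seq DNA sequence.
#' @param units Non-empty unit set (order = preference order).
#' @return A `tr_approx` object: list with `segments` (tibble `start`,
#'   `end`, `unit`, `edits`; one row per unit copy, 0-based half-open) and
#'   `total_edits`, the minimum edit distance.
#' @examples
#' approx_decompose("ACCGACTGACCG", "ACCG")$total_edits  # 1
#' @export
approx_decompose <- function(seq, units) {
  s <- dna_string(seq)
  units <- check_units(units, allow_empty = FALSE)
  r <- cpp_approx_decompose(s, units)
  segments <- tibble(
    start = as.integer(r$start),
    end = as.integer(r$end),
    unit = units[r$unit_idx + 1L],
    edits = as.integer(r$edits)
  )
  structure(
    list(seq = s, n = nchar(s), units = units, segments = segments,
         total_edits = as.integer(r$total_edits)),
    class = "tr_approx"
  )
}

#' Run-length encoding of a decomposition
#'
#' Collapses consecutive segments carrying the same unit into runs
#' `(unit)^copies`, the mosaic pattern notation. Uncovered segments (exact
#' decompositions only) appear as runs with `unit = NA` and `copies = NA`.
#'
#' @param x A `tr_approx`, `tr_decomposition` or `tr_annotation`.
#' @return A tibble with columns `unit`, `copies`, `start`, `end`, `edits`
#'   (`edits` is `NA` for exact decompositions).
#' @export
run_length_encode <- function(x) {
  seg <- decomposition_segments(x)
  if (nrow(seg) == 0L) {
    return(tibble(unit = character(), copies = integer(),
                  start = integer(), end = integer(), edits = integer()))
  }
  key <- ifelse(is.na(seg$unit), "\r<uncovered>", seg$unit)
  r <- rle(key)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  uncov <- r$values == "\r<uncovered>"
  tibble(
    unit = ifelse(uncov, NA_character_, r$values),
    copies = ifelse(uncov, NA_integer_, r$lengths),
    start = seg$start[idx_start],
    end = seg$end[idx_end],
    edits = vapply(seq_along(r$values), function(i) {
      e <- seg$edits[idx_start[i]:idx_end[i]]
      if (all(is.na(e))) NA_integer_ else sum(e, na.rm = TRUE)
    }, integer(1))
  )
}

# normalise the three decomposition flavours to a segment table with
# columns start / end / unit / edits
decomposition_segments <- function(x) {
  if (inherits(x, "tr_annotation")) x <- x$approx %||% x$selection$decomposition
  if (inherits(x, "tr_approx")) return(x$segments)
  if (inherits(x, "tr_decomposition")) {
    seg <- x$segments
    return(tibble(start = seg$start, end = seg$end, unit = seg$label,
                  edits = NA_integer_))
  }
  abort("`x` must be a tr_approx, tr_decomposition or tr_annotation.",
        class = "mosaictr_type_error")
}

#' Mosaic tandem-repeat classification
#'
#' A decomposition is called mosaic tandem repeats of its unit set if the
#' part of the sequence lying inside tandem runs — maximal stretches of at
#' least `min_tandem_copies` consecutive copies of the same unit — exceeds
#' `coverage_threshold` of the sequence length (strict inequality:
#' "exceeds"). Isolated single copies of a unit do not count towards
#' coverage, so scattered matches cannot qualify a sequence.
#'
#' @param x A `tr_approx`, `tr_decomposition` or `tr_annotation`.
#' @param coverage_threshold Fraction of the sequence length that tandem
#'   runs must exceed (default 0.8).
#' @param min_tandem_copies Minimum consecutive copies for a run to count
#'   (default 2).
#' @return A one-row tibble with `is_mosaic`, `coverage` (bases inside
#'   qualifying runs), `n` and `coverage_threshold`.
#' @examples
#' d <- manual_decomposition("ACACCCGACGA", c("AC", "AC", "C", "CGA", "CGA"),
#'                           units = c("AC", "CGA"))
#' classify_mosaic(d)  # coverage 10 of 11: mosaic
#' @export
classify_mosaic <- function(x, coverage_threshold = 0.8,
                            min_tandem_copies = 2) {
  if (!is.numeric(coverage_threshold) || coverage_threshold <= 0 ||
      coverage_threshold > 1) {
    abort("`coverage_threshold` must be in (0, 1].",
          class = "mosaictr_argument_error")
  }
  n <- x$n
  runs <- run_length_encode(x)
  ok <- !is.na(runs$unit) & runs$copies >= min_tandem_copies
  coverage <- sum((runs$end - runs$start)[ok])
  tibble(
    is_mosaic = coverage > n * coverage_threshold,
    coverage = as.integer(coverage),
    n = as.integer(n),
    coverage_threshold = coverage_threshold
  )
}
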