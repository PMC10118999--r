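# exact decompositions and the parsimony penalty

# internal constructor shared by manual_decomposition() and
# best_exact_decomposition(); segments must tile [0, n)
new_tr_decomposition <- function(seq, units, segments) {
  n <- nchar(seq)
  stopifnot(nrow(segments) == 0 || (segments$start[1] == 0 &&
            segments$end[nrow(segments)] == n))
  seg_len <- segments$end - segments$start
  covered <- sum(seg_len[!is.na(segments$label)])
  occ <- table(factor(segments$label, levels = units))
  occ <- setNames(as.integer(occ), units)
  penalty <- sum(nchar(units)) + sum(occ)
  structure(
    list(
      seq = seq, n = n, units = units, segments = segments,
      occurrences = occ,
      covered_length = covered, uncovered_length = n - covered,
      penalty = penalty, extended_penalty = penalty + (n - covered)
    ),
    class = "tr_decomposition"
  )
}

#' Build an exact decomposition from explicit pieces
#'
#' Tiles `seq` with the given `pieces` (which must concatenate exactly to
#' `seq`, in order). Pieces present in `units` become unit segments; any
#' other piece is recorded as uncovered. Useful for scoring hand-written
#' decompositions.
#'
#' @param seq DNA sequence.
#' @param pieces Character vector of consecutive substrings tiling `seq`.
#' @param units Unit set (character vector); defaults to the distinct pieces.
#' @return A `tr_decomposition` object; see [best_exact_decomposition()].
#' @examples
#' d <- manual_decomposition("ACCGACCGACCG", rep("ACCG", 3),
#'                           units = c("ACCG", "AC", "CG", "CGAC"))
#' penalty_of(d)
#' @export
manual_decomposition <- function(seq, pieces, units = unique(pieces)) {
  s <- dna_string(seq)
  pieces <- toupper(as.character(pieces))
  if (paste(pieces, collapse = "") != s) {
    abort("`pieces` must concatenate exactly to `seq`.",
          class = "mosaictr_tiling_error")
  }
  units <- check_units(units)
  ends <- cumsum(nchar(pieces))
  segments <- tibble(
    start = c(0L, ends[-length(ends)]),
    end = as.integer(ends),
    label = ifelse(pieces %in% units, pieces, NA_character_)
  )
  new_tr_decomposition(s, units, segments)
}

#' Penalty and extended penalty of a decomposition
#'
#' The penalty of a decomposition `D` under unit set `U` is
#' `sum over u in U of (|u| + o(u))`, where `o(u)` is the number of segments
#' of `D` labelled `u`; every unit of `U` contributes its length even when
#' unused. The extended penalty adds the total length of uncovered segments,
#' so that rare error-induced segments are paid for by length instead of
#' inflating the unit inventory.
#'
#' @param d A `tr_decomposition`.
#' @param units Unit set to score against; defaults to the decomposition's
#'   own unit set. Every labelled segment of `d` must use a unit of `units`.
#' @return A one-row tibble with columns `penalty`, `extended_penalty`,
#'   `coverage` (covered length) and `uncovered_length`.
#' @export
penalty_of <- function(d, units = NULL) {
  if (!inherits(d, "tr_decomposition")) {
    abort("`d` must be a `tr_decomposition`.", class = "mosaictr_type_error")
  }
  units <- if (is.null(units)) d$units else check_units(units)
  labels <- d$segments$label
  outside <- setdiff(labels[!is.na(labels)], units)
  if (length(outside)) {
    abort(
      sprintf("decomposition uses a label outside the unit set: '%s'.",
              outside[1]),
      class = "mosaictr_label_error"
    )
  }
  occ <- table(factor(labels, levels = units))
  penalty <- sum(nchar(units)) + sum(occ)
  uncov <- d$uncovered_length
  tibble(
    penalty = as.integer(penalty),
    extended_penalty = as.integer(penalty + uncov),
    coverage = as.integer(d$covered_length),
    uncovered_length = as.integer(uncov)
  )
}

#' Minimum extended-penalty exact tiling for a fixed unit set
#'
#' Dynamic program over end positions: a position is either an uncovered
#' letter (cost 1) or the end of an exact occurrence of some unit (cost 1
#' per copy); the optimum plus the constant `sum(|u|)` is the minimum
#' extended penalty achievable with the unit set. Adjacent uncovered letters
#' are merged into single segments in the output. Ties are broken towards
#' larger covered length, then towards the longer matching unit.
#'
#' @param seq DNA sequence.
#' @param units Unit set (may be empty, in which case the whole sequence is
#'   one uncovered segment and the extended penalty is `n`).
#' @return A `tr_decomposition`: a list with the segment table
#'   (`segments`: `start`, `end`, `label`, where `NA` labels are uncovered),
#'   per-unit occurrence counts, covered/uncovered lengths, `penalty` and
#'   `extended_penalty`.
#' @examples
#' best_exact_decomposition("ACCGACCGACCG", "AC")$extended_penalty  # 11
#' @export
best_exact_decomposition <- function(seq, units = character()) {
  s <- dna_string(seq)
  units <- check_units(units)
  r <- cpp_exact_decompose(s, units)
  idx <- as.integer(r$unit_idx)
  label <- rep(NA_character_, length(idx))
  label[idx >= 0L] <- units[idx[idx >= 0L] + 1L]
  segments <- tibble(
    start = as.integer(r$start),
    end = as.integer(r$end),
    label = label
  )
  new_tr_decomposition(s, units, segments)
}

#' Greedy maximum-parsimony unit selection
#'
#' Starting from the empty unit set (extended penalty `n`), each round
#' scores every remaining candidate `v` by the extended penalty of
#' [best_exact_decomposition()] under `U + v`, adds the best candidate, and
#' stops when no candidate strictly decreases the extended penalty. Ties are
#' broken towards larger covered length, then the shorter unit, then the
#' lexicographically smaller text. Units left with zero occurrences by later
#' rounds are dropped at the end. The underlying joint optimisation of unit
#' set and tiling is believed intractable; the greedy result is an upper
#' bound on the true minimum extended penalty.
#'
#' @param seq DNA sequence.
#' @param candidates Candidate units: a character vector or the tibble
#'   returned by [enumerate_units()]. Defaults to
#'   `enumerate_units(seq, max_unit_len)`.
#' @param max_unit_len Maximum candidate unit length when `candidates` is
#'   NULL.
#' @return A `tr_selection`: list with `units` (in selection order),
#'   `decomposition` (the final [best_exact_decomposition()]), `penalty`
#'   (one-row tibble from [penalty_of()]) and `trace` (one row per greedy
#'   round: `round`, `unit`, `extended_penalty`).
#' @examples
#' greedy_select_units("ACCGACCGACCG")$units  # "ACCG"
#' @export
greedy_select_units <- function(seq, candidates = NULL, max_unit_len = 100) {
  s <- dna_string(seq)
  n <- nchar(s)
  if (is.null(candidates)) candidates <- enumerate_units(s, max_unit_len)
  cand <- if (is.data.frame(candidates)) candidates$text
          else as.character(candidates)
  cand <- unique(toupper(cand))

  u_sel <- character(0)
  best_ext <- n
  trace <- list()
  round <- 0L
  repeat {
    avail <- setdiff(cand, u_sel)
    if (length(avail) == 0L) break
    base_len <- sum(nchar(u_sel))
    ext <- integer(length(avail))
    cov <- integer(length(avail))
    for (i in seq_along(avail)) {
      r <- cpp_exact_decompose(s, c(u_sel, avail[i]))
      ext[i] <- base_len + nchar(avail[i]) + r$cost
      cov[i] <- r$covered
    }
    pick <- order(ext, -cov, nchar(avail), avail)[1]
    if (ext[pick] >= best_ext) break
    round <- round + 1L
    u_sel <- c(u_sel, avail[pick])
    best_ext <- ext[pick]
    trace[[round]] <- tibble(round = round, unit = avail[pick],
                             extended_penalty = ext[pick])
  }

  d <- best_exact_decomposition(s, u_sel)
  unused <- names(which(d$occurrences == 0L))
  if (length(unused)) {
    u_sel <- setdiff(u_sel, unused)
    d <- best_exact_decomposition(s, u_sel)
  }
  structure(
    list(
      seq = s, n = n, units = u_sel, decomposition = d,
      penalty = penalty_of(d),
      trace = if (length(trace)) dplyr::bind_rows(trace)
              else tibble(round = integer(), unit = character(),
                          extended_penalty = integer())
    ),
    class = "tr_selection"
  )
}
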