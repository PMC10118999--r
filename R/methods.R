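# print / tidy / glance / autoplot methods

#' @export
print.tr_decomposition <- function(x, ...) {
  cat(sprintf(
    "<tr_decomposition> n = %d, units = {%s}\n  penalty = %d, extended = %d, covered = %d/%d\n",
    x$n, paste(x$units, collapse = ", "), x$penalty, x$extended_penalty,
    x$covered_length, x$n))
  print(x$segments, ...)
  invisible(x)
}

#' @export
print.tr_approx <- function(x, ...) {
  cat(sprintf("<tr_approx> n = %d, units = {%s}, total edits = %d\n",
              x$n, paste(x$units, collapse = ", "), x$total_edits))
  print(x$segments, ...)
  invisible(x)
}

#' @export
print.tr_selection <- function(x, ...) {
  cat(sprintf(
    "<tr_selection> units = {%s}\n  extended penalty = %d (empty-set baseline %d)\n",
    paste(x$units, collapse = ", "), x$penalty$extended_penalty, x$n))
  invisible(x)
}

#' @export
print.tr_annotation <- function(x, ...) {
  writeLines(format_annotation(x))
  invisible(x)
}

#' Tidy segment / run / trace tables of result objects
#'
#' `tidy()` returns the per-segment (or per-run, or per-round) tibble of a
#' result; `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @name mosaictr-tidiers
NULL

#' @rdname mosaictr-tidiers
#' @method tidy tr_decomposition
#' @export
tidy.tr_decomposition <- function(x, ...) x$segments

#' @rdname mosaictr-tidiers
#' @method tidy tr_approx
#' @export
tidy.tr_approx <- function(x, ...) x$segments

#' @rdname mosaictr-tidiers
#' @method tidy tr_selection
#' @export
tidy.tr_selection <- function(x, ...) x$trace

#' @rdname mosaictr-tidiers
#' @method tidy tr_annotation
#' @export
tidy.tr_annotation <- function(x, ...) x$runs

#' @rdname mosaictr-tidiers
#' @method glance tr_decomposition
#' @export
glance.tr_decomposition <- function(x, ...) {
  dplyr::bind_cols(penalty_of(x), tibble(n = x$n, n_units = length(x$units)))
}

#' @rdname mosaictr-tidiers
#' @method glance tr_approx
#' @export
glance.tr_approx <- function(x, ...) {
  tibble(n = x$n, n_units = length(x$units),
         n_segments = nrow(x$segments), total_edits = x$total_edits)
}

#' @rdname mosaictr-tidiers
#' @method glance tr_selection
#' @export
glance.tr_selection <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n, n_units = length(x$units),
                          units = paste(x$units, collapse = ",")),
                   x$penalty)
}

#' @rdname mosaictr-tidiers
#' @method glance tr_annotation
#' @export
glance.tr_annotation <- function(x, ...) {
  tibble(
    id = x$id %||% NA_character_, n = x$n, pattern = x$pattern,
    n_units = length(x$units), n_runs = nrow(x$runs),
    total_edits = x$total_edits, is_mosaic = x$is_mosaic,
    coverage = x$coverage
  )
}

#' Plot benchmark accuracy
#'
#' Accuracy against sequencing-error rate, one panel per pattern, coloured
#' by allowance.
#'
#' @param object A `tr_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_benchmark
#' @export
autoplot.tr_benchmark <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$accuracy), ]
  df$allowance_pct <- factor(sprintf("%g%%", 100 * df$allowance))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$error_rate, y = .data$accuracy,
    colour = .data$allowance_pct, group = .data$allowance_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::labs(x = "sequencing error rate", y = "prediction accuracy",
                  colour = "allowance") +
    ggplot2::ylim(0, 1)
}

#' @importFrom rlang .data
NULL
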