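# full decomposition pipeline and the annotation text format

#' Decompose one tandem-repeat sequence
#'
#' Runs the full pipeline on a single sequence: enumerate candidate units
#' ([enumerate_units()]), select a parsimonious unit set
#' ([greedy_select_units()]), decompose error-tolerantly
#' ([approx_decompose()]), run-length encode, and classify
#' ([classify_mosaic()]). If no candidate unit exists (no repetitive
#' borderless substring), the annotation has an empty unit set and no runs.
#'
#' @param seq DNA sequence.
#' @param id Optional sequence identifier carried into the annotation.
#' @param max_unit_len Maximum candidate unit length (default 100).
#' @param coverage_threshold,min_tandem_copies See [classify_mosaic()].
#' @return A `tr_annotation` object: list with `id`, `seq`, `n`, `units`,
#'   `runs` (run-length tibble), `pattern` (text form such as
#'   `"(AAAG)6(AG)11(AAAG)20"`), `total_edits`, `is_mosaic`, `coverage`,
#'   plus the intermediate `selection` and `approx` objects.
#' @examples
#' decompose_tr("ACCGACCGACCG")$pattern  # "(ACCG)3"
#' @export
decompose_tr <- function(seq, id = NULL, max_unit_len = 100,
                         coverage_threshold = 0.8, min_tandem_copies = 2) {
  s <- dna_string(seq)
  n <- nchar(s)
  sel <- greedy_select_units(s, max_unit_len = max_unit_len)
  if (length(sel$units)) {
    ap <- approx_decompose(s, sel$units)
    runs <- run_length_encode(ap)
    cls <- classify_mosaic(ap, coverage_threshold, min_tandem_copies)
    total_edits <- ap$total_edits
  } else {
    ap <- NULL
    runs <- run_length_encode(sel$decomposition)[0, ]
    cls <- tibble(is_mosaic = FALSE, coverage = 0L, n = n,
                  coverage_threshold = coverage_threshold)
    total_edits <- NA_integer_
  }
  structure(
    list(
      id = id, seq = s, n = n, units = sel$units,
      runs = runs, pattern = format_pattern(runs),
      total_edits = total_edits,
      is_mosaic = cls$is_mosaic, coverage = cls$coverage,
      coverage_threshold = coverage_threshold,
      min_tandem_copies = min_tandem_copies,
      selection = sel, approx = ap
    ),
    class = "tr_annotation"
  )
}

#' Decompose every sequence of a table
#'
#' Data-frame-first wrapper around [decompose_tr()]: takes a tibble with a
#' sequence column (such as the output of [read_fasta()]) and returns one
#' row per sequence.
#'
#' @param data A data frame with the sequences.
#' @param seq_col,id_col Column names holding sequence and identifier.
#' @param ... Passed on to [decompose_tr()].
#' @return A tibble with columns `id`, `n`, `pattern`, `n_units`, `units`
#'   (list-column), `total_edits`, `is_mosaic`, `coverage` and `annotation`
#'   (list-column of `tr_annotation` objects).
#' @examples
#' tibble::tibble(id = "x", seq = "ACCGACCGACCG") |> tr_decompose()
#' @export
tr_decompose <- function(data, seq_col = "seq", id_col = "id", ...) {
  if (!is.data.frame(data) || !seq_col %in% names(data)) {
    abort(sprintf("`data` must be a data frame with a '%s' column.", seq_col),
          class = "mosaictr_type_error")
  }
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]])
         else sprintf("seq%d", seq_len(nrow(data)))
  anns <- purrr::map2(data[[seq_col]], ids,
                      function(s, i) decompose_tr(s, id = i, ...))
  dplyr::bind_cols(
    tibble(id = ids),
    purrr::map_dfr(anns, function(a) {
      tibble(
        n = a$n, pattern = a$pattern, n_units = length(a$units),
        units = list(a$units), total_edits = a$total_edits,
        is_mosaic = a$is_mosaic, coverage = a$coverage
      )
    }),
    tibble(annotation = anns)
  )
}

#' Mosaic pattern text form
#'
#' `format_pattern()` renders a run-length table as `"(AC)20(AG)30"`;
#' `parse_pattern()` inverts it; `render_pattern()` expands it to the DNA
#' sequence.
#'
#' @param runs A tibble with columns `unit` and `copies` (extra columns are
#'   ignored), or for `parse_pattern()` a pattern string.
#' @return `format_pattern()`: a string; `parse_pattern()`: a tibble with
#'   `unit` and `copies`; `render_pattern()`: the expanded sequence.
#' @examples
#' parse_pattern("(AC)20(AG)30")
#' @export
format_pattern <- function(runs) {
  if (nrow(runs) == 0L) return("")
  if (anyNA(runs$unit)) {
    abort("pattern notation requires fully covered runs (no NA units).",
          class = "mosaictr_pattern_error")
  }
  paste0("(", runs$unit, ")", runs$copies, collapse = "")
}

#' @rdname format_pattern
#' @param pattern A pattern string such as `"(AC)20(AG)30"`.
#' @export
parse_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L) {
    abort("`pattern` must be a single string.", class = "mosaictr_type_error")
  }
  if (!nzchar(pattern)) return(tibble(unit = character(), copies = integer()))
  m <- gregexpr("\\(([ACGTN]+)\\)([0-9]+)", pattern, perl = TRUE)[[1]]
  hits <- regmatches(pattern, gregexpr("\\(([ACGTN]+)\\)([0-9]+)",
                                       pattern, perl = TRUE))[[1]]
  if (m[1] == -1 ||
      sum(attr(m, "match.length")) != nchar(pattern)) {
    abort(sprintf("not a valid pattern string: '%s'.", pattern),
          class = "mosaictr_pattern_error")
  }
  tibble(
    unit = sub("^\\(([ACGTN]+)\\).*$", "\\1", hits),
    copies = as.integer(sub("^.*\\)([0-9]+)$", "\\1", hits))
  )
}

#' @rdname format_pattern
#' @export
render_pattern <- function(runs) {
  if (is.character(runs)) runs <- parse_pattern(runs)
  paste(strrep(runs$unit, runs$copies), collapse = "")
}

#' Annotation text format
#'
#' `format_annotation()` serialises a `tr_annotation` as plain text: a
#' `>id` header line, key/value lines (`pattern`, `length`, `units`,
#' `edits`, `mosaic`, `coverage`) and one `run` line per run with BED-like
#' 0-based half-open coordinates (`run<TAB>unit<TAB>start<TAB>end<TAB>copies
#' <TAB>edits`). `parse_annotation()` reads one or more such records back.
#'
#' @param ann A `tr_annotation`.
#' @return `format_annotation()`: a character vector of lines;
#'   `parse_annotation()`: a list of records, each a list with `id`,
#'   `pattern`, `n`, `units`, `total_edits`, `is_mosaic`, `coverage` and a
#'   `runs` tibble.
#' @export
format_annotation <- function(ann) {
  if (!inherits(ann, "tr_annotation")) {
    abort("`ann` must be a `tr_annotation`.", class = "mosaictr_type_error")
  }
  runs <- ann$runs
  c(
    paste0(">", ann$id %||% "unnamed"),
    paste0("pattern\t", ann$pattern),
    paste0("length\t", ann$n),
    paste0("units\t", paste(ann$units, collapse = ",")),
    paste0("edits\t", ann$total_edits),
    paste0("mosaic\t", ann$is_mosaic),
    paste0("coverage\t", ann$coverage),
    if (nrow(runs)) {
      paste("run", runs$unit, runs$start, runs$end, runs$copies,
            runs$edits, sep = "\t")
    }
  )
}

#' @rdname format_annotation
#' @param lines Character vector of annotation lines (possibly several
#'   records), or a file path via `read_annotations()`.
#' @export
parse_annotation <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)
  int1 <- function(x) suppressWarnings(as.integer(x))
  lapply(seq_along(starts), function(i) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    kv <- strsplit(block[-1], "\t", fixed = TRUE)
    keys <- vapply(kv, `[[`, "", 1L)
    val <- function(key) {
      hit <- which(keys == key)
      if (length(hit)) kv[[hit[1]]][2] else NA_character_
    }
    run_rows <- kv[keys == "run"]
    runs <- if (length(run_rows)) {
      tibble(
        unit = vapply(run_rows, `[[`, "", 2L),
        copies = int1(vapply(run_rows, `[[`, "", 5L)),
        start = int1(vapply(run_rows, `[[`, "", 3L)),
        end = int1(vapply(run_rows, `[[`, "", 4L)),
        edits = int1(vapply(run_rows, `[[`, "", 6L))
      )
    } else {
      tibble(unit = character(), copies = integer(), start = integer(),
             end = integer(), edits = integer())
    }
    units <- val("units")
    list(
      id = substring(block[1], 2L),
      pattern = val("pattern") %||% "",
      n = int1(val("length")),
      units = if (is.na(units) || !nzchar(units)) character()
              else strsplit(units, ",", fixed = TRUE)[[1]],
      total_edits = int1(val("edits")),
      is_mosaic = as.logical(val("mosaic")),
      coverage = int1(val("coverage")),
      runs = runs
    )
  })
}

#' @rdname format_annotation
#' @param anns A list of `tr_annotation` objects (or the `annotation`
#'   list-column of [tr_decompose()] output).
#' @param path Output / input file path.
#' @export
write_annotations <- function(anns, path) {
  if (inherits(anns, "tr_annotation")) anns <- list(anns)
  writeLines(unlist(lapply(anns, format_annotation)), path)
  invisible(path)
}

#' @rdname format_annotation
#' @export
read_annotations <- function(path) {
  parse_annotation(readLines(path, warn = FALSE))
}
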