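# synthetic mosaic tandem-repeat benchmark

#' Built-in mosaic benchmark patterns
#'
#' The eight mosaic pattern templates used by the synthetic benchmark,
#' spanning two to five runs and unit lengths from 2 to 15 bases:
#' (a) (AC)i(AG)j, (b) (ACC)i(GTT)j, (c) (AAG)i(AG)j, (d) (AAG)i(AGG)j,
#' (e) (AAAG)i(AG)j, (f) (AAAG)i(AG)j(AAAG)k,
#' (g) (AAAG)i(AG)j(AGGG)k(AG)l(AAAG)m,
#' (h) (AAAAAG)i(AAAGAGAGGGAAAAG)j(AGGGG)k.
#' All template units are non-self-overlapping.
#'
#' @return A tibble with columns `pattern` (letters a-h) and `units`
#'   (list-column of the ordered run units).
#' @export
builtin_patterns <- function() {
  tibble(
    pattern = letters[1:8],
    units = list(
      c("AC", "AG"),
      c("ACC", "GTT"),
      c("AAG", "AG"),
      c("AAG", "AGG"),
      c("AAAG", "AG"),
      c("AAAG", "AG", "AAAG"),
      c("AAAG", "AG", "AGGG", "AG", "AAAG"),
      c("AAAAAG", "AAAGAGAGGGAAAAG", "AGGGG")
    )
  )
}

# run templates may reuse a unit in non-adjacent runs (patterns f and g),
# so this is weaker than check_units()
pattern_units <- function(pattern) {
  pats <- builtin_patterns()
  if (is.character(pattern) && length(pattern) == 1L &&
      pattern %in% pats$pattern) {
    return(pats$units[[match(pattern, pats$pattern)]])
  }
  units <- toupper(as.character(pattern))
  if (length(units) == 0L || anyNA(units) || any(!nzchar(units)) ||
      any(grepl("[^ACGTN]", units))) {
    abort("run units must be non-empty DNA strings.",
          class = "mosaictr_type_error")
  }
  units
}

#' Instantiate a mosaic pattern with random copy counts
#'
#' Draws one copy count per run uniformly from `[count_low, count_high]`
#' and renders the concatenated sequence. Adjacent runs must use distinct
#' units.
#'
#' @param template A pattern letter (`"a"`..`"h"`, see [builtin_patterns()])
#'   or a character vector of ordered run units.
#' @param count_low,count_high Copy-count bounds (defaults 10 and 200).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with `runs` (tibble `unit`, `copies`), `seq` and
#'   `pattern` (text form).
#' @examples
#' instantiate_pattern("a", seed = 1)$pattern
#' @export
instantiate_pattern <- function(template, count_low = 10, count_high = 200,
                                seed = NULL) {
  units <- pattern_units(template)
  k <- length(units)
  if (k > 1 && any(units[-1] == units[-k])) {
    abort("adjacent runs must use distinct units.",
          class = "mosaictr_pattern_error")
  }
  if (!is.numeric(count_low) || !is.numeric(count_high) ||
      count_low < 1 || count_low > count_high) {
    abort("need 1 <= count_low <= count_high.",
          class = "mosaictr_argument_error")
  }
  copies <- with_seed(seed, {
    count_low + sample.int(count_high - count_low + 1L, k, replace = TRUE) - 1L
  })
  runs <- tibble(unit = units, copies = as.integer(copies))
  list(runs = runs, seq = render_pattern(runs), pattern = format_pattern(runs))
}

#' Inject sequencing errors into a sequence
#'
#' Each base is independently hit with probability `rate`; a hit is a
#' substitution (to a uniformly chosen different base), an insertion of a
#' uniform base after the position, or a deletion, with probabilities
#' `mix` (uniform thirds by default).
#'
#' @param seq DNA sequence.
#' @param rate Per-base error probability in `[0, 1)`.
#' @param mix Length-3 numeric: relative probabilities of substitution,
#'   insertion, deletion; normalised to sum to 1.
#' @param seed Optional RNG seed.
#' @return The mutated sequence (a character scalar).
#' @export
inject_errors <- function(seq, rate, mix = c(sub = 1, ins = 1, del = 1) / 3,
                          seed = NULL) {
  s <- dna_string(seq)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    abort("`rate` must be in [0, 1).", class = "mosaictr_argument_error")
  }
  if (length(mix) != 3L || any(mix < 0) || sum(mix) <= 0) {
    abort("`mix` must be 3 nonnegative weights.",
          class = "mosaictr_argument_error")
  }
  mix <- mix / sum(mix)
  if (rate == 0) return(s)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    hit <- runif(n) < rate
    nh <- sum(hit)
    if (nh > 0L) {
      ops <- sample.int(3L, nh, replace = TRUE, prob = mix)
      out <- chars
      idx <- which(hit)
      for (t in seq_len(nh)) {
        i <- idx[t]
        if (ops[t] == 1L) {                       # substitution
          out[i] <- sample(setdiff(bases, chars[i]), 1L)
        } else if (ops[t] == 2L) {                # insertion
          out[i] <- paste0(chars[i], sample(bases, 1L))
        } else {                                  # deletion
          out[i] <- ""
        }
      }
      chars <- out
    }
    paste(chars, collapse = "")
  })
}

#' Score a predicted run-length pattern against the truth
#'
#' A prediction is accurate iff it has exactly the same ordered list of
#' run units as the truth and each run's predicted copy count `c'`
#' satisfies `|c' - c| <= allowance * c`. Any structural mismatch (missing,
#' extra or reordered runs; a different unit string, rotations included)
#' counts as inaccurate.
#'
#' @param truth,predicted Run-length tables (tibbles with `unit` and
#'   `copies`) or pattern strings such as `"(AC)20(AG)30"`.
#' @param allowance Copy-count tolerance as a fraction of the true count
#'   (0.02 = "2% allowance"; default 0 = exact).
#' @return `TRUE` or `FALSE`.
#' @examples
#' evaluate_prediction("(AC)100(AG)30", "(AC)98(AG)30", allowance = 0.02)
#' @export
evaluate_prediction <- function(truth, predicted, allowance = 0) {
  if (!is.numeric(allowance) || length(allowance) != 1L || allowance < 0) {
    abort("`allowance` must be a nonnegative fraction.",
          class = "mosaictr_argument_error")
  }
  tr <- if (is.character(truth)) parse_pattern(truth) else truth
  pr <- if (is.character(predicted)) parse_pattern(predicted) else predicted
  if (nrow(tr) != nrow(pr)) return(FALSE)
  if (nrow(tr) == 0L) return(TRUE)
  if (anyNA(pr$unit) || any(tr$unit != pr$unit)) return(FALSE)
  all(abs(pr$copies - tr$copies) <= allowance * tr$copies)
}

#' Generate one benchmark dataset
#'
#' Draws `n_records` instances of a mosaic pattern with uniform copy
#' counts, stores the truth, and injects sequencing errors at `error_rate`.
#' Generation is bit-reproducible under `seed`.
#'
#' @inheritParams instantiate_pattern
#' @inheritParams inject_errors
#' @param error_rate Per-base error probability.
#' @param n_records Number of strings to generate.
#' @return A tibble with columns `record`, `pattern` (truth text form),
#'   `truth` (list-column of run tables), `clean_seq` and `seq`.
#' @export
make_benchmark_dataset <- function(template, error_rate = 0, n_records = 100,
                                   count_low = 10, count_high = 200,
                                   mix = c(1, 1, 1) / 3, seed = NULL) {
  units <- pattern_units(template)
  with_seed(seed, {
    recs <- lapply(seq_len(n_records), function(i) {
      inst <- instantiate_pattern(units, count_low, count_high)
      err <- inject_errors(inst$seq, error_rate, mix)
      tibble(record = i, pattern = inst$pattern, truth = list(inst$runs),
             clean_seq = inst$seq, seq = err)
    })
    dplyr::bind_rows(recs)
  })
}

#' Run the synthetic benchmark
#'
#' For each pattern and error rate, generates a dataset, runs the full
#' decomposition pipeline on every record, and reports the fraction of
#' records whose run-length prediction is accurate at each allowance
#' ([evaluate_prediction()]), together with the mean compression ratio
#' ([compression_ratio()]) of the dataset.
#'
#' @param patterns Pattern letters (see [builtin_patterns()]).
#' @param error_rates Per-base error probabilities.
#' @param n_records Strings per dataset.
#' @param allowances Copy-count tolerances (fractions).
#' @param count_low,count_high Copy-count bounds.
#' @param mix Error-type mix, see [inject_errors()].
#' @param max_unit_len Maximum candidate unit length.
#' @param theta Substring-census length bound for the compression ratio.
#' @param decompose If `FALSE`, skip decomposition and report only
#'   compression statistics (one row per dataset, `allowance`/`accuracy`
#'   `NA`).
#' @param compression If `FALSE`, skip the compression census.
#' @param seed RNG seed for the whole run.
#' @param verbose Print per-dataset progress messages.
#' @return A `tr_benchmark` tibble: one row per (pattern, error rate,
#'   allowance) with columns `pattern`, `error_rate`, `allowance`, `n`,
#'   `accuracy`, `mean_compression_ratio`.
#' @export
run_benchmark <- function(patterns = letters[1:8],
                          error_rates = c(0, 0.01, 0.03, 0.05, 0.10, 0.15),
                          n_records = 100, allowances = c(0, 0.02),
                          count_low = 10, count_high = 200,
                          mix = c(1, 1, 1) / 3,
                          max_unit_len = 100, theta = 20,
                          decompose = TRUE, compression = TRUE,
                          seed = NULL, verbose = FALSE) {
  pats <- builtin_patterns()
  if (!all(patterns %in% pats$pattern)) {
    abort("unknown pattern id; use letters a-h.",
          class = "mosaictr_argument_error")
  }
  rows <- list()
  with_seed(seed, {
    for (p in patterns) {
      for (rate in error_rates) {
        ds <- make_benchmark_dataset(p, rate, n_records,
                                     count_low, count_high, mix)
        comp <- if (compression) {
          mean(vapply(ds$seq,
                      function(s) compression_ratio(s, theta)$ratio,
                      numeric(1)))
        } else NA_real_
        if (decompose) {
          hits <- matrix(FALSE, n_records, length(allowances))
          for (i in seq_len(n_records)) {
            ann <- decompose_tr(ds$seq[i], max_unit_len = max_unit_len)
            for (a in seq_along(allowances)) {
              hits[i, a] <- evaluate_prediction(ds$truth[[i]], ann$runs,
                                                allowances[a])
            }
          }
          for (a in seq_along(allowances)) {
            rows[[length(rows) + 1L]] <- tibble(
              pattern = p, error_rate = rate, allowance = allowances[a],
              n = n_records, accuracy = mean(hits[, a]),
              mean_compression_ratio = comp
            )
          }
        } else {
          rows[[length(rows) + 1L]] <- tibble(
            pattern = p, error_rate = rate, allowance = NA_real_,
            n = n_records, accuracy = NA_real_,
            mean_compression_ratio = comp
          )
        }
        if (verbose) {
          message(sprintf("pattern %s, rate %.2f done", p, rate))
        }
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tr_benchmark", class(out))
  out
}

#' Write a benchmark dataset as FASTA
#'
#' Record headers carry the ground truth, e.g.
#' `>a_0.03_1 pattern=(AC)20(AG)30 rate=0.03`.
#'
#' @param dataset Output of [make_benchmark_dataset()].
#' @param path Output path.
#' @param prefix Header prefix (default `"rec"`).
#' @param error_rate Rate recorded in the headers (default `NA`).
#' @return `path`, invisibly.
#' @export
write_benchmark_fasta <- function(dataset, path, prefix = "rec",
                                  error_rate = NA) {
  ids <- sprintf("%s_%d pattern=%s rate=%s", prefix, dataset$record,
                 dataset$pattern, format(error_rate))
  write_fasta(tibble(id = ids, seq = dataset$seq), path)
}
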