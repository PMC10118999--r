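# synthetic benchmark: patterns, error injection, scoring, reports

test_that("the eight built-in templates have the documented structure", {
  pats <- builtin_patterns()
  expect_equal(pats$pattern, letters[1:8])
  expect_equal(pats$units[[1]], c("AC", "AG"))
  expect_equal(lengths(pats$units), c(2L, 2L, 2L, 2L, 2L, 3L, 5L, 3L))
  expect_equal(pats$units[[7]], c("AAAG", "AG", "AGGG", "AG", "AAAG"))
  # every template unit is non-self-overlapping except the 15-mer of (h),
  # whose prefix and suffix share AAAG
  for (us in pats$units) {
    expect_true(all(vapply(setdiff(us, "AAAGAGAGGGAAAAG"),
                           is_borderless, logical(1))))
  }
  expect_false(is_borderless("AAAGAGAGGGAAAAG"))
})

test_that("instantiation renders the right lengths, reproducibly", {
  inst <- instantiate_pattern("a", count_low = 20, count_high = 20)
  expect_equal(nchar(inst$seq), 2 * 20 + 2 * 20)

  h <- instantiate_pattern("h", count_low = 200, count_high = 200)
  expect_equal(nchar(h$seq), 200 * 6 + 200 * 15 + 200 * 5)  # 5200

  i1 <- instantiate_pattern("g", seed = 99)
  i2 <- instantiate_pattern("g", seed = 99)
  expect_identical(i1$seq, i2$seq)
  expect_true(all(i1$runs$copies >= 10 & i1$runs$copies <= 200))
  expect_equal(render_pattern(i1$runs), i1$seq)
  expect_error(instantiate_pattern("a", count_low = 5, count_high = 2),
               class = "mosaictr_argument_error")
})

test_that("mean instantiated length matches the closed-form expectation", {
  set.seed(71)
  lens <- replicate(300, nchar(instantiate_pattern("a")$seq))
  # E[len] = (2 + 2) * mean(10:200) = 4 * 105 = 420; sd ~ 155
  expect_lt(abs(mean(lens) - 420), 40)
})

test_that("error injection respects rate, mix and seed", {
  s <- strrep("ACGT", 25)
  expect_identical(inject_errors(s, 0), s)

  e1 <- inject_errors(s, 0.1, seed = 3)
  e2 <- inject_errors(s, 0.1, seed = 3)
  expect_identical(e1, e2)

  # substitution-only: length preserved
  sub_only <- inject_errors(s, 0.5, mix = c(1, 0, 0), seed = 5)
  expect_equal(nchar(sub_only), nchar(s))
  # deletion-only: length can only shrink
  del_only <- inject_errors(s, 0.5, mix = c(0, 0, 1), seed = 5)
  expect_lte(nchar(del_only), nchar(s))

  # number of edit events concentrates around n * rate (binomial, 4 sigma)
  big <- strrep("A", 10000)
  hit <- inject_errors(big, 0.15, mix = c(1, 0, 0), seed = 7)
  nsub <- sum(strsplit(hit, "")[[1]] != "A")
  sigma <- sqrt(10000 * 0.15 * 0.85)
  expect_lt(abs(nsub - 1500), 4 * sigma)
})

test_that("prediction scoring follows the allowance rule", {
  truth <- runs_tbl(c("AC", "AG"), c(20, 30))
  expect_true(evaluate_prediction(truth, runs_tbl(c("AC", "AG"), c(20, 30))))
  expect_true(evaluate_prediction("(AC)100", "(AC)98", allowance = 0.02))
  expect_false(evaluate_prediction("(AC)100", "(AC)97", allowance = 0.02))
  # structural mismatch never passes
  expect_false(evaluate_prediction(runs_tbl(c("AAAG", "AG", "AAAG"),
                                            c(5, 5, 5)),
                                   runs_tbl("AAAG", 15), allowance = 1))
  # all runs must pass, not just some
  expect_false(evaluate_prediction(truth, runs_tbl(c("AC", "AG"), c(20, 40))))
})

test_that("datasets are reproducible and store truth before errors", {
  d1 <- make_benchmark_dataset("b", error_rate = 0.05, n_records = 5, seed = 13)
  d2 <- make_benchmark_dataset("b", error_rate = 0.05, n_records = 5, seed = 13)
  expect_identical(d1$seq, d2$seq)
  expect_identical(d1$pattern, d2$pattern)
  for (i in seq_len(5)) {
    expect_identical(render_pattern(d1$truth[[i]]), d1$clean_seq[i])
  }
  d0 <- make_benchmark_dataset("a", error_rate = 0, n_records = 3, seed = 2)
  expect_identical(d0$seq, d0$clean_seq)
})

test_that("benchmark FASTA round-trips with truth in the header", {
  ds <- make_benchmark_dataset("a", 0, n_records = 3, seed = 4)
  f <- withr::local_tempfile(fileext = ".fa")
  write_benchmark_fasta(ds, f, prefix = "a0", error_rate = 0)
  back <- read_fasta(f)
  expect_equal(nrow(back), 3L)
  expect_identical(back$seq, ds$seq)
  expect_match(back$desc[1], "pattern=\\(AC\\)[0-9]+\\(AG\\)[0-9]+")
})

test_that("the pipeline recovers clean mosaic patterns end to end", {
  ds <- make_benchmark_dataset("c", 0, n_records = 6, seed = 21,
                               count_low = 10, count_high = 40)
  for (i in seq_len(6)) {
    ann <- decompose_tr(ds$seq[i])
    expect_true(evaluate_prediction(ds$truth[[i]], ann$runs, 0),
                info = ds$pattern[i])
  }
})

test_that("run_benchmark reports accuracy and compression per dataset", {
  rep1 <- run_benchmark(patterns = c("a", "b"), error_rates = c(0, 0.03),
                        n_records = 5, allowances = c(0, 0.02),
                        count_low = 10, count_high = 30, seed = 8)
  expect_s3_class(rep1, "tr_benchmark")
  expect_equal(nrow(rep1), 2 * 2 * 2)
  expect_true(all(rep1$accuracy >= 0 & rep1$accuracy <= 1))
  expect_true(all(rep1$mean_compression_ratio > 0 &
                    rep1$mean_compression_ratio <= 1))
  # allowance relaxation is monotone on every dataset
  wide <- split(rep1, list(rep1$pattern, rep1$error_rate))
  for (g in wide) {
    g <- g[order(g$allowance), ]
    expect_true(all(diff(g$accuracy) >= 0))
  }
  # clean datasets decompose exactly
  expect_true(all(rep1$accuracy[rep1$error_rate == 0] == 1))

  rep2 <- run_benchmark(patterns = c("a", "b"), error_rates = c(0, 0.03),
                        n_records = 5, allowances = c(0, 0.02),
                        count_low = 10, count_high = 30, seed = 8)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("autoplot produces a ggplot of the benchmark report", {
  rep1 <- run_benchmark(patterns = "a", error_rates = 0, n_records = 2,
                        count_low = 10, count_high = 15, seed = 3)
  expect_s3_class(autoplot(rep1), "ggplot")
})
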