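# penalty, extended penalty, exact tiling DP and greedy unit selection

S_RUN <- "ACCGACCGACCG"
U_RUN <- c("ACCG", "AC", "CG", "CGAC")

test_that("penalty of hand-written decompositions matches the definition", {
  d1 <- manual_decomposition(S_RUN, rep("ACCG", 3), U_RUN)
  d2 <- manual_decomposition(S_RUN, rep(c("AC", "CG"), 3), U_RUN)
  d3 <- manual_decomposition(S_RUN, c("AC", "CGAC", "CGAC", "CG"), U_RUN)
  expect_equal(penalty_of(d1)$penalty, 15L)  # (4+3)+(2+0)+(2+0)+(4+0)
  expect_equal(penalty_of(d2)$penalty, 18L)
  expect_equal(penalty_of(d3)$penalty, 16L)
  # unused units eliminated: U = {ACCG} alone
  expect_equal(penalty_of(d1, "ACCG")$penalty, 7L)
  # fully covered: extended penalty equals penalty
  expect_equal(penalty_of(d1)$extended_penalty, 15L)
  expect_equal(penalty_of(d1)$coverage, 12L)
})

test_that("labels outside the scoring unit set are rejected", {
  d <- manual_decomposition(S_RUN, rep("ACCG", 3), U_RUN)
  expect_error(penalty_of(d, c("AC", "CG")), class = "mosaictr_label_error")
})

test_that("pieces must tile the sequence exactly", {
  expect_error(manual_decomposition("ACGT", c("AC", "G")),
               class = "mosaictr_tiling_error")
})

test_that("exact DP reproduces the single-unit extended penalties", {
  expect_equal(best_exact_decomposition(S_RUN, "ACCG")$extended_penalty, 7L)
  expect_equal(best_exact_decomposition(S_RUN, "AC")$extended_penalty, 11L)
  expect_equal(best_exact_decomposition(S_RUN, "CG")$extended_penalty, 11L)
  expect_equal(best_exact_decomposition(S_RUN, "CGAC")$extended_penalty, 10L)

  # U = {AC}: three CG stretches are uncovered
  d <- best_exact_decomposition(S_RUN, "AC")
  expect_equal(d$occurrences[["AC"]], 3L)
  expect_equal(d$uncovered_length, 6L)

  # empty unit set: one merged uncovered segment, extended penalty n
  d0 <- best_exact_decomposition("ACGTACGT", character())
  expect_equal(d0$extended_penalty, 8L)
  expect_equal(nrow(d0$segments), 1L)
  expect_true(is.na(d0$segments$label))
})

test_that("segments tile [0, n) and bookkeeping is consistent", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(sample(5:40, 1), c("A", "C", "G"))
    units <- unique(replicate(2, random_dna(sample(1:3, 1), c("A", "C", "G"))))
    d <- best_exact_decomposition(s, units)
    seg <- d$segments
    expect_equal(seg$start[1], 0L)
    expect_equal(seg$end[nrow(seg)], nchar(s))
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    expect_equal(d$covered_length + d$uncovered_length, nchar(s))
    expect_equal(d$extended_penalty, penalty_of(d)$extended_penalty)
    lab <- seg$label
    expect_true(all(substring(s, seg$start + 1, seg$end)[!is.na(lab)]
                    == lab[!is.na(lab)]))
  }
})

test_that("exact DP equals exhaustive tiling search on small instances", {
  set.seed(23)
  for (rep in 1:40) {
    s <- random_dna(sample(4:15, 1), c("A", "C"))
    k <- sample(1:3, 1)
    units <- unique(replicate(k, random_dna(sample(1:4, 1), c("A", "C"))))
    expect_equal(best_exact_decomposition(s, units)$extended_penalty,
                 brute_min_extended(s, units), info = paste(s, toString(units)))
  }
})

test_that("DP extended penalty is never beaten by a hand-constructed tiling", {
  d2 <- manual_decomposition(S_RUN, rep(c("AC", "CG"), 3), U_RUN)
  d3 <- manual_decomposition(S_RUN, c("AC", "CGAC", "CGAC", "CG"), U_RUN)
  dp <- best_exact_decomposition(S_RUN, U_RUN)
  expect_lte(dp$extended_penalty, penalty_of(d2)$extended_penalty)
  expect_lte(dp$extended_penalty, penalty_of(d3)$extended_penalty)
})

test_that("greedy selection reproduces the running example", {
  sel <- greedy_select_units(S_RUN)
  expect_equal(sel$units, "ACCG")
  expect_equal(sel$penalty$extended_penalty, 7L)
  expect_equal(nrow(sel$trace), 1L)
})

test_that("greedy trace is strictly decreasing and bounded by n rounds", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_dna(sample(10:60, 1), c("A", "G"))
    sel <- greedy_select_units(s)
    tr <- sel$trace$extended_penalty
    expect_true(all(diff(c(nchar(s), tr)) < 0))
    expect_lte(nrow(sel$trace), nchar(s))
  }
})

test_that("greedy recovers the unit of a perfect single-unit repeat", {
  # |u| >= 2: for a homopolymer (u = "A", n = k) the unit set {A} scores
  # k + 1 > n, so no unit strictly decreases the extended penalty and the
  # parsimony objective itself prefers the empty unit set
  set.seed(17)
  units <- c("AC", "AAG", "ACCG", "AATAG", "ACCGAGTTCG")
  for (u in units) {
    k <- sample(3:12, 1)
    sel <- greedy_select_units(strrep(u, k))
    expect_equal(sel$units, u)
    expect_equal(sel$penalty$extended_penalty, nchar(u) + k)
  }
})

test_that("greedy is an upper bound on the exhaustive subset optimum", {
  set.seed(37)
  for (rep in 1:12) {
    s <- random_dna(sample(6:12, 1), c("A", "C"))
    cand <- enumerate_units(s)$text
    if (length(cand) > 10) cand <- cand[1:10]
    sel <- greedy_select_units(s, candidates = cand)
    subsets_min <- nchar(s)  # empty set baseline
    if (length(cand)) {
      for (bits in 1:(2^length(cand) - 1)) {
        sub <- cand[bitwAnd(bits, 2^(seq_along(cand) - 1)) > 0]
        subsets_min <- min(subsets_min,
                           best_exact_decomposition(s, sub)$extended_penalty)
      }
    }
    expect_gte(sel$penalty$extended_penalty, subsets_min)
  }
})

test_that("ambiguous repeat: both optimal decompositions score 14", {
  s <- "AGAGAGGGAGGGAGAGAGGGAGGG"
  pA <- penalty_of(manual_decomposition(
    s, c("AG", "AG", "AGGG", "AGGG", "AG", "AG", "AGGG", "AGGG"),
    c("AG", "AGGG")))
  pB <- penalty_of(manual_decomposition(
    s, rep("AGAGAGGGAGGG", 2), "AGAGAGGGAGGG"))
  expect_equal(pA$penalty, 14L)
  expect_equal(pB$penalty, 14L)
  expect_equal(greedy_select_units(s)$penalty$extended_penalty, 14L)
})
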