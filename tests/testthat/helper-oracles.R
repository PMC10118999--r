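# brute-force oracles, independent of the package's C++ implementations

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# lexicographic sort of all suffixes (C locale via radix order), 0-based
brute_sa <- function(s) {
  n <- nchar(s)
  order(substring(s, 1:n, n), method = "radix") - 1L
}

brute_lcp_pair <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < m && substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) {
    k <- k + 1L
  }
  k
}

# lcp[i] = LCP of adjacent sorted suffixes
brute_lcp <- function(s) {
  n <- nchar(s)
  if (n < 2) return(integer(0))
  sufs <- sort(substring(s, 1:n, n), method = "radix")
  vapply(seq_len(n - 1),
         function(i) brute_lcp_pair(sufs[i], sufs[i + 1]), integer(1))
}

# len[i+1] = longest substring starting at 0-based i occurring >= 2 times
# (overlapping occurrences count)
brute_len <- function(s) {
  n <- nchar(s)
  len <- integer(n)
  for (l in seq_len(n - 1)) {
    subs <- substring(s, 1:(n - l + 1), l:n)
    rep_start <- subs %in% subs[duplicated(subs)]
    len[which(rep_start)] <- l
  }
  len
}

# longest proper border of each prefix of t
brute_border <- function(t) {
  m <- nchar(t)
  vapply(seq_len(m), function(k) {
    for (l in (k - 1):0) {
      if (l == 0 ||
          substr(t, 1, l) == substr(t, k - l + 1, k)) return(l)
    }
    0L
  }, integer(1))
}

is_borderless <- function(t) {
  b <- brute_border(t)
  b[length(b)] == 0L
}

# definition-based candidate set: distinct substrings, length <= max_len,
# occurring >= 2 times, zero proper border
brute_units <- function(s, max_len = 100) {
  n <- nchar(s)
  out <- character(0)
  for (l in seq_len(min(max_len, n - 1))) {
    subs <- substring(s, 1:(n - l + 1), l:n)
    reps <- unique(subs[subs %in% subs[duplicated(subs)]])
    reps <- reps[!grepl("N", reps, fixed = TRUE)]
    out <- c(out, reps[vapply(reps, is_borderless, logical(1))])
  }
  sort(out)
}

# exhaustive minimum extended penalty over all tilings (plain recursion,
# no shared machinery with the package DP); n <= ~15
brute_min_extended <- function(s, units) {
  n <- nchar(s)
  rec <- function(b) {
    if (b == n) return(0L)
    best <- 1L + rec(b + 1L)
    for (u in units) {
      m <- nchar(u)
      if (b + m <= n && substr(s, b + 1, b + m) == u) {
        best <- min(best, 1L + rec(b + m))
      }
    }
    best
  }
  sum(nchar(units)) + rec(0L)
}

# exhaustive minimum edit distance of s over the wraparound language:
# infix(u), or suffix(u_a) + complete copies + prefix(u_b); utils::adist
# is the independent Levenshtein oracle
brute_wraparound_dist <- function(s, units, max_copies = NULL) {
  n <- nchar(s)
  cap <- n + 2L * max(nchar(units))  # longer references are never optimal
  if (is.null(max_copies)) {
    max_copies <- ceiling(cap / min(nchar(units))) + 1L
  }
  sufs <- unique(unlist(lapply(units, function(u) {
    substring(u, seq_len(nchar(u) + 1), nchar(u))
  })))                                           # includes "" and full u
  pres <- unique(unlist(lapply(units, function(u) {
    substring(u, 1, 0:nchar(u))
  })))
  middles <- ""
  level <- ""
  for (k in seq_len(max_copies)) {
    level <- as.vector(outer(level, units, paste0))
    level <- unique(level[nchar(level) <= cap])
    if (length(level) == 0) break
    middles <- c(middles, level)
  }
  refs <- as.vector(outer(as.vector(outer(sufs, middles, paste0)),
                          pres, paste0))
  infixes <- unlist(lapply(units, function(u) {
    m <- nchar(u)
    unlist(lapply(seq_len(m), function(b) substring(u, b, b:m)))
  }))
  refs <- unique(c("", refs, infixes))
  min(utils::adist(s, refs))
}

# run-length truth of a pattern instantiation (for readable tests)
runs_tbl <- function(units, copies) {
  tibble::tibble(unit = units, copies = as.integer(copies))
}
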