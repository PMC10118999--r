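---
title: "Decomposing mosaic tandem repeats: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing mosaic tandem repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaictr)
```

## The problem

A mosaic tandem repeat is a genomic region composed of consecutive runs of
several distinct repeat units, `(AAAG)i (AG)j (AGGG)k ...`. Such regions,
now routinely spanned by long reads, are poorly served by single-unit
repeat finders, which tend to report one dominant unit and lose the run
structure. `mosaictr` recovers the full structure: the unit inventory, the
order and copy count of each run, and the total edit cost separating the
read from its idealised repeat.

The method rests on two ideas: a *parsimony objective* that scores a
candidate unit inventory by how cheaply it explains the sequence, and a
restriction of the unit search space to *repetitive non-self-overlapping*
substrings that makes the search tractable.

## Candidate units

A substring is eligible as a unit if it occurs at least twice in the input
(overlapping occurrences count) and has no nonempty proper border (no
prefix equal to a suffix). The border condition does two jobs: it picks a
single representative among the rotations of a repeated motif (in
`(AAGA)^k` the rotation `AAAG` is borderless while `AAGA` is not), and it
excludes strings that are themselves exact tandem powers (`ACAC` has border
`AC`). Every tandem repeat has a borderless unit, so nothing expressible is
lost.

Enumeration uses the suffix array and LCP array of the input to build
`LEN[i]`, the length of the longest repeated substring starting at `i`
(the maximum LCP with a suffix-array neighbour; boundary entries of the
suffix array use their single neighbour), and the Morris–Pratt failure
function of each suffix for the border test, O(n²) overall. The suffix
array is built by prefix doubling (O(n log² n)), which is robust on the
highly repetitive inputs this package exists for; at the intended scale
(reads and loci up to a few tens of kilobases) construction time is
negligible next to the greedy selection, so a linear-time construction
would buy nothing.

Substrings containing `N` are never candidates: an ambiguity code cannot
be a repeat unit. The default maximum unit length is 100 bases
(`max_unit_len`), long enough for minisatellite units while bounding the
enumeration.

How much does the eligibility rule shrink the search space?
`compression_ratio()` reports `w_nsop / w_all`, where `w_all` counts all
distinct substrings of length at most θ (default 20) and `w_nsop` counts
the unit-eligible ones among them, i.e. those both repetitive and
borderless. We define the numerator as the unit-eligible set deliberately:
it is the set of units the selection phase actually has to consider, so
the ratio measures the real reduction of the search space. (Counting
borderless substrings alone would not measure this: the one-off substrings
that straddle run junctions are mostly borderless, inflating the numerator
with strings that are never candidates.) On the synthetic benchmark corpus
the per-dataset mean ratio is typically a few percent — the acceptance
script recomputes the median over 48 regenerated datasets, about 4% — so
the selection phase usually weighs tens of candidates rather than
thousands of substrings.

## The extended penalty and unit selection

A decomposition `D` of `S` by a unit set `U` tiles `S` with exact
occurrences of units and uncovered segments. Its extended penalty is

$$\sum_{u \in U} (|u| + o(u)) \;+ \sum_{s \in D,\, s \notin U} |s|$$

with `o(u)` the number of occurrences of `u` in `D`. Each unit pays its
length once (inventory cost) and one per copy (slippage-event cost); each
uncovered base pays one. The formula embodies maximum parsimony: prefer
few, short units that cover nearly everything, without being forced to
admit rare error-induced strings into the inventory.

For fixed `U` the minimum extended penalty over all tilings is computed
exactly by a dynamic program over end positions (`cost(j)` = min of an
uncovered letter or a matching unit occurrence ending at `j`); the sum of
unit lengths is a constant on top. Selecting `U` itself is done greedily:
start from the empty set (extended penalty `n`), each round score every
remaining candidate by the DP under `U ∪ {v}`, add the best, stop when no
candidate strictly decreases the penalty, and finally drop units whose
occurrence count the last tiling left at zero. The joint optimisation of
unit set and tiling is conjectured intractable (the fixed-`U` decision
version is NP-complete), so the greedy result is an upper bound; the test
suite checks it against exhaustive subset search on small instances but
deliberately does not assert equality.

Determinism requires explicit tie-breaks, which are design choices of this
package:

* among candidates with equal extended penalty: larger covered length,
  then shorter unit, then lexicographically smaller text (shorter units
  match the parsimony spirit);
* within the tiling DP: larger covered length, then the longer matching
  unit;
* the stopping rule uses *strict* decrease, which prevents cycling on
  ties.

Greedy rounds score candidates with the *exact* tiling DP, not the
error-tolerant one: all the penalty arithmetic is defined over exact
occurrences, and errors are handled downstream. Eliminated zero-occurrence
units are not re-admitted; elimination happens once, at the end.

One edge case follows directly from the objective: on a homopolymer
`A^k`, the unit set `{A}` scores `1 + k`, worse than the `k` of leaving
everything uncovered, so no unit is selected at all. The parsimony
formula simply does not regard a homopolymer as worth a unit; callers who
care about homopolymer runs should treat the empty annotation accordingly.

## Error-tolerant decomposition

The selected units are aligned to `S` by wraparound dynamic programming —
approximate matching against the regular language `(u1|...|uk)*` under
unit-cost Levenshtein distance (match 0, mismatch/insertion/deletion 1, no
affine gaps). The DP keeps one row block per unit; completing a unit allows
a free transition into the start of any unit at the same position. Two
structural allowances model the `s (u)^k p` shape of real TRs: the
alignment may enter a unit mid-way at the start of `S` and leave mid-way at
the end, at no cost; interior copies must traverse complete units. The
distance is therefore the minimum over references of the form
*suffix + complete copies + prefix* (or a single unit infix), which is
exactly what the brute-force oracle in the tests enumerates.

The wraparound transition creates an apparent cycle (end of a unit feeds
the start of units at the same column); it is resolved by a second pass per
column, which is sufficient because a wrap followed by pure deletions back
to a unit end can never reduce the cost. Traceback ties prefer continuing
the current unit over switching and earlier-selected units otherwise,
stabilising the run-length encoding.

A decomposition is classified as *mosaic tandem repeats* when its tandem
runs — maximal stretches of at least `min_tandem_copies = 2` consecutive
copies of one unit — cover strictly more than `coverage_threshold = 0.8`
of the sequence. Requiring two consecutive copies is the only reading
consistent with the two canonical examples (`AC AC C CGA CGA` qualifies at
0.8, `AC CGA AC T CGA` does not): isolated scattered copies must not count.
"Exceeds" is read as strict inequality, so full coverage does not qualify
at a threshold of exactly 1.

## The synthetic benchmark

`make_benchmark_dataset()` and `run_benchmark()` emulate the study
conditions under which the method is evaluated:

* eight mosaic templates, from two runs of short units (`(AC)i(AG)j`) to
  five alternating runs and a 15-base minisatellite unit;
* copy counts drawn uniformly from 10–200 per run;
* per-base sequencing errors at rates 0, 1, 3, 5, 10 and 15%, each error
  a substitution, insertion or deletion with equal probability (the
  operation mix is not specified by the benchmark design, so uniform
  thirds is the neutral default, configurable via `mix`);
* scoring by allowance: a run passes if its predicted copy count is within
  `X%` of the truth, a string passes if every run does, and unit strings
  must match literally — rotations do not count, and any extra or missing
  run fails the record.

With copy counts of at least 10, duplicated sub-patterns that would make
the optimal decomposition ambiguous (as in `AGAGAGGGAGGGAGAGAGGGAGGG`,
where `(AG)2(AGGG)2(AG)2(AGGG)2` and `(AGAGAGGGAGGG)2` both score 14)
cannot arise in the generated data, so each record has a single optimal
answer.

What the generator does *not* emulate: platform-specific error profiles
(homopolymer-length errors of nanopore reads, burst indels), unit-variant
structure within runs, flanking non-repetitive sequence, and coverage of
multiple reads per locus. Passing benchmarks therefore demonstrate
correctness of the decomposition machinery under idealised independent
errors, not end-to-end performance on a particular sequencing platform.

One template is structurally special: the middle unit of pattern (h),
`AAAGAGAGGGAAAAG`, has the proper border `AAAG`, so it is self-overlapping
and can never be emitted as a literal unit by the pipeline (candidate
enumeration excludes it by design). Pattern (h) consequently cannot reach
accuracy 1 under literal run matching even on error-free input; it is kept
in the corpus as a stress case for the compression census and for users
who score with rotation-tolerant criteria of their own.

## Problem sizes and test design

The test suite checks every string-algorithmic component against
brute-force oracles written directly from the definitions: lexicographic
suffix sorting and substring counting for the suffix structures (500
random strings up to 100 bases, mixed alphabets), exhaustive tiling
enumeration for the exact DP (strings up to 15 bases), and exhaustive
reference enumeration with `utils::adist` as the independent edit-distance
oracle for the wraparound DP (strings up to 30 bases, unit sets of size
≤ 2). Pipeline-level checks use 100 error-free instances of each two-unit
template and small error-injected grids (8 records per dataset); the
compression census runs at the full 48-dataset grid with 100 strings per
dataset. These sizes were chosen to exercise every code path at desk
scale while keeping the default suite fast; all generators are seeded and
bit-reproducible.

## Known limitations

* Greedy selection is a heuristic: on adversarial inputs it can settle on
  a locally optimal unit set (the tests assert only the upper-bound
  relation to the exhaustive optimum).
* Literal unit matching means a prediction phased on a rotation of the
  true unit counts as wrong, which is conservative for benchmark scoring.
* Edit costs are unit Levenshtein; no affine gaps and no quality-aware
  scoring.
* Homopolymer runs select no unit under the parsimony objective (see
  above).
* The mosaic coverage rule counts whole segments inside qualifying runs;
  partial flanking copies contribute only through the wraparound DP's
  partial first/last segments.
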