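#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// ---- suffix structures ----------------------------------------------------

// prefix-doubling suffix array; O(n log^2 n), robust on highly repetitive
// input (the common case for tandem repeats)
static std::vector<int> build_sa(const std::string& s) {
  int n = (int)s.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = (unsigned char)s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + k < n ? rnk[a + k] : -1;
      int rb = b + k < n ? rnk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm: lcp[i] = LCP(suffix sa[i], suffix sa[i+1])
static std::vector<int> build_lcp(const std::string& s,
                                  const std::vector<int>& sa) {
  int n = (int)s.size();
  std::vector<int> rnk(n), lcp(n > 1 ? n - 1 : 0, 0);
  for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rnk[i] - 1] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// LEN[i] = longest l with s[i, i+l) occurring >= 2 times = max LCP with a
// suffix-array neighbour; boundary entries use their single neighbour
static std::vector<int> build_len(int n, const std::vector<int>& sa,
                                  const std::vector<int>& lcp) {
  std::vector<int> len(n, 0);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    if (i > 0) m = std::max(m, lcp[i - 1]);
    if (i < n - 1) m = std::max(m, lcp[i]);
    len[sa[i]] = m;
  }
  return len;
}

// [[Rcpp::export]]
List cpp_suffix_structures(std::string s) {
  std::vector<int> sa = build_sa(s);
  std::vector<int> lcp = build_lcp(s, sa);
  std::vector<int> len = build_len((int)s.size(), sa, lcp);
  return List::create(_["sa"] = sa, _["lcp"] = lcp, _["len"] = len);
}

// ---- Morris-Pratt border array --------------------------------------------

// f[k-1] = length of the longest proper border of t[0, k)
static std::vector<int> failure(const std::string& t) {
  int m = (int)t.size();
  std::vector<int> f(m, 0);
  int l = 0;
  for (int k = 1; k < m; ++k) {
    while (l > 0 && t[k] != t[l]) l = f[l - 1];
    if (t[k] == t[l]) ++l;
    f[k] = l;
  }
  return f;
}

static bool borderless(const std::string& t) {
  std::vector<int> f = failure(t);
  return f.empty() || f.back() == 0;
}

// [[Rcpp::export]]
IntegerVector cpp_border_array(std::string t) {
  std::vector<int> f = failure(t);
  return wrap(f);
}

// ---- candidate unit enumeration -------------------------------------------

// all substrings s[i, i+l), l <= max_len, that occur >= 2 times
// (LEN[i] >= l) and have no nonempty proper border (OL_i[l] == 0);
// deduplicated by text, leftmost witness kept; substrings containing N
// are excluded
// [[Rcpp::export]]
DataFrame cpp_enumerate_units(std::string s, int max_len) {
  int n = (int)s.size();
  std::vector<int> sa = build_sa(s);
  std::vector<int> lcp = build_lcp(s, sa);
  std::vector<int> len = build_len(n, sa, lcp);

  std::vector<int> nextN(n + 1, n);
  for (int i = n - 1; i >= 0; --i)
    nextN[i] = (s[i] == 'N') ? i : nextN[i + 1];

  std::unordered_set<std::string> seen;
  std::vector<std::string> texts;
  std::vector<int> starts;
  for (int i = 0; i < n; ++i) {
    int lmax = std::min(std::min(max_len, len[i]), nextN[i] - i);
    if (lmax < 1) continue;
    std::string suf = s.substr(i);
    std::vector<int> f = failure(suf);
    for (int l = 1; l <= lmax; ++l) {
      if (f[l - 1] == 0) {
        std::string t = s.substr(i, (size_t)l);
        if (seen.insert(t).second) {
          texts.push_back(t);
          starts.push_back(i);
        }
      }
    }
  }
  return DataFrame::create(_["text"] = texts, _["start"] = starts,
                           _["stringsAsFactors"] = false);
}

// ---- exact tiling DP -------------------------------------------------------

// cost(j) = min(cost(j-1) + 1 [uncovered letter],
//               min over units u matching at j: cost(j-|u|) + 1 [one copy]);
// minimises (#copies + #uncovered letters) = extended penalty - sum |u|.
// Ties broken towards larger covered length, then the longer matching unit.
// [[Rcpp::export]]
List cpp_exact_decompose(std::string s, std::vector<std::string> units) {
  int n = (int)s.size(), K = (int)units.size();
  std::vector<int> cost(n + 1, 0), cov(n + 1, 0), choice(n + 1, -1);
  for (int j = 1; j <= n; ++j) {
    cost[j] = cost[j - 1] + 1;
    cov[j] = cov[j - 1];
    choice[j] = -1;
    for (int k = 0; k < K; ++k) {
      int m = (int)units[k].size();
      if (m <= j && s.compare(j - m, m, units[k]) == 0) {
        int c = cost[j - m] + 1, v = cov[j - m] + m;
        bool better = c < cost[j] ||
          (c == cost[j] && (v > cov[j] ||
            (v == cov[j] && choice[j] >= 0 &&
             m > (int)units[choice[j]].size())));
        if (c == cost[j] && choice[j] == -1 && v >= cov[j]) better = true;
        if (better) { cost[j] = c; cov[j] = v; choice[j] = k; }
      }
    }
  }
  // traceback; adjacent uncovered letters merged into one segment
  std::vector<int> b, e, u;
  int j = n;
  while (j > 0) {
    if (choice[j] == -1) {
      int end = j;
      while (j > 0 && choice[j] == -1) --j;
      b.push_back(j); e.push_back(end); u.push_back(-1);
    } else {
      int m = (int)units[choice[j]].size();
      b.push_back(j - m); e.push_back(j); u.push_back(choice[j]);
      j -= m;
    }
  }
  std::reverse(b.begin(), b.end());
  std::reverse(e.begin(), e.end());
  std::reverse(u.begin(), u.end());
  return List::create(
      _["start"] = b, _["end"] = e, _["unit_idx"] = u,
      _["cost"] = cost[n], _["covered"] = cov[n]);
}

// ---- wraparound (approximate regular-expression) DP ------------------------

// Alignment of s against the language suffix(u) (u1|...|uk)* prefix(u):
// one row block per unit, rows 0..|u|; free entry at any row at column 0
// (partial first copy), free wraparound from any completed unit (row |u|)
// to row 0 of any unit at the same column, free exit at any row at column n
// (partial last copy).  Unit costs: match 0, mismatch/insertion/deletion 1.
enum Op : uint8_t { OP_NONE = 0, OP_DIAG, OP_INS, OP_DEL, OP_WRAP, OP_START };

// [[Rcpp::export]]
List cpp_approx_decompose(std::string s, std::vector<std::string> units) {
  int n = (int)s.size(), K = (int)units.size();
  std::vector<int> mlen(K);
  std::vector<size_t> off(K);
  size_t rows = 0;
  for (int k = 0; k < K; ++k) {
    mlen[k] = (int)units[k].size();
    off[k] = rows;
    rows += (size_t)mlen[k] + 1;
  }
  const size_t W = (size_t)n + 1;
  std::vector<int> D(rows * W);
  std::vector<uint8_t> OP(rows * W);
  std::vector<int> wrapfrom((size_t)n + 1, 0);
  auto at = [&](int k, int i, int j) -> size_t {
    return (off[k] + (size_t)i) * W + (size_t)j;
  };

  for (int k = 0; k < K; ++k)
    for (int i = 0; i <= mlen[k]; ++i) {
      D[at(k, i, 0)] = 0;
      OP[at(k, i, 0)] = OP_START;
    }
  {  // column-0 wraparound source (all zeros; smallest unit index)
    wrapfrom[0] = 0;
  }

  for (int j = 1; j <= n; ++j) {
    char cs = s[j - 1];
    for (int k = 0; k < K; ++k) {
      // row 0, pass 1: insertion only (wrap applied in pass 2)
      D[at(k, 0, j)] = D[at(k, 0, j - 1)] + 1;
      OP[at(k, 0, j)] = OP_INS;
      const std::string& u = units[k];
      for (int i = 1; i <= mlen[k]; ++i) {
        int best = D[at(k, i - 1, j - 1)] + (u[i - 1] == cs ? 0 : 1);
        uint8_t op = OP_DIAG;
        int del = D[at(k, i - 1, j)] + 1;
        if (del < best) { best = del; op = OP_DEL; }
        int ins = D[at(k, i, j - 1)] + 1;
        if (ins < best) { best = ins; op = OP_INS; }
        D[at(k, i, j)] = best;
        OP[at(k, i, j)] = op;
      }
    }
    // wraparound: cheapest completed unit at this column
    int A = INT_MAX, src = 0;
    for (int k = 0; k < K; ++k) {
      int v = D[at(k, mlen[k], j)];
      if (v < A) { A = v; src = k; }
    }
    wrapfrom[j] = src;
    for (int k = 0; k < K; ++k) {
      if (A < D[at(k, 0, j)]) {
        D[at(k, 0, j)] = A;
        OP[at(k, 0, j)] = OP_WRAP;
      }
      for (int i = 1; i <= mlen[k]; ++i) {  // re-relax deletions below row 0
        if (D[at(k, i - 1, j)] + 1 < D[at(k, i, j)]) {
          D[at(k, i, j)] = D[at(k, i - 1, j)] + 1;
          OP[at(k, i, j)] = OP_DEL;
        }
      }
    }
  }

  // best exit: minimal cost at column n; ties towards the more complete
  // copy (larger row), then the earlier-selected unit
  int bk = 0, bi = 0, bcost = INT_MAX;
  for (int k = 0; k < K; ++k)
    for (int i = mlen[k]; i >= 0; --i) {
      if (i == 0 && OP[at(k, 0, n)] == OP_WRAP) continue;  // empty last copy
      int v = D[at(k, i, n)];
      if (v < bcost) { bcost = v; bk = k; bi = i; }
    }

  // traceback into per-copy segments
  std::vector<int> seg_b, seg_e, seg_u, seg_ed;
  int k = bk, i = bi, j = n;
  int end_j = n, end_cost = bcost;
  for (;;) {
    uint8_t op = OP[at(k, i, j)];
    if (op == OP_START) {
      seg_b.push_back(j); seg_e.push_back(end_j); seg_u.push_back(k);
      seg_ed.push_back(end_cost - D[at(k, i, j)]);
      break;
    } else if (op == OP_WRAP) {
      seg_b.push_back(j); seg_e.push_back(end_j); seg_u.push_back(k);
      seg_ed.push_back(end_cost - D[at(k, 0, j)]);
      int kk = wrapfrom[j];
      k = kk; i = mlen[kk];
      end_j = j; end_cost = D[at(k, i, j)];
    } else if (op == OP_DIAG) {
      --i; --j;
    } else if (op == OP_INS) {
      --j;
    } else {  // OP_DEL
      --i;
    }
  }
  std::reverse(seg_b.begin(), seg_b.end());
  std::reverse(seg_e.begin(), seg_e.end());
  std::reverse(seg_u.begin(), seg_u.end());
  std::reverse(seg_ed.begin(), seg_ed.end());
  return List::create(
      _["start"] = seg_b, _["end"] = seg_e, _["unit_idx"] = seg_u,
      _["edits"] = seg_ed, _["total_edits"] = bcost);
}

// ---- distinct-substring census --------------------------------------------

// W_all = distinct substrings of length <= theta; W_nsop = the candidate
// units among them: repetitive (>= 2 occurrences, checked via LEN on the
// first-seen = leftmost occurrence) and borderless
// [[Rcpp::export]]
List cpp_substring_counts(std::string s, int theta) {
  int n = (int)s.size();
  std::vector<int> sa = build_sa(s);
  std::vector<int> lcp = build_lcp(s, sa);
  std::vector<int> len = build_len(n, sa, lcp);
  double w_all = 0, w_nsop = 0;
  for (int l = 1; l <= std::min(theta, n); ++l) {
    std::unordered_set<std::string> seen;
    seen.reserve((size_t)(n - l + 1) * 2);
    for (int i = 0; i + l <= n; ++i) {
      std::string t = s.substr((size_t)i, (size_t)l);
      if (seen.insert(t).second) {
        ++w_all;
        if (len[i] >= l && borderless(t)) ++w_nsop;
      }
    }
  }
  return List::create(_["w_all"] = w_all, _["w_nsop"] = w_nsop);
}
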