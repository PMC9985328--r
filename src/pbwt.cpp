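#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximal perfect haplotype block enumeration via the positional
// Burrows-Wheeler transform.
//
// Per column j we maintain the pBWT arrays a (row order by colexicographic
// prefix) and d (d[r] = start of the longest common suffix of the prefixes
// in a-rows r-1 and r; d[0] = j+1 by convention). Blocks ending at column j
// are the lcp-intervals of the match-length array j+1-d, reported only when
// right-maximal, i.e. the interval's rows disagree somewhere in column j+1
// (tested in O(1) with prefix sums of the change vector). Total time is
// O(nk + z) for z reported blocks.

// [[Rcpp::export]]
List pbwt_blocks_cpp(const IntegerMatrix& alleles, bool materialize_rows,
                     int min_sites) {
  const int k = alleles.nrow(), n = alleles.ncol();
  if (k < 2 || n < 1) stop("pbwt_blocks_cpp: need k >= 2 and n >= 1");

  std::vector<int> a(k), d(k, 1), a0(k), a1(k), d0(k), d1(k);
  for (int r = 0; r < k; ++r) a[r] = r;
  // next-column change prefix sums in a-order (for right-maximality)
  std::vector<int> csum(k, 0);

  std::vector<int> out_i, out_j, out_sz;
  List out_rows = List::create();
  std::vector<SEXP> row_sets;

  // lcp-interval stack
  std::vector<int> st_lcp, st_lb;
  st_lcp.reserve(k + 1); st_lb.reserve(k + 1);

  const int* base = alleles.begin();
  for (int j = 1; j <= n; ++j) {
    // update a, d for column j
    const int* colj = base + (size_t)(j - 1) * k;
    int p = j + 1, q = j + 1, u = 0, v = 0;
    for (int r = 0; r < k; ++r) {
      const int id = a[r], dd = d[r];
      if (dd > p) p = dd;
      if (dd > q) q = dd;
      const int al = colj[id];
      if (al == 0) { a0[u] = id; d0[u] = p; ++u; p = 0; }
      else if (al == 1) { a1[v] = id; d1[v] = q; ++v; q = 0; }
      else stop("pbwt_blocks_cpp: non-binary allele at row %d column %d", id + 1, j);
    }
    for (int r = 0; r < u; ++r) { a[r] = a0[r]; d[r] = d0[r]; }
    for (int r = 0; r < v; ++r) { a[u + r] = a1[r]; d[u + r] = d1[r]; }

    // prefix sums of changes in column j+1, in the new a-order
    const bool has_next = j < n;
    if (has_next) {
      const int* coln = base + (size_t)j * k;
      csum[0] = 0;
      int prev = coln[a[0]];
      for (int r = 1; r < k; ++r) {
        const int cur = coln[a[r]];
        csum[r] = csum[r - 1] + (cur != prev ? 1 : 0);
        prev = cur;
      }
    }

    // enumerate lcp-intervals of match lengths lcp[r] = j + 1 - d[r]
    st_lcp.clear(); st_lb.clear();
    st_lcp.push_back(0); st_lb.push_back(0);
    for (int r = 1; r <= k; ++r) {
      const int cur = (r < k) ? (j + 1 - d[r]) : 0;
      int lb = r - 1;
      while (cur < st_lcp.back()) {
        const int lv = st_lcp.back();
        lb = st_lb.back();
        st_lcp.pop_back(); st_lb.pop_back();
        const int rb = r - 1;  // rows a[lb..rb]
        if (lv >= min_sites) {
          const bool right_max = !has_next || (csum[rb] - csum[lb] > 0);
          if (right_max) {
            out_i.push_back(j + 1 - lv);
            out_j.push_back(j);
            out_sz.push_back(rb - lb + 1);
            if (materialize_rows) {
              IntegerVector rs(rb - lb + 1);
              for (int t = lb; t <= rb; ++t) rs[t - lb] = a[t] + 1;
              row_sets.push_back(rs);
            }
          }
        }
      }
      if (cur > st_lcp.back()) { st_lcp.push_back(cur); st_lb.push_back(lb); }
    }
  }

  List res = List::create(
    _["i"] = IntegerVector(out_i.begin(), out_i.end()),
    _["j"] = IntegerVector(out_j.begin(), out_j.end()),
    _["k_block"] = IntegerVector(out_sz.begin(), out_sz.end()));
  if (materialize_rows) {
    List rows(row_sets.size());
    for (size_t t = 0; t < row_sets.size(); ++t) rows[t] = row_sets[t];
    res["rows"] = rows;
  }
  return res;
}

// One pBWT column update, exposed for testing and inspection.
// a_prev: permutation of 1..k (1-based), d_prev: divergence values for
// column j-1, col: binary alleles of column j in original row order.
// [[Rcpp::export]]
List pbwt_step_cpp(const IntegerVector& a_prev, const IntegerVector& d_prev,
                   const IntegerVector& col, int j) {
  const int k = a_prev.size();
  std::vector<int> a0(k), a1(k), d0(k), d1(k);
  int p = j + 1, q = j + 1, u = 0, v = 0;
  for (int r = 0; r < k; ++r) {
    const int id = a_prev[r] - 1, dd = d_prev[r];
    if (dd > p) p = dd;
    if (dd > q) q = dd;
    const int al = col[id];
    if (al == 0) { a0[u] = id; d0[u] = p; ++u; p = 0; }
    else if (al == 1) { a1[v] = id; d1[v] = q; ++v; q = 0; }
    else stop("pbwt_step_cpp: non-binary allele");
  }
  IntegerVector a(k), d(k);
  for (int r = 0; r < u; ++r) { a[r] = a0[r] + 1; d[r] = d0[r]; }
  for (int r = 0; r < v; ++r) { a[u + r] = a1[r] + 1; d[u + r] = d1[r]; }
  return List::create(_["a"] = a, _["d"] = d, _["j"] = j);
}
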