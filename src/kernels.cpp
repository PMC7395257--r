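#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pairwise minimum LCA path distances from Dewey index paths.
// `paths` is a list (one element per concept, in codebook order) of lists of
// integer vectors; each vector is a root..concept node-index path. The
// distance between two concepts is the minimum over path pairs of
// (len1 - lcp) + (len2 - lcp), lcp = longest common path prefix.
// [[Rcpp::export]]
IntegerMatrix cpp_pair_dist_matrix(List paths) {
  const int n = paths.size();
  std::vector< std::vector< std::vector<int> > > P(n);
  for (int i = 0; i < n; ++i) {
    List pi = paths[i];
    P[i].resize(pi.size());
    for (int j = 0; j < pi.size(); ++j) {
      IntegerVector v = pi[j];
      P[i][j].assign(v.begin(), v.end());
    }
  }
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    D(i, i) = 0;
    for (int j = 0; j < i; ++j) {
      int best = INT_MAX;
      for (const auto &a : P[i]) {
        for (const auto &b : P[j]) {
          const size_t m = std::min(a.size(), b.size());
          size_t lcp = 0;
          while (lcp < m && a[lcp] == b[lcp]) ++lcp;
          const int d = (int)(a.size() - lcp) + (int)(b.size() - lcp);
          if (d < best) best = d;
        }
      }
      D(i, j) = best;
      D(j, i) = best;
    }
  }
  return D;
}

// Directed mean-of-minima path scores of a query set against many candidate
// sets. `A` and each element of `Bsets` are 1-based concept indices into `D`.
// Column 1: mean over a in A of min_b D[a, b]; column 2: the reverse
// direction. Used by the retrieval loop for the APL family.
// [[Rcpp::export]]
NumericMatrix cpp_apl_scores(IntegerMatrix D, IntegerVector A, List Bsets) {
  const int nset = Bsets.size();
  const int na = A.size();
  NumericMatrix out(nset, 2);
  for (int s = 0; s < nset; ++s) {
    IntegerVector B = Bsets[s];
    const int nb = B.size();
    if (na == 0 || nb == 0) {
      out(s, 0) = NA_REAL; out(s, 1) = NA_REAL; continue;
    }
    double sum_ab = 0.0;
    std::vector<int> colmin(nb, INT_MAX);
    for (int i = 0; i < na; ++i) {
      const int ai = A[i] - 1;
      int rowmin = INT_MAX;
      for (int j = 0; j < nb; ++j) {
        const int d = D(ai, B[j] - 1);
        if (d < rowmin) rowmin = d;
        if (d < colmin[j]) colmin[j] = d;
      }
      sum_ab += rowmin;
    }
    double sum_ba = 0.0;
    for (int j = 0; j < nb; ++j) sum_ba += colmin[j];
    out(s, 0) = sum_ab / na;
    out(s, 1) = sum_ba / nb;
  }
  return out;
}

// Intersection and union sizes of a sorted query index set against many
// sorted candidate index sets (bag-of-concepts support).
// [[Rcpp::export]]
NumericMatrix cpp_set_overlap(IntegerVector A, List Bsets) {
  const int nset = Bsets.size();
  NumericMatrix out(nset, 2);
  const int na = A.size();
  for (int s = 0; s < nset; ++s) {
    IntegerVector B = Bsets[s];
    const int nb = B.size();
    int i = 0, j = 0, inter = 0;
    while (i < na && j < nb) {
      if (A[i] == B[j]) { ++inter; ++i; ++j; }
      else if (A[i] < B[j]) ++i;
      else ++j;
    }
    out(s, 0) = inter;
    out(s, 1) = na + nb - inter;
  }
  return out;
}
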