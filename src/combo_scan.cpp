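#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// IG in bits from a joint count layout cnt[2*cell + y], plus the number of
// observed (nonzero) genotype categories and the complete-case count.
// IG * n * ln2 = sum_cells c ln c - sum_rows r ln r - sum_cols s ln s + n ln n.
// Shared by the generic and the pairwise kernels so both produce
// bit-identical statistics for the same table.
static inline void ig_from_counts(const int* cnt, int ncell,
                                  double* ig, int* levels, int* ncomp) {
  static const double inv_log2 = 1.0 / std::log(2.0);
  long ntot = 0, ny0 = 0, ny1 = 0;
  int nlev = 0;
  double cell_term = 0.0, row_term = 0.0;
  for (int r = 0; r < ncell; ++r) {
    long c0 = cnt[2 * r], c1 = cnt[2 * r + 1];
    long rt = c0 + c1;
    if (rt == 0) continue;
    ++nlev;
    ntot += rt; ny0 += c0; ny1 += c1;
    if (c0 > 0) cell_term += c0 * std::log((double)c0);
    if (c1 > 0) cell_term += c1 * std::log((double)c1);
    row_term += rt * std::log((double)rt);
  }
  *ncomp = (int)ntot;
  *levels = nlev;
  if (ntot == 0) {
    *ig = NA_REAL;
    return;
  }
  double col_term = 0.0;
  if (ny0 > 0) col_term += ny0 * std::log((double)ny0);
  if (ny1 > 0) col_term += ny1 * std::log((double)ny1);
  double v = (cell_term - row_term - col_term + ntot * std::log((double)ntot)) /
             ntot * inv_log2;
  if (v < 0) v = 0;  // floating-point cancellation
  *ig = v;
}

// Information gain of a batch of SNP combinations against a binary phenotype.
//
// G:      samples x SNPs integer matrix, codes 0/1/2, NA = missing
// y:      0/1 phenotype, length nrow(G)
// combos: k x C matrix of 1-based SNP column indices
//
// For each combination the joint genotype is tabulated against y over the
// samples with no missing genotype among the k SNPs (complete cases); the
// returned IG is H(Y) - H(Y|X) in bits with Y margins taken over those same
// complete cases. levels = number of joint-genotype categories observed with
// nonzero count; n = complete-case count. Combinations with an empty
// complete-case set return IG = NA.
// [[Rcpp::export]]
List combo_scan_cpp(IntegerMatrix G, IntegerVector y, IntegerMatrix combos) {
  const int n = G.nrow();
  const int k = combos.nrow();
  const int C = combos.ncol();
  if (y.size() != n)
    stop("phenotype length does not match the genotype matrix");
  if (k < 1)
    stop("combination order must be >= 1");
  if (k > 12)
    stop("combination order > 12 is not supported (3^k cells)");

  int ncell = 1;
  for (int l = 0; l < k; ++l) ncell *= 3;

  std::vector<int> cnt(2 * ncell);
  std::vector<const int*> col(k);
  const int* gbase = G.begin();

  NumericVector ig(C);
  IntegerVector levels(C), ncomp(C);

  for (int c = 0; c < C; ++c) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int l = 0; l < k; ++l) {
      int j = combos(l, c);
      if (j < 1 || j > G.ncol()) stop("SNP index out of range");
      col[l] = gbase + (size_t)(j - 1) * n;
    }
    for (int s = 0; s < n; ++s) {
      int ys = y[s];
      if (ys == NA_INTEGER) continue;
      int code = 0;
      bool ok = true;
      for (int l = 0; l < k; ++l) {
        int gv = col[l][s];
        if (gv == NA_INTEGER) { ok = false; break; }
        code = code * 3 + gv;
      }
      if (ok) ++cnt[2 * code + ys];
    }
    ig_from_counts(cnt.data(), ncell, &ig[c], &levels[c], &ncomp[c]);
  }

  return List::create(_["ig"] = ig, _["levels"] = levels, _["n"] = ncomp);
}

// All-pairs scan: equivalent to combo_scan_cpp with combos = combn(M, 2)
// (and returned in that order: (1,2), (1,3), ..., (M-1,M)), but with the
// anchor SNP's contribution to the table index precomputed per sample, which
// matters when C(M,2) is in the 1e5..1e9 range.
// [[Rcpp::export]]
List pair_scan_cpp(IntegerMatrix G, IntegerVector y) {
  const int n = G.nrow();
  const int M = G.ncol();
  if (y.size() != n)
    stop("phenotype length does not match the genotype matrix");
  if (M < 2) stop("need at least two SNPs for a pairwise scan");
  const R_xlen_t C = (R_xlen_t)M * (M - 1) / 2;

  NumericVector ig(C);
  IntegerVector levels(C), ncomp(C);
  std::vector<int> pa(n);  // 2*(3*g_a) + y for the anchor SNP, -1 if excluded
  const int* gbase = G.begin();
  int cnt[18];

  R_xlen_t c = 0;
  for (int a = 0; a < M - 1; ++a) {
    const int* ga = gbase + (size_t)a * n;
    for (int s = 0; s < n; ++s) {
      int gv = ga[s], ys = y[s];
      pa[s] = (gv == NA_INTEGER || ys == NA_INTEGER) ? -1 : 6 * gv + ys;
    }
    for (int b = a + 1; b < M; ++b) {
      const int* gb = gbase + (size_t)b * n;
      std::fill(cnt, cnt + 18, 0);
      for (int s = 0; s < n; ++s) {
        int gv = gb[s];
        if (gv == NA_INTEGER || pa[s] < 0) continue;
        ++cnt[pa[s] + 2 * gv];  // 2*(3*g_a + g_b) + y
      }
      ig_from_counts(cnt, 9, &ig[c], &levels[c], &ncomp[c]);
      ++c;
    }
  }

  return List::create(_["ig"] = ig, _["levels"] = levels, _["n"] = ncomp);
}
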