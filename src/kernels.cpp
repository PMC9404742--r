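#include <Rcpp.h>
#include <set>
#include <functional>
using namespace Rcpp;

// Binary search for row `r` among the row indices of column `c` of a CSC
// lower-triangular pattern.  Returns 0-based position into the x slot, or -1.
static inline int find_pos(const int* Lp, const int* Li, int c, int r) {
  int lo = Lp[c], hi = Lp[c + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (Li[mid] == r) return mid;
    if (Li[mid] < r) lo = mid + 1; else hi = mid - 1;
  }
  return -1;
}

// Takahashi selected inverse of C = L L' on the sparsity pattern of L.
// L is the simplicial sparse Cholesky factor (lower triangular, CSC, row
// indices sorted within columns, diagonal entry first).  Returns the values
// of C^{-1} at the positions of L (same p/i slots).  The symbolic pattern of
// a Cholesky factor is closed under the Takahashi recursion, so every entry
// needed is present; structurally absent entries are treated as zero.
// [[Rcpp::export]]
NumericVector takahashi_selinv(IntegerVector Lp_, IntegerVector Li_,
                               NumericVector Lx_, int n) {
  const int* Lp = Lp_.begin();
  const int* Li = Li_.begin();
  const double* Lx = Lx_.begin();
  NumericVector Sx_(Lx_.size());
  double* Sx = Sx_.begin();

  for (int j = n - 1; j >= 0; --j) {
    int p0 = Lp[j], p1 = Lp[j + 1];
    if (p0 >= p1) stop("empty column in Cholesky factor");
    if (Li[p0] != j) stop("Cholesky factor column lacks diagonal entry");
    double ljj = Lx[p0];
    double dj = ljj * ljj;
    // off-diagonals S_ij, i > j (descending i so nothing in this column is
    // needed before it is written; they only depend on later columns)
    for (int pi = p1 - 1; pi > p0; --pi) {
      int i = Li[pi];
      double s = 0.0;
      for (int pk = p0 + 1; pk < p1; ++pk) {
        int k = Li[pk];
        double lkj = Lx[pk] / ljj;  // unit-L entry
        double sik;
        if (k == i) {
          // S_ii is the diagonal of (already processed) column i
          sik = Sx[Lp[i]];
        } else {
          int a = (i > k) ? i : k;
          int b = (i > k) ? k : i;
          int pos = find_pos(Lp, Li, b, a);
          sik = (pos >= 0) ? Sx[pos] : 0.0;
        }
        s += lkj * sik;
      }
      Sx[pi] = -s;
    }
    // diagonal S_jj
    double s = 1.0 / dj;
    for (int pk = p0 + 1; pk < p1; ++pk) {
      double lkj = Lx[pk] / ljj;
      s -= lkj * Sx[pk];
    }
    Sx[p0] = s;
  }
  return Sx_;
}

// Positions (1-based, into the x/i slots of L) of entries (rows, cols) of a
// lower-triangular CSC pattern; 0 when absent.
// [[Rcpp::export]]
IntegerVector pattern_positions(IntegerVector Lp_, IntegerVector Li_,
                                IntegerVector rows, IntegerVector cols) {
  const int* Lp = Lp_.begin();
  const int* Li = Li_.begin();
  int m = rows.size();
  IntegerVector out(m);
  for (int t = 0; t < m; ++t) {
    int pos = find_pos(Lp, Li, cols[t], rows[t]);
    out[t] = pos + 1;  // 0 if not found
  }
  return out;
}

// Meuwissen & Luo (1992) inbreeding coefficients and the Cholesky diagonal
// d of A = T D T'.  sire/dam are 1-based indices into the topologically
// sorted pedigree, 0 for unknown.  Unknown parents are unrelated, non-inbred
// base animals.
// [[Rcpp::export]]
List ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), d(n);
  std::vector<double> L(n, 0.0);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    if (s > 0 && dd > 0)
      d[i] = 0.5 - 0.25 * (F[s - 1] + F[dd - 1]);
    else if (s > 0)
      d[i] = 0.75 - 0.25 * F[s - 1];
    else if (dd > 0)
      d[i] = 0.75 - 0.25 * F[dd - 1];
    else
      d[i] = 1.0;

    if (s == 0 || dd == 0) {
      F[i] = 0.0;
      continue;
    }
    // trace ancestors of i; a_ii = sum L_j^2 d_j over the ancestor set
    std::set<int, std::greater<int> > anc;
    double aii = 0.0;
    L[i] = 1.0;
    anc.insert(i);
    while (!anc.empty()) {
      int j = *anc.begin();
      anc.erase(anc.begin());
      int js = sire[j], jd = dam[j];
      if (js > 0) { L[js - 1] += 0.5 * L[j]; anc.insert(js - 1); }
      if (jd > 0) { L[jd - 1] += 0.5 * L[j]; anc.insert(jd - 1); }
      aii += L[j] * L[j] * d[j];
      L[j] = 0.0;
    }
    F[i] = aii - 1.0;
  }
  return List::create(_["F"] = F, _["d"] = d);
}
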