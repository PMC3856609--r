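#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of fp_pos.row(n) + fp_neg.row(k-n) over permutations; even-length
// median is the midpoint of the central pair
static double combined_fp_median(const IntegerMatrix& fp_pos,
                                 const IntegerMatrix& fp_neg,
                                 int n, int kn, std::vector<int>& buf) {
  const int B = fp_pos.ncol();
  for (int b = 0; b < B; ++b) buf[b] = fp_pos(n, b) + fp_neg(kn, b);
  const int mid = B / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + B);
  double med = buf[mid];
  if (B % 2 == 0) {
    int lo = *std::max_element(buf.begin(), buf.begin() + mid);
    med = (med + lo) / 2.0;
  }
  return med;
}

// Minimize the estimated FDR over all splits (n, k-n) for one total k.
// Returns {min_fdr, best_n}; best_n is the smallest minimizer (splits are
// scanned with n ascending and only a strictly smaller FDR replaces the
// incumbent). Splits with zero observed exceedances are skipped.
static void min_split_for_k(const IntegerMatrix& fp_pos,
                            const IntegerMatrix& fp_neg,
                            const IntegerVector& tp_pos,
                            const IntegerVector& tp_neg,
                            double pi0, int k, std::vector<int>& buf,
                            double& min_fdr, int& best_n) {
  min_fdr = R_PosInf;
  best_n = NA_INTEGER;
  for (int n = 0; n <= k; ++n) {
    const int tp = tp_pos[n] + tp_neg[k - n];
    if (tp == 0) continue;
    double med = combined_fp_median(fp_pos, fp_neg, n, k - n, buf);
    double cfdr = med * pi0 / tp;
    if (cfdr > 1.0) cfdr = 1.0;
    if (cfdr < min_fdr) {
      min_fdr = cfdr;
      best_n = n;
    }
  }
}

// [[Rcpp::export]]
List scan_splits_cpp(IntegerMatrix fp_pos, IntegerMatrix fp_neg,
                     IntegerVector tp_pos, IntegerVector tp_neg,
                     double pi0, int kmax) {
  const int B = fp_pos.ncol();
  std::vector<int> buf(B);
  NumericVector min_fdr(kmax + 1);
  IntegerVector best_n(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    double f; int n;
    min_split_for_k(fp_pos, fp_neg, tp_pos, tp_neg, pi0, k, buf, f, n);
    min_fdr[k] = f;
    best_n[k] = n;
  }
  return List::create(_["min_fdr"] = min_fdr, _["best_n_pos"] = best_n);
}

// Scan k downward from kmax and stop at the first k whose minimized
// estimated FDR is strictly below psi (the max-N search's printed control
// flow). Returns k = -1 when no k qualifies.
// [[Rcpp::export]]
List scan_descend_cpp(IntegerMatrix fp_pos, IntegerMatrix fp_neg,
                      IntegerVector tp_pos, IntegerVector tp_neg,
                      double pi0, double psi, int kmax) {
  const int B = fp_pos.ncol();
  std::vector<int> buf(B);
  for (int k = kmax; k >= 0; --k) {
    double f; int n;
    min_split_for_k(fp_pos, fp_neg, tp_pos, tp_neg, pi0, k, buf, f, n);
    if (f < psi) {
      return List::create(_["k"] = k, _["n_pos"] = n, _["fdr"] = f);
    }
  }
  return List::create(_["k"] = -1, _["n_pos"] = NA_INTEGER,
                      _["fdr"] = NA_REAL);
}
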