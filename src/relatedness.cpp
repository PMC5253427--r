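#include <Rcpp.h>
using namespace Rcpp;

// Per-pair maximum-likelihood IBD coefficients (k0, k1, k2) on the simplex.
// P0, P1, P2 are npair x nloci matrices of genotype-pair probabilities given
// 0/1/2 genes shared identical by descent (NA = locus unscored for the
// pair). Coarse simplex grid (step 0.05) then deterministic pattern-search
// refinement; ties on the grid break toward larger k0 (less related).

static double loglik_pair(const NumericMatrix& P0, const NumericMatrix& P1,
                          const NumericMatrix& P2, int row,
                          double k0, double k1, double k2) {
  double ll = 0;
  int L = P0.ncol();
  for (int l = 0; l < L; ++l) {
    double p0 = P0(row, l);
    if (ISNAN(p0)) continue;
    double v = k0 * p0 + k1 * P1(row, l) + k2 * P2(row, l);
    if (v <= 0) return -INFINITY;
    ll += std::log(v);
  }
  return ll;
}

// [[Rcpp::export]]
NumericMatrix ml_k_cpp(NumericMatrix P0, NumericMatrix P1, NumericMatrix P2) {
  int npair = P0.nrow();
  NumericMatrix out(npair, 4); // k0 k1 k2 loglik
  const double step = 0.05;
  for (int r = 0; r < npair; ++r) {
    double best_ll = -INFINITY, bk1 = 0, bk2 = 0, bk0 = 1;
    // grid, ordered so larger k0 is visited first and wins ties
    for (int i1 = 0; i1 <= 20; ++i1) {
      for (int i2 = 0; i2 + i1 <= 20; ++i2) {
        double k1 = i1 * step, k2 = i2 * step, k0 = 1.0 - k1 - k2;
        double ll = loglik_pair(P0, P1, P2, r, k0, k1, k2);
        if (ll > best_ll + 1e-12) { best_ll = ll; bk0 = k0; bk1 = k1; bk2 = k2; }
      }
    }
    // pattern search on (k1, k2), k0 implicit
    double h = step / 2.0;
    while (h > 1e-7) {
      bool moved = false;
      const double dirs[8][2] = {{1,0},{-1,0},{0,1},{0,-1},{1,1},{-1,-1},{1,-1},{-1,1}};
      for (int d = 0; d < 8; ++d) {
        double k1 = bk1 + h * dirs[d][0];
        double k2 = bk2 + h * dirs[d][1];
        if (k1 < 0 || k2 < 0 || k1 + k2 > 1) continue;
        double ll = loglik_pair(P0, P1, P2, r, 1.0 - k1 - k2, k1, k2);
        if (ll > best_ll + 1e-12) {
          best_ll = ll; bk1 = k1; bk2 = k2; moved = true;
        }
      }
      if (!moved) h /= 2.0;
    }
    out(r, 0) = 1.0 - bk1 - bk2;
    out(r, 1) = bk1;
    out(r, 2) = bk2;
    out(r, 3) = best_ll;
  }
  return out;
}
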