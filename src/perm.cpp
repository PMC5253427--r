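#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle of 0..n-1 using R's RNG so set.seed() controls it.
static void shuffle_idx(std::vector<int>& p) {
  int n = p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
}

static double pearson_lower(const NumericMatrix& X, const NumericVector& gvec,
                            const std::vector<int>& p) {
  int n = X.nrow();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int m = 0, k = 0;
  for (int j = 0; j < n - 1; ++j) {
    for (int i = j + 1; i < n; ++i, ++k) {
      double gv = gvec[k];
      double xv = X(p[i], p[j]);
      if (ISNAN(gv) || ISNAN(xv)) continue;
      sx += xv; sy += gv; sxx += xv * xv; syy += gv * gv; sxy += xv * gv;
      ++m;
    }
  }
  if (m < 3) return NA_REAL;
  double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
  if (vx <= 0 || vy <= 0) return NA_REAL;
  return (sxy - sx * sy / m) / std::sqrt(vx * vy);
}

// Permutation null for a Mantel-type statistic: gvec is the fixed
// lower-triangle vectorization (column-major, strict lower triangle) of the
// response; X is the matrix whose unit labels are jointly permuted.
// [[Rcpp::export]]
NumericVector mantel_perm_cpp(NumericMatrix X, NumericVector gvec, int n_perm) {
  int n = X.nrow();
  NumericVector out(n_perm);
  std::vector<int> p(n);
  for (int b = 0; b < n_perm; ++b) {
    shuffle_idx(p);
    out[b] = pearson_lower(X, gvec, p);
  }
  return out;
}

// Exhaustive enumeration of all n! joint label permutations (identity
// included); feasible for the small-n exactness checks.
// [[Rcpp::export]]
NumericVector mantel_enum_cpp(NumericMatrix X, NumericVector gvec) {
  int n = X.nrow();
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  std::vector<double> rs;
  do {
    rs.push_back(pearson_lower(X, gvec, p));
  } while (std::next_permutation(p.begin(), p.end()));
  return wrap(rs);
}
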