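#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for recent directional migration rates
// (Wilson-Rannala model): latent migrant ancestry per individual
// (non-migrant / first- / second-generation migrant from each source),
// per-population allele frequencies p, inbreeding coefficients F, and the
// migration matrix m with the total-immigration constraint
// sum_{j != i} m[i][j] <= 1/3. All randomness comes from R's RNG.
//
// Genotype likelihood for individual in population i at one locus (a, b):
//   non-migrant / gen-1 from s: p_s(a)^2 (1-F_s) + p_s(a) F_s   (aa)
//                               2 p_s(a) p_s(b) (1-F_s)          (ab)
//   gen-2 from s (one gene from s, one from home pop i):
//                               p_s(a) p_i(a)                    (aa)
//                               p_s(a) p_i(b) + p_s(b) p_i(a)    (ab)
// Ancestry prior given m (home pop i): P(gen1 from j) = m_ij,
// P(gen2 from j) = 2 m_ij m_ii, P(non-migrant) = 1 - sum of the rest.

struct BAState {
  int n, K, L;
  std::vector<int> pop;                    // home population per individual
  std::vector<std::vector<std::pair<int,int>>> geno; // [ind][locus] allele idx or (-1,-1)
  std::vector<int> nall;                   // alleles per locus
  std::vector<std::vector<std::vector<double>>> p; // [pop][locus][allele]
  std::vector<double> F;
  std::vector<std::vector<double>> m;      // m[i][j], j != i; diagonal implicit
  std::vector<int> anc_src, anc_gen;       // per individual
};

static double mdiag(const BAState& st, int i) {
  double s = 0;
  for (int j = 0; j < st.K; ++j) if (j != i) s += st.m[i][j];
  return 1.0 - s;
}

static double locus_ll(const BAState& st, int ind, int src, int gen, int l) {
  int a = st.geno[ind][l].first, b = st.geno[ind][l].second;
  if (a < 0) return 0.0;
  int home = st.pop[ind];
  double v;
  if (gen <= 1) {
    const std::vector<double>& ps = st.p[src][l];
    double Fs = st.F[src];
    if (a == b) v = ps[a] * ps[a] * (1 - Fs) + ps[a] * Fs;
    else        v = 2 * ps[a] * ps[b] * (1 - Fs);
  } else {
    const std::vector<double>& ps = st.p[src][l];
    const std::vector<double>& ph = st.p[home][l];
    if (a == b) v = ps[a] * ph[a];
    else        v = ps[a] * ph[b] + ps[b] * ph[a];
  }
  if (v <= 0) return -INFINITY;
  return std::log(v);
}

static double ind_ll(const BAState& st, int ind, int src, int gen) {
  double s = 0;
  for (int l = 0; l < st.L; ++l) s += locus_ll(st, ind, src, gen, l);
  return s;
}

static double state_prior(const BAState& st, int ind, int src, int gen) {
  int i = st.pop[ind];
  double mii = mdiag(st, i);
  if (gen == 0) {
    double tot = 0;
    for (int j = 0; j < st.K; ++j) if (j != i) tot += st.m[i][j] * (1.0 + 2.0 * mii);
    return 1.0 - tot;
  }
  if (gen == 1) return st.m[i][src];
  return 2.0 * st.m[i][src] * mii;
}

static void gibbs_ancestry(BAState& st, int ind) {
  int i = st.pop[ind];
  int nstate = 1 + 2 * (st.K - 1);
  std::vector<double> lw(nstate);
  std::vector<int> ssrc(nstate), sgen(nstate);
  int k = 0;
  ssrc[k] = i; sgen[k] = 0;
  lw[k] = std::log(std::max(state_prior(st, ind, i, 0), 1e-300)) + ind_ll(st, ind, i, 0);
  ++k;
  for (int j = 0; j < st.K; ++j) {
    if (j == i) continue;
    for (int gen = 1; gen <= 2; ++gen, ++k) {
      ssrc[k] = j; sgen[k] = gen;
      lw[k] = std::log(std::max(state_prior(st, ind, j, gen), 1e-300)) +
              ind_ll(st, ind, j, gen);
    }
  }
  double mx = *std::max_element(lw.begin(), lw.end());
  double tot = 0;
  for (int s = 0; s < nstate; ++s) { lw[s] = std::exp(lw[s] - mx); tot += lw[s]; }
  double u = unif_rand() * tot, c = 0;
  int pick = nstate - 1;
  for (int s = 0; s < nstate; ++s) { c += lw[s]; if (u <= c) { pick = s; break; } }
  st.anc_src[ind] = ssrc[pick];
  st.anc_gen[ind] = sgen[pick];
}

// reflect x into [lo, hi]
static double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  if (w <= 0) return lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2 * lo - x;
    if (x > hi) x = 2 * hi - x;
  }
  return x;
}

static bool update_m(BAState& st, double delta_m) {
  if (st.K < 2) return false;
  int i = (int)(unif_rand() * st.K);
  int j = (int)(unif_rand() * (st.K - 1));
  if (j >= i) ++j;
  double other = 0;
  for (int k = 0; k < st.K; ++k) if (k != i && k != j) other += st.m[i][k];
  double ub = 1.0 / 3.0 - other;
  double cur = st.m[i][j];
  double prop = reflect(cur + (2 * unif_rand() - 1) * delta_m, 0.0, ub);
  // MH on the ancestry priors of individuals sampled in population i
  double logr = 0;
  double old = cur;
  st.m[i][j] = prop;
  for (int ind = 0; ind < st.n; ++ind) {
    if (st.pop[ind] != i) continue;
    double pr_new = state_prior(st, ind, st.anc_src[ind], st.anc_gen[ind]);
    st.m[i][j] = old;
    double pr_old = state_prior(st, ind, st.anc_src[ind], st.anc_gen[ind]);
    st.m[i][j] = prop;
    if (pr_new <= 0) { logr = -INFINITY; break; }
    logr += std::log(pr_new) - std::log(pr_old);
  }
  if (std::log(unif_rand()) < logr) return true;
  st.m[i][j] = old;
  return false;
}

static bool update_F(BAState& st, double delta_F) {
  int i = (int)(unif_rand() * st.K);
  double old = st.F[i];
  double prop = reflect(old + (2 * unif_rand() - 1) * delta_F, 0.0, 1.0);
  double logr = 0;
  for (int ind = 0; ind < st.n; ++ind) {
    int src = st.anc_src[ind], gen = st.anc_gen[ind];
    bool uses = (gen <= 1 && src == i);
    if (!uses) continue;
    double l_old = ind_ll(st, ind, src, gen);
    st.F[i] = prop;
    double l_new = ind_ll(st, ind, src, gen);
    st.F[i] = old;
    logr += l_new - l_old;
  }
  if (std::log(unif_rand()) < logr) { st.F[i] = prop; return true; }
  return false;
}

static bool update_p(BAState& st, double delta_p) {
  if (st.L == 0) return false;
  int i = (int)(unif_rand() * st.K);
  int l = (int)(unif_rand() * st.L);
  int na = st.nall[l];
  if (na < 2) return false;
  int a = (int)(unif_rand() * na);
  int b = (int)(unif_rand() * (na - 1));
  if (b >= a) ++b;
  double u = unif_rand() * delta_p;
  double pa = st.p[i][l][a] + u, pb = st.p[i][l][b] - u;
  if (pb < 0 || pa > 1) return false; // out of simplex: reject
  double logr = 0;
  double oa = st.p[i][l][a], ob = st.p[i][l][b];
  for (int ind = 0; ind < st.n; ++ind) {
    int src = st.anc_src[ind], gen = st.anc_gen[ind];
    bool uses = (src == i) || (gen == 2 && st.pop[ind] == i);
    if (!uses) continue;
    double l_old = locus_ll(st, ind, src, gen, l);
    st.p[i][l][a] = pa; st.p[i][l][b] = pb;
    double l_new = locus_ll(st, ind, src, gen, l);
    st.p[i][l][a] = oa; st.p[i][l][b] = ob;
    if (l_new == -INFINITY) { logr = -INFINITY; break; }
    logr += l_new - l_old;
  }
  if (std::log(unif_rand()) < logr) {
    st.p[i][l][a] = pa; st.p[i][l][b] = pb;
    return true;
  }
  return false;
}

// geno: n x (2L) allele indices, 0-based, -1 missing (both slots)
// [[Rcpp::export]]
List bayesass_chain_cpp(IntegerMatrix geno, IntegerVector pop, int K,
                        IntegerVector nall, int n_iter, int burn_in, int thin,
                        double delta_p, double delta_F, double delta_m) {
  RNGScope scope;
  BAState st;
  st.n = geno.nrow();
  st.L = nall.size();
  st.K = K;
  st.pop.assign(pop.begin(), pop.end());
  st.nall.assign(nall.begin(), nall.end());
  st.geno.resize(st.n, std::vector<std::pair<int,int>>(st.L));
  for (int ind = 0; ind < st.n; ++ind)
    for (int l = 0; l < st.L; ++l)
      st.geno[ind][l] = {geno(ind, 2 * l), geno(ind, 2 * l + 1)};
  // init p from observed pooled-ish counts with pseudocount
  st.p.assign(K, std::vector<std::vector<double>>(st.L));
  for (int i = 0; i < K; ++i)
    for (int l = 0; l < st.L; ++l) {
      std::vector<double> cnt(st.nall[l], 0.5);
      for (int ind = 0; ind < st.n; ++ind) {
        if (st.pop[ind] != i) continue;
        int a = st.geno[ind][l].first, b = st.geno[ind][l].second;
        if (a >= 0) { cnt[a] += 1; cnt[b] += 1; }
      }
      double tot = 0;
      for (double c : cnt) tot += c;
      for (double& c : cnt) c /= tot;
      st.p[i][l] = cnt;
    }
  st.F.assign(K, 0.1);
  st.m.assign(K, std::vector<double>(K, 0.0));
  double m0 = std::min(0.01, 1.0 / (3.0 * std::max(1, K - 1)));
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      if (i != j) st.m[i][j] = m0;
  st.anc_src.resize(st.n);
  st.anc_gen.assign(st.n, 0);
  for (int ind = 0; ind < st.n; ++ind) st.anc_src[ind] = st.pop[ind];

  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it) if ((it + 1) % thin == 0) ++n_keep;
  NumericMatrix m_samp(n_keep, K * K);
  NumericMatrix F_samp(n_keep, K);
  std::vector<long> prop_cnt(3, 0), acc_cnt(3, 0);
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    int ind = (int)(unif_rand() * st.n);
    gibbs_ancestry(st, ind);
    int fam = (int)(unif_rand() * 3);
    bool acc = false;
    if (fam == 0) acc = update_m(st, delta_m);
    else if (fam == 1) acc = update_F(st, delta_F);
    else acc = update_p(st, delta_p);
    ++prop_cnt[fam];
    if (acc) ++acc_cnt[fam];
    if (it >= burn_in && (it + 1) % thin == 0) {
      for (int i = 0; i < K; ++i) {
        double d = mdiag(st, i);
        for (int j = 0; j < K; ++j)
          m_samp(keep, i * K + j) = (i == j) ? d : st.m[i][j];
        F_samp(keep, i) = st.F[i];
      }
      ++keep;
    }
  }
  NumericVector acc_rate(3);
  for (int f = 0; f < 3; ++f)
    acc_rate[f] = prop_cnt[f] > 0 ? (double)acc_cnt[f] / prop_cnt[f] : NA_REAL;
  acc_rate.names() = CharacterVector::create("m", "F", "p");
  return List::create(_["m_samples"] = m_samp, _["F_samples"] = F_samp,
                      _["acceptance"] = acc_rate);
}
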