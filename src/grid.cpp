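#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-block sufficient statistics of the profile-RSS objective for every
// (s, mu) grid cell.
//
// Pairs are the flattened per-SNP linked-exon windows (nearest exon
// first): r[j], l[j] for j in off[i]..off[i+1]-1 belong to SNP i. For a
// cell (s, mu) the per-SNP factor is
//   g_i = sum_j mu*l_j * prod_{k<j}(1 - mu*l_k) * f(r_j, s, t) + prod_j (1 - mu*l_j)
// and the output accumulates, per block b and cell c,
//   num[b, c] = sum_{i in b} pn_i * g_i,   den[b, c] = sum_{i in b} g_i^2.
//
// Cells are ordered s-major (mu fastest), matching expand.grid(mu, s).
// The t-dependent powers (1-r)^t (autosome) or (1-(2/3)r)^(t+1) (X) do
// not depend on s or mu and are precomputed per pair; the f-vector is
// recomputed once per distinct s, not per cell.
// [[Rcpp::export]]
List cpp_profile_sums(NumericVector r, NumericVector l, IntegerVector off,
                      NumericVector pn, IntegerVector block, int n_blocks,
                      NumericVector s_vals, NumericVector mu_vals,
                      double t, bool equilibrium, bool xmode) {
  const int n_snp = pn.size();
  const int n_pair = r.size();
  const int ns = s_vals.size(), nm = mu_vals.size();
  const int ncell = ns * nm;
  NumericMatrix num(n_blocks, ncell), den(n_blocks, ncell);

  std::vector<double> re(n_pair), u(n_pair), f(n_pair);
  for (int j = 0; j < n_pair; ++j) {
    double rj = xmode ? (2.0 / 3.0) * r[j] : r[j];
    re[j] = rj;
    if (!equilibrium)
      u[j] = std::exp((xmode ? t + 1.0 : t) * std::log1p(-rj));
  }

  for (int is = 0; is < ns; ++is) {
    Rcpp::checkUserInterrupt();
    const double s = s_vals[is];
    const double onems = 1.0 - s;
    const double st = equilibrium ? 0.0 : std::exp(t * std::log1p(-s));
    for (int j = 0; j < n_pair; ++j) {
      const double rj = re[j];
      const double d = s + rj - s * rj;
      double fj;
      if (s == 0.0) {
        fj = 1.0;
      } else if (equilibrium) {
        fj = rj / d;
      } else if (xmode) {
        fj = (s * u[j] * st + rj) / d;
      } else {
        // (1-s)^t (1-r)^t (1-r) s + r, over 1 - (1-s)(1-r)
        fj = (st * u[j] * (1.0 - rj) * s + rj) / d;
      }
      f[j] = fj;
    }
    (void)onems;
    // all mu cells for this s in one pass over the pairs; the mu lanes
    // are independent, so the inner loops vectorize
    std::vector<double> acc(nm), prod(nm);
    const double *muv = &mu_vals[0];
    for (int i = 0; i < n_snp; ++i) {
      const int a = off[i], b = off[i + 1];
      const int bk = block[i];
      const double pni = pn[i];
      if (a == b) {
        for (int im = 0; im < nm; ++im) {
          num(bk, is * nm + im) += pni;
          den(bk, is * nm + im) += 1.0;
        }
        continue;
      }
      for (int im = 0; im < nm; ++im) { acc[im] = 0.0; prod[im] = 1.0; }
      for (int j = a; j < b; ++j) {
        const double fj = f[j], lj = l[j];
        for (int im = 0; im < nm; ++im) {
          double ml = muv[im] * lj;
          ml = (ml > 1.0) ? 1.0 : ml;
          acc[im] += ml * prod[im] * fj;
          prod[im] *= (1.0 - ml);
        }
      }
      for (int im = 0; im < nm; ++im) {
        const double g = acc[im] + prod[im];
        num(bk, is * nm + im) += pni * g;
        den(bk, is * nm + im) += g * g;
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
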