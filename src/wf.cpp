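#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-site Wright-Fisher dynamics with additive selection (genotype
// fitnesses 1, 1-s, 1-2s, floored at 0), irreversible wild-type ->
// deleterious mutation at rate u per copy, and binomial resampling of N2
// = 2*Ne copies. Two absorbing-boundary shortcuts keep long burn-ins
// tractable: at 0 copies the waiting time to the next mutational origin
// is geometric and is sampled directly, and at fixation the site stays
// fixed (no back mutation; selection has no variance to act on).

static inline double sel_freq(double p, double s) {
  if (s <= 0.0 || p <= 0.0 || p >= 1.0) return p;
  const double w11 = std::max(1.0 - 2.0 * s, 0.0);
  const double whet = std::max(1.0 - s, 0.0);
  const double q = 1.0 - p;
  const double wbar = q * q + 2.0 * p * q * whet + p * p * w11;
  if (wbar <= 0.0) return 0.0;
  return (p * q * whet + p * p * w11) / wbar;
}

// evolve a site for ngen generations; returns the final copy number
static int evolve(int k, int N2, double s, double u, double ngen) {
  double g = 0.0;
  const double pmut0 = (u > 0.0) ? -std::expm1((double)N2 * std::log1p(-u)) : 0.0;
  while (g < ngen) {
    if (k >= N2) return N2;            // fixed: absorbed
    if (k == 0) {
      if (pmut0 <= 0.0) return 0;      // no mutation: absorbed at loss
      double gap = R::rgeom(pmut0);    // generations with no new mutant
      if (g + gap + 1.0 > ngen) return 0;
      g += gap + 1.0;
      k = 1;
      continue;
    }
    double p = sel_freq((double)k / N2, s);
    if (u > 0.0 && p < 1.0) p += (1.0 - p) * u;
    k = (int)R::rbinom((double)N2, p);
    g += 1.0;
  }
  return k;
}

// [[Rcpp::export]]
List cpp_simulate_split(NumericVector s, int Ne_anc, int Ne_donor,
                        int Ne_recip, double u, double burn_in,
                        double t_split, int bn_dur, int bn_Ne,
                        double init_freq, bool use_init) {
  const int n = s.size();
  const int Na2 = 2 * Ne_anc, Nd2 = 2 * Ne_donor, Nr2 = 2 * Ne_recip;
  NumericVector fd(n), fr(n);
  for (int i = 0; i < n; ++i) {
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    const double si = s[i];
    int kd, kr;
    if (use_init) {
      kd = (int)std::lround(init_freq * Nd2);
      kr = (int)std::lround(init_freq * Nr2);
    } else {
      int ka = evolve(0, Na2, si, u, burn_in);
      double pa = (double)ka / Na2;
      kd = (int)R::rbinom((double)Nd2, pa);
      kr = (int)R::rbinom((double)Nr2, pa);
    }
    kd = evolve(kd, Nd2, si, u, t_split);
    fd[i] = (double)kd / Nd2;
    if (bn_dur > 0) {
      double pre = t_split - bn_dur;
      if (pre < 0) pre = 0;
      kr = evolve(kr, Nr2, si, u, pre);
      const int Nb2 = 2 * bn_Ne;
      kr = (int)R::rbinom((double)Nb2, (double)kr / Nr2);
      kr = evolve(kr, Nb2, si, u, (double)bn_dur);
      fr[i] = (double)kr / Nb2;
    } else {
      kr = evolve(kr, Nr2, si, u, t_split);
      fr[i] = (double)kr / Nr2;
    }
  }
  return List::create(_["freq_donor"] = fd, _["freq_recipient"] = fr);
}
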