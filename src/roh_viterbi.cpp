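#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state HMM for runs of homozygosity, Viterbi decoding.
// States: 0 = NORMAL, 1 = AUTOZYGOUS.
// Emissions at a site with population alt-allele frequency p and error e:
//   P(het | NORMAL)     = 2p(1-p)(1-e) + e(1 - 2p(1-p))
//   P(het | AUTOZYGOUS) = e
// with P(hom | .) = 1 - P(het | .).
// Transition between adjacent used markers d bp apart:
//   P(NORMAL -> AUTOZYGOUS) = 1 - exp(-t_in  * d)
//   P(AUTOZYGOUS -> NORMAL) = 1 - exp(-t_out * d)
// Initial distribution is the stationary one of the per-bp rates.

// [[Rcpp::export]]
IntegerVector roh_viterbi_cpp(IntegerVector het, NumericVector pos, NumericVector p,
                              double e_het, double t_in, double t_out) {
  int T = het.size();
  IntegerVector path(T);
  if (T == 0) return path;
  double pi_auto = t_in / (t_in + t_out);
  std::vector<double> d0(T), d1(T);
  std::vector<int> b0(T), b1(T);
  auto lemit = [&](int t, int s) {
    double h2 = 2.0 * p[t] * (1.0 - p[t]);
    double phet = (s == 1) ? e_het : h2 * (1.0 - e_het) + e_het * (1.0 - h2);
    double pr = het[t] ? phet : 1.0 - phet;
    return std::log(std::max(pr, 1e-300));
  };
  d0[0] = std::log(1.0 - pi_auto) + lemit(0, 0);
  d1[0] = std::log(pi_auto) + lemit(0, 1);
  for (int t = 1; t < T; ++t) {
    double d = std::abs(pos[t] - pos[t - 1]);
    double p01 = 1.0 - std::exp(-t_in * d);   // NORMAL -> AUTO
    double p10 = 1.0 - std::exp(-t_out * d);  // AUTO -> NORMAL
    double l00 = std::log(1.0 - p01), l01 = std::log(std::max(p01, 1e-300));
    double l11 = std::log(1.0 - p10), l10 = std::log(std::max(p10, 1e-300));
    double a0 = d0[t - 1] + l00, b0v = d1[t - 1] + l10;
    if (a0 >= b0v) { d0[t] = a0; b0[t] = 0; } else { d0[t] = b0v; b0[t] = 1; }
    double a1 = d0[t - 1] + l01, b1v = d1[t - 1] + l11;
    if (a1 >= b1v) { d1[t] = a1; b1[t] = 0; } else { d1[t] = b1v; b1[t] = 1; }
    d0[t] += lemit(t, 0);
    d1[t] += lemit(t, 1);
  }
  int s = (d1[T - 1] > d0[T - 1]) ? 1 : 0;
  path[T - 1] = s;
  for (int t = T - 1; t > 0; --t) {
    s = s ? b1[t] : b0[t];
    path[t - 1] = s;
  }
  return path;
}
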