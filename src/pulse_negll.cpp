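// Negative Poisson log-likelihood of a pulse-model parameter vector
// against binned interior tract counts.  Mirrors the R reference path
// (expected_bin_counts + poisson_loglik) exactly; exists because the
// optimizer evaluates it ~10^4 times per fit.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// theta: (f2, then per pulse (t or v, m)); after[i] = 0 for a free pulse
// time in (t_min, G0), else the 1-based index of the predecessor pulse
// with t_i = t_min + (t_after - t_min) * v_i.
// anc_idx: 1-based ancestry row (in obs) of founding[1], founding[2],
// then each pulse.
// [[Rcpp::export]]
double pulse_negll_cpp(NumericVector theta, IntegerVector after,
                       IntegerVector anc_idx, double G0, NumericMatrix obs,
                       NumericVector lo_e, NumericVector hi_e,
                       NumericVector Lu, NumericVector Lw, double n_hap,
                       bool neighbor, double rate_offset, double t_min,
                       double lgamma_const) {
  const double BAD = 1e10;
  int np = after.size();
  int M = 2 + np;
  int A = obs.nrow();
  int B = obs.ncol();

  std::vector<double> tv(M), mv(M);
  double f2 = theta[0];
  tv[0] = G0; tv[1] = G0;
  mv[0] = 1.0 - f2; mv[1] = f2;
  for (int i = 0; i < np; ++i) {
    double t = theta[1 + 2 * i];
    if (after[i] > 0) {
      double t_after = tv[1 + after[i]];  // predecessors come first
      t = t_min + (t_after - t_min) * t;
    }
    tv[2 + i] = t;
    mv[2 + i] = theta[2 + 2 * i];
  }

  // group events by time, descending
  std::vector<double> ut(tv);
  std::sort(ut.begin(), ut.end(), std::greater<double>());
  ut.erase(std::unique(ut.begin(), ut.end()), ut.end());
  int K = ut.size();
  std::vector<int> grp(M);
  std::vector<double> Mk(K, 0.0);
  for (int i = 0; i < M; ++i) {
    int k = std::lower_bound(ut.begin(), ut.end(), tv[i],
                             std::greater<double>()) - ut.begin();
    grp[i] = k;
    Mk[k] += mv[i];
  }
  for (int k = 0; k < K; ++k)
    if (Mk[k] > 1.0 + 1e-12) return BAD;

  // survival through strictly more recent event groups
  std::vector<double> S(K);
  double acc = 1.0;
  for (int k = K - 1; k >= 0; --k) {
    S[k] = acc;
    acc *= (1.0 - Mk[k]);
  }
  std::vector<double> p(M);
  for (int i = 0; i < M; ++i) p[i] = mv[i] * S[grp[i]];

  // pool composition per interval (ut[k+1], ut[k]]
  std::vector<double> qk(K * A, 0.0), q(A, 0.0);
  for (int k = 0; k < K; ++k) {
    for (int a = 0; a < A; ++a) q[a] *= (1.0 - Mk[k]);
    for (int i = 0; i < M; ++i)
      if (grp[i] == k) q[anc_idx[i] - 1] += mv[i];
    for (int a = 0; a < A; ++a) qk[k * A + a] = q[a];
  }

  std::vector<double> r(M);
  for (int i = 0; i < M; ++i) {
    double ri = std::max(tv[i] + rate_offset, 1e-6);
    if (neighbor) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double lower = (k + 1 < K) ? ut[k + 1] : 0.0;
        double ov = std::min(ut[k], tv[i]) - lower;
        if (ov > 0) s += ov * qk[k * A + anc_idx[i] - 1];
      }
      ri = std::max(ri * (1.0 - s / tv[i]), 1e-6);
    }
    r[i] = ri;
  }

  std::vector<double> lam(A * B, 0.0);
  for (int i = 0; i < M; ++i) {
    if (p[i] <= 0) continue;
    double ri = r[i];
    int a = anc_idx[i] - 1;
    for (int j = 0; j < Lu.size(); ++j) {
      double L = Lu[j], w = Lw[j];
      for (int b = 0; b < B; ++b) {
        double lo = std::min(lo_e[b], L), hi = std::min(hi_e[b], L);
        double I = std::exp(-ri * lo) * (L - lo) -
                   std::exp(-ri * hi) * (L - hi) -
                   (std::exp(-ri * lo) - std::exp(-ri * hi)) / ri;
        if (I > 0) lam[a * B + b] += n_hap * p[i] * ri * w * I;
      }
    }
  }

  double ll = -lgamma_const;
  for (int a = 0; a < A; ++a)
    for (int b = 0; b < B; ++b) {
      double l = lam[a * B + b], n = obs(a, b);
      if (l > 0) ll += n * std::log(l) - l;
      else if (n > 0) return BAD;
    }
  if (!std::isfinite(ll)) return BAD;
  return -ll;
}
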