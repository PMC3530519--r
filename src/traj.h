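#ifndef MSATDEMOG_TRAJ_H
#define MSATDEMOG_TRAJ_H

#include <Rcpp.h>
#include <cmath>

// Backward-in-time population size trajectory.
// shape: 0 constant (N0 everywhere), 1 exponential, 2 linear,
// 3 step (N0 for t < T, N1 beyond); N(t) = N1 for t >= T.
struct Traj {
  double N0, N1, T;
  int shape;
};

inline double traj_N(const Traj &tr, double t) {
  if (tr.shape == 0) return tr.N0;
  if (tr.T <= 0.0 || t >= tr.T) return tr.N1;
  if (tr.shape == 3) return tr.N0;
  if (tr.shape == 1)
    return tr.N0 * std::exp(std::log(tr.N1 / tr.N0) * t / tr.T);
  return tr.N0 + (tr.N1 - tr.N0) * t / tr.T;
}

// Lambda(t) = int_0^t du / N(u), closed form per shape
inline double traj_intensity(const Traj &tr, double t) {
  if (tr.shape == 0) return t / tr.N0;
  if (tr.T <= 0.0) return t / tr.N1;
  double tcap = t < tr.T ? t : tr.T;
  double head;
  if (tr.shape == 3) {
    head = tcap / tr.N0;
  } else if (tr.shape == 1) {
    double beta = std::log(tr.N1 / tr.N0) / tr.T;
    if (std::fabs(beta) * tr.T < 1e-12) head = tcap / tr.N0;
    else head = (1.0 - std::exp(-beta * tcap)) / (tr.N0 * beta);
  } else {
    double a = (tr.N1 - tr.N0) / tr.T;
    if (std::fabs(a) * tr.T < 1e-12 * tr.N0) head = tcap / tr.N0;
    else head = std::log1p(a * tcap / tr.N0) / a;
  }
  if (t > tr.T) head += (t - tr.T) / tr.N1;
  return head;
}

// inverse of traj_intensity (Lambda >= 0)
inline double traj_intensity_inv(const Traj &tr, double L) {
  if (tr.shape == 0) return L * tr.N0;
  if (tr.T <= 0.0) return L * tr.N1;
  double LT = traj_intensity(tr, tr.T);
  if (L >= LT) return tr.T + (L - LT) * tr.N1;
  if (tr.shape == 3) return L * tr.N0;
  if (tr.shape == 1) {
    double beta = std::log(tr.N1 / tr.N0) / tr.T;
    if (std::fabs(beta) * tr.T < 1e-12) return L * tr.N0;
    return -std::log1p(-L * tr.N0 * beta) / beta;
  }
  double a = (tr.N1 - tr.N0) / tr.T;
  if (std::fabs(a) * tr.T < 1e-12 * tr.N0) return L * tr.N0;
  return tr.N0 * std::expm1(a * L) / a;
}

// net allele-size displacement from nmut two-phase mutations:
// single step (+/-1) with prob ps, else +/- (msMin + Geom(q)) repeat units
// (msMin = 1 or 2 depending on whether "multistep" includes single steps)
inline int tpm_net_disp(int nmut, double ps, double q, int msMin) {
  int d = 0;
  for (int i = 0; i < nmut; ++i) {
    int mag = 1;
    if (ps < 1.0 && unif_rand() >= ps) mag = msMin + (int) R::rgeom(q);
    d += (unif_rand() < 0.5) ? mag : -mag;
  }
  return d;
}

#endif
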