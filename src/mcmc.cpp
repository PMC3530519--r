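// Likelihood kernels and genealogy moves for the Bayesian single
// size-change model: coalescent prior density of a genealogy under the
// trajectory, stepwise-mutation (Skellam) branch transition terms, and the
// Metropolis-Hastings tree updates (node-time slides, root-gap scaling,
// wide exchange of subtrees, internal-state random walks).
//
// Tree encoding shared with the R driver: nodes 0..2n-2 (0-based), leaves
// 0..n-1 at time 0 with fixed observed states, `parent` = 0-based parent
// index with -1 at the root; vectors are modified in place by the sweep.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "traj.h"

using namespace Rcpp;

// log P(net displacement = d | Poisson(m) symmetric unit steps)
// = -m + log I_|d|(m); series fallback where the scaled Bessel underflows
static double skellam_lp(int d, double m) {
  int ad = d < 0 ? -d : d;
  if (m <= 0.0) return ad == 0 ? 0.0 : R_NegInf;
  double bi = R::bessel_i(m, (double) ad, 2.0);
  if (bi > 0.0 && R_finite(bi)) return std::log(bi);
  return ad * std::log(m / 2.0) - R::lgammafn(ad + 1.0) - m;
}

// [[Rcpp::export]]
NumericVector skellam_logpmf_cpp(IntegerVector d, double m) {
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = skellam_lp(d[i], m);
  return out;
}

static double coal_ll(const NumericVector &times, int nLeaf, const Traj &tr) {
  int nn = times.size();
  std::vector<double> ts;
  ts.reserve(nn - nLeaf);
  for (int v = nLeaf; v < nn; ++v) {
    if (times[v] <= 0.0) return R_NegInf;
    ts.push_back(times[v]);
  }
  std::sort(ts.begin(), ts.end());
  double ll = 0.0, prevL = 0.0;
  double k = (double) nLeaf;
  for (size_t i = 0; i < ts.size(); ++i) {
    double L = traj_intensity(tr, ts[i]);
    ll += -(k * (k - 1.0) / 4.0) * (L - prevL);
    ll += -std::log(2.0 * traj_N(tr, ts[i]));
    prevL = L;
    k -= 1.0;
  }
  return ll;
}

static double mut_ll(const IntegerVector &parent, const NumericVector &times,
                     const IntegerVector &states, double mu) {
  double ll = 0.0;
  for (int v = 0; v < parent.size(); ++v) {
    int p = parent[v];
    if (p < 0) continue;
    double len = times[p] - times[v];
    if (len < 0.0) return R_NegInf;
    ll += skellam_lp(states[v] - states[p], mu * len);
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export]]
double coal_loglik_cpp(NumericVector times, int nLeaf, double N0, double N1,
                       double TT, int shape) {
  Traj tr{N0, N1, TT, shape};
  return coal_ll(times, nLeaf, tr);
}

// [[Rcpp::export]]
double mut_loglik_cpp(IntegerVector parent, NumericVector times,
                      IntegerVector states, double mu) {
  return mut_ll(parent, times, states, mu);
}

// [[Rcpp::export]]
List tree_loglik_cpp(IntegerVector parent, NumericVector times,
                     IntegerVector states, int nLeaf, double N0, double N1,
                     double TT, int shape, double mu) {
  Traj tr{N0, N1, TT, shape};
  return List::create(_["coal"] = coal_ll(times, nLeaf, tr),
                      _["mut"] = mut_ll(parent, times, states, mu));
}

static void build_children(const IntegerVector &parent, std::vector<int> &c1,
                           std::vector<int> &c2) {
  int nn = parent.size();
  c1.assign(nn, -1);
  c2.assign(nn, -1);
  for (int v = 0; v < nn; ++v) {
    int p = parent[v];
    if (p >= 0) {
      if (c1[p] < 0) c1[p] = v; else c2[p] = v;
    }
  }
}

static double branch_lp(const IntegerVector &parent, const NumericVector &times,
                        const IntegerVector &states, double mu, int v) {
  int p = parent[v];
  if (p < 0) return 0.0;
  double len = times[p] - times[v];
  if (len < 0.0) return R_NegInf;
  return skellam_lp(states[v] - states[p], mu * len);
}

static bool is_ancestor(const IntegerVector &parent, int anc, int v) {
  int p = v;
  while (p >= 0) {
    if (p == anc) return true;
    p = parent[p];
  }
  return false;
}

// One sweep of genealogy updates for one locus; modifies parent/times/states
// in place and returns the updated likelihood parts and acceptance counts.
// [[Rcpp::export]]
NumericVector tree_sweep_cpp(IntegerVector parent, NumericVector times,
                             IntegerVector states, int nLeaf, double N0,
                             double N1, double TT, int shape, double mu,
                             int nTime, int nSwap, int nState,
                             double rootStep, double coalLL, double mutLL) {
  Traj tr{N0, N1, TT, shape};
  int nn = parent.size();
  std::vector<int> c1, c2;
  int accT = 0, accW = 0, accS = 0;

  // -- node time moves ---------------------------------------------------
  for (int rep = 0; rep < nTime; ++rep) {
    build_children(parent, c1, c2);
    int v = nLeaf + (int) (unif_rand() * (nn - nLeaf));
    double lower = std::max(times[c1[v]], times[c2[v]]);
    double told = times[v];
    double tnew, logHast = 0.0;
    if (parent[v] < 0) {
      double gap = told - lower;
      double fac = std::exp(rootStep * (unif_rand() - 0.5) * 2.0);
      tnew = lower + gap * fac;
      logHast = std::log(fac);
    } else {
      double upper = times[parent[v]];
      if (upper <= lower) continue;
      tnew = lower + unif_rand() * (upper - lower);
    }
    double oldMut = branch_lp(parent, times, states, mu, v) +
                    branch_lp(parent, times, states, mu, c1[v]) +
                    branch_lp(parent, times, states, mu, c2[v]);
    times[v] = tnew;
    double newMut = branch_lp(parent, times, states, mu, v) +
                    branch_lp(parent, times, states, mu, c1[v]) +
                    branch_lp(parent, times, states, mu, c2[v]);
    double newCoal = coal_ll(times, nLeaf, tr);
    double dll = (newCoal - coalLL) + (newMut - oldMut) + logHast;
    if (R_finite(dll) && (dll >= 0.0 || unif_rand() < std::exp(dll))) {
      coalLL = newCoal;
      mutLL += newMut - oldMut;
      ++accT;
    } else {
      times[v] = told;
    }
  }

  // -- wide exchange (topology) -------------------------------------------
  for (int rep = 0; rep < nSwap; ++rep) {
    int a = (int) (unif_rand() * nn);
    int b = (int) (unif_rand() * (nn - 1));
    if (b >= a) ++b;
    int pa = parent[a], pb = parent[b];
    if (pa < 0 || pb < 0 || pa == pb) continue;
    if (times[pa] <= times[b] || times[pb] <= times[a]) continue;
    if (is_ancestor(parent, a, b) || is_ancestor(parent, b, a)) continue;
    double oldMut = branch_lp(parent, times, states, mu, a) +
                    branch_lp(parent, times, states, mu, b);
    parent[a] = pb;
    parent[b] = pa;
    double newMut = branch_lp(parent, times, states, mu, a) +
                    branch_lp(parent, times, states, mu, b);
    double dll = newMut - oldMut;
    if (R_finite(dll) && (dll >= 0.0 || unif_rand() < std::exp(dll))) {
      mutLL += dll;
      ++accW;
    } else {
      parent[a] = pa;
      parent[b] = pb;
    }
  }

  // -- internal allele-state moves ----------------------------------------
  for (int rep = 0; rep < nState; ++rep) {
    build_children(parent, c1, c2);
    int v = nLeaf + (int) (unif_rand() * (nn - nLeaf));
    int mag = unif_rand() < 0.5 ? 1 : 2;
    int delta = unif_rand() < 0.5 ? mag : -mag;
    double oldMut = branch_lp(parent, times, states, mu, v) +
                    branch_lp(parent, times, states, mu, c1[v]) +
                    branch_lp(parent, times, states, mu, c2[v]);
    states[v] += delta;
    double newMut = branch_lp(parent, times, states, mu, v) +
                    branch_lp(parent, times, states, mu, c1[v]) +
                    branch_lp(parent, times, states, mu, c2[v]);
    double dll = newMut - oldMut;
    if (R_finite(dll) && (dll >= 0.0 || unif_rand() < std::exp(dll))) {
      mutLL += dll;
      ++accS;
    } else {
      states[v] -= delta;
    }
  }

  return NumericVector::create(coalLL, mutLL, (double) accT, (double) accW,
                               (double) accS);
}

// Initialize a genealogy with valid support: coalescent node times simulated
// under the trajectory, uniformly random pairings, and internal states
// copied from a random child so every branch carries a finite transition
// probability once mu > 0.
// [[Rcpp::export]]
List init_tree_cpp(IntegerVector leafStates, double N0, double N1, double TT,
                   int shape) {
  Traj tr{N0, N1, TT, shape};
  int n = leafStates.size();
  int nn = 2 * n - 1;
  IntegerVector parent(nn, -1);
  NumericVector times(nn, 0.0);
  IntegerVector states(nn, 0);
  for (int i = 0; i < n; ++i) states[i] = leafStates[i];
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int nextNode = n;
  while (active.size() > 1) {
    double k = (double) active.size();
    double E = exp_rand();
    double Lt = traj_intensity(tr, t) + 4.0 * E / (k * (k - 1.0));
    t = traj_intensity_inv(tr, Lt);
    int i = (int) (unif_rand() * active.size());
    int j = (int) (unif_rand() * (active.size() - 1));
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int pn = nextNode++;
    times[pn] = t;
    parent[a] = pn;
    parent[b] = pn;
    states[pn] = unif_rand() < 0.5 ? states[a] : states[b];
    active[i] = pn;
    active.erase(active.begin() + j);
  }
  return List::create(_["parent"] = parent, _["times"] = times,
                      _["states"] = states);
}
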