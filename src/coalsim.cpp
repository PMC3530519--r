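// Coalescent simulation of microsatellite allele sizes under a single
// population-size change, two-phase mutation, serial sampling and an
// island-model structured variant. Times are in generations before
// sampling; pairwise coalescence rate for diploid gene copies is
// 1/(2 N(t)) per generation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "traj.h"

using namespace Rcpp;

// Given a built tree (parent pointers, node times), drop mutations on every
// branch and propagate allele states from the root (state 0) to the leaves.
static void mutate_tree(const std::vector<int> &parent,
                        const std::vector<double> &times,
                        std::vector<int> &state,
                        double mu, double ps, double q, int msMin) {
  int nn = parent.size();
  std::vector<int> ord(nn);
  for (int i = 0; i < nn; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return times[a] > times[b]; });
  for (int i = 0; i < nn; ++i) {
    int v = ord[i];
    if (parent[v] < 0) { state[v] = 0; continue; }
    double len = times[parent[v]] - times[v];
    int nmut = (mu * len > 0) ? (int) R::rpois(mu * len) : 0;
    state[v] = state[parent[v]] + tpm_net_disp(nmut, ps, q, msMin);
  }
}

// Single-deme serial coalescent with exact inversion of the cumulative
// coalescent intensity. sampleTimes gives the age (generations) of each
// gene copy. Returns leaf allele sizes relative to the root (= 0).
static std::vector<int> sim_single(const std::vector<double> &sampleTimes,
                                   const Traj &tr, double mu,
                                   double ps, double q, int msMin) {
  int n = sampleTimes.size();
  int nn = 2 * n - 1;
  std::vector<int> parent(nn, -1);
  std::vector<double> times(nn, 0.0);
  for (int i = 0; i < n; ++i) times[i] = sampleTimes[i];

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return sampleTimes[a] < sampleTimes[b];
  });

  std::vector<int> active;
  int pos = 0, nextNode = n;
  double t = sampleTimes[ord[0]];
  while (pos < n && sampleTimes[ord[pos]] <= t) active.push_back(ord[pos++]);

  while (active.size() > 1 || pos < n) {
    if (active.size() < 2) {
      t = sampleTimes[ord[pos]];
      while (pos < n && sampleTimes[ord[pos]] <= t) active.push_back(ord[pos++]);
      continue;
    }
    double k = (double) active.size();
    double E = exp_rand();
    double Ltarget = traj_intensity(tr, t) + 4.0 * E / (k * (k - 1.0));
    double t2 = traj_intensity_inv(tr, Ltarget);
    if (pos < n && t2 > sampleTimes[ord[pos]]) {
      t = sampleTimes[ord[pos]];
      while (pos < n && sampleTimes[ord[pos]] <= t) active.push_back(ord[pos++]);
      continue;
    }
    int i = (int) (unif_rand() * active.size());
    int j = (int) (unif_rand() * (active.size() - 1));
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int pn = nextNode++;
    times[pn] = t2;
    parent[a] = pn;
    parent[b] = pn;
    // replace a by pn, remove b
    active[i] = pn;
    active.erase(active.begin() + j);
    t = t2;
  }

  std::vector<int> state(nn, 0);
  mutate_tree(parent, times, state, mu, ps, q, msMin);
  state.resize(n);
  return state;
}

// [[Rcpp::export]]
IntegerVector sim_locus_cpp(NumericVector sampleTimes, double N0, double N1,
                            double TT, int shape, double mu, double ps,
                            double q, int msMin) {
  Traj tr{N0, N1, TT, shape};
  std::vector<double> st(sampleTimes.begin(), sampleTimes.end());
  std::vector<int> out = sim_single(st, tr, mu, ps, q, msMin);
  return wrap(out);
}

// [[Rcpp::export]]
double traj_intensity_cpp(double t, double N0, double N1, double TT,
                          int shape) {
  Traj tr{N0, N1, TT, shape};
  return traj_intensity(tr, t);
}

// [[Rcpp::export]]
double traj_N_cpp(double t, double N0, double N1, double TT, int shape) {
  Traj tr{N0, N1, TT, shape};
  return traj_N(tr, t);
}

// Per-replicate summary statistics of a simulated locus: number of alleles,
// unbiased expected heterozygosity, allele-size range, and mean squared
// pairwise size difference. Used for equilibrium closed-form checks and
// null distributions.
// [[Rcpp::export]]
NumericMatrix sim_locus_stats_cpp(int nGenes, double N0, double N1, double TT,
                                  int shape, double mu, double ps, double q,
                                  int msMin, int reps) {
  Traj tr{N0, N1, TT, shape};
  std::vector<double> st(nGenes, 0.0);
  NumericMatrix out(reps, 4);
  colnames(out) = CharacterVector::create("k", "he", "range", "msd");
  for (int r = 0; r < reps; ++r) {
    std::vector<int> g = sim_single(st, tr, mu, ps, q, msMin);
    std::sort(g.begin(), g.end());
    int k = 1;
    for (int i = 1; i < nGenes; ++i) if (g[i] != g[i - 1]) ++k;
    double sum = 0, sum2 = 0;
    for (int i = 0; i < nGenes; ++i) { sum += g[i]; sum2 += (double) g[i] * g[i]; }
    double n = (double) nGenes;
    // sum of squared frequencies
    double sp2 = 0;
    int run = 1;
    for (int i = 1; i <= nGenes; ++i) {
      if (i < nGenes && g[i] == g[i - 1]) { ++run; continue; }
      sp2 += (run / n) * (run / n);
      run = 1;
    }
    double he = (n / (n - 1.0)) * (1.0 - sp2);
    // mean over unordered pairs of (xi - xj)^2 = 2 * n/(n-1) * Var_pop
    double varp = sum2 / n - (sum / n) * (sum / n);
    double msd = 2.0 * n / (n - 1.0) * varp;
    out(r, 0) = k;
    out(r, 1) = he;
    out(r, 2) = g[nGenes - 1] - g[0];
    out(r, 3) = msd;
  }
  return out;
}

// Multi-locus mean M-ratio (k / (range + 1)) for equilibrium replicate
// datasets; monomorphic loci contribute M = 1 when includeMono, else are
// dropped from the mean.
// [[Rcpp::export]]
NumericVector sim_mean_M_cpp(int nGenes, int nLoci, double theta, double mu,
                             double ps, double q, int msMin, int reps,
                             bool includeMono) {
  double N = theta / (4.0 * mu);
  Traj tr{N, N, 0.0, 0};
  std::vector<double> st(nGenes, 0.0);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double sum = 0;
    int cnt = 0;
    for (int l = 0; l < nLoci; ++l) {
      std::vector<int> g = sim_single(st, tr, mu, ps, q, msMin);
      int mn = g[0], mx = g[0];
      std::vector<int> u(g);
      std::sort(u.begin(), u.end());
      int k = 1;
      for (int i = 1; i < nGenes; ++i) if (u[i] != u[i - 1]) ++k;
      mn = u[0];
      mx = u[nGenes - 1];
      if (k == 1 && !includeMono) continue;
      sum += (double) k / (double) (mx - mn + 1);
      ++cnt;
    }
    out[r] = cnt > 0 ? sum / cnt : NA_REAL;
  }
  return out;
}

// Equilibrium unbiased He replicates conditional on the observed number of
// alleles k: rejection sampling at a caller-supplied theta. Returns the
// accepted He values (may be shorter than `need` if maxAttempts is hit)
// and the number of attempts used.
// [[Rcpp::export]]
List sim_he_given_k_cpp(int nGenes, int k, double theta, double mu, double ps,
                        double q, int msMin, int need, int maxAttempts) {
  double N = theta / (4.0 * mu);
  Traj tr{N, N, 0.0, 0};
  std::vector<double> st(nGenes, 0.0);
  std::vector<double> he;
  he.reserve(need);
  int att = 0;
  double n = (double) nGenes;
  while ((int) he.size() < need && att < maxAttempts) {
    ++att;
    std::vector<int> g = sim_single(st, tr, mu, ps, q, msMin);
    std::sort(g.begin(), g.end());
    int kk = 1;
    for (int i = 1; i < nGenes; ++i) if (g[i] != g[i - 1]) ++kk;
    if (kk != k) continue;
    double sp2 = 0;
    int run = 1;
    for (int i = 1; i <= nGenes; ++i) {
      if (i < nGenes && g[i] == g[i - 1]) { ++run; continue; }
      sp2 += (run / n) * (run / n);
      run = 1;
    }
    he.push_back((n / (n - 1.0)) * (1.0 - sp2));
  }
  return List::create(_["he"] = wrap(he), _["attempts"] = att);
}

// Mean number of alleles in equilibrium samples at a given theta (used by
// the theta search of the heterozygosity-excess test).
// [[Rcpp::export]]
double sim_mean_k_cpp(int nGenes, double theta, double mu, double ps,
                      double q, int msMin, int reps) {
  double N = theta / (4.0 * mu);
  Traj tr{N, N, 0.0, 0};
  std::vector<double> st(nGenes, 0.0);
  double tot = 0;
  for (int r = 0; r < reps; ++r) {
    std::vector<int> g = sim_single(st, tr, mu, ps, q, msMin);
    std::sort(g.begin(), g.end());
    int k = 1;
    for (int i = 1; i < nGenes; ++i) if (g[i] != g[i - 1]) ++k;
    tot += k;
  }
  return tot / reps;
}

// Wright-Fisher forward evolution of a gene pool: each generation the
// 2 * nBreeders gametes are drawn with replacement from the previous pool
// and mutated. Returns the final pool.
// [[Rcpp::export]]
IntegerVector wf_evolve_cpp(IntegerVector pool, int nGenerations,
                            int nBreeders, double mu, double ps, double q,
                            int msMin) {
  std::vector<int> cur(pool.begin(), pool.end());
  int m = 2 * nBreeders;
  for (int gen = 0; gen < nGenerations; ++gen) {
    std::vector<int> nxt(m);
    for (int j = 0; j < m; ++j) {
      int src = (int) (unif_rand() * cur.size());
      int nmut = (int) R::rpois(mu);
      nxt[j] = cur[src] + tpm_net_disp(nmut, ps, q, msMin);
    }
    cur.swap(nxt);
  }
  return wrap(cur);
}

// Structured serial coalescent (finite island model) with a global size
// scaler from the trajectory: deme i has size demeSizes[i] * N(t)/N0.
// migMatrix[i][j] is the per-generation backward migration rate from deme i
// to deme j. merges rows (time, from, to) move all lineages of deme `from`
// into deme `to` at `time` and silence migration of the dead deme.
// Simulated by thinning with segment-wise exact bounds (N monotone on
// [0, T] and constant beyond).
// [[Rcpp::export]]
IntegerVector sim_locus_struct_cpp(IntegerVector deme, NumericVector sampleTimes,
                                   NumericVector demeSizes,
                                   NumericMatrix migMatrix,
                                   NumericMatrix merges,
                                   double N0, double N1, double TT, int shape,
                                   double mu, double ps, double q,
                                   int msMin) {
  Traj tr{N0, N1, TT, shape};
  int n = deme.size();
  int d = demeSizes.size();
  int nn = 2 * n - 1;
  std::vector<int> parent(nn, -1);
  std::vector<double> times(nn, 0.0);
  std::vector<int> nodeDeme(nn, 0);
  for (int i = 0; i < n; ++i) { times[i] = sampleTimes[i]; nodeDeme[i] = deme[i]; }

  std::vector<std::vector<double> > mig(d, std::vector<double>(d, 0.0));
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) mig[i][j] = migMatrix(i, j);

  // boundaries: sample activations, merges, trajectory change time
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return sampleTimes[a] < sampleTimes[b];
  });
  std::vector<int> mord(merges.nrow());
  for (int i = 0; i < (int) mord.size(); ++i) mord[i] = i;
  std::sort(mord.begin(), mord.end(), [&](int a, int b) {
    return merges(a, 0) < merges(b, 0);
  });

  std::vector<std::vector<int> > active(d);
  int pos = 0, mpos = 0, nextNode = n;
  double t = sampleTimes[ord[0]];
  auto activate = [&](double now) {
    while (pos < n && sampleTimes[ord[pos]] <= now) {
      active[nodeDeme[ord[pos]]].push_back(ord[pos]);
      ++pos;
    }
  };
  auto applyMerges = [&](double now) {
    while (mpos < (int) mord.size() && merges(mord[mpos], 0) <= now) {
      int from = (int) merges(mord[mpos], 1);
      int to = (int) merges(mord[mpos], 2);
      for (size_t i = 0; i < active[from].size(); ++i)
        active[to].push_back(active[from][i]);
      active[from].clear();
      for (int j = 0; j < d; ++j) { mig[from][j] = 0.0; mig[j][from] = 0.0; }
      // future samples of the dead deme land in the receiving deme
      for (int v = 0; v < nn; ++v) if (nodeDeme[v] == from) nodeDeme[v] = to;
      ++mpos;
    }
  };
  activate(t);
  applyMerges(t);

  int guard = 0;
  const int guardMax = 100000000;
  while (true) {
    int totalActive = 0;
    for (int i = 0; i < d; ++i) totalActive += active[i].size();
    if (totalActive <= 1 && pos >= n) break;
    if (++guard > guardMax)
      stop("structured coalescent failed to coalesce (check migration/merge)");

    // next boundary after t
    double segEnd = R_PosInf;
    if (pos < n) segEnd = std::min(segEnd, sampleTimes[ord[pos]]);
    if (mpos < (int) mord.size()) segEnd = std::min(segEnd, merges(mord[mpos], 0));
    if (tr.shape != 0 && t < tr.T) segEnd = std::min(segEnd, tr.T);

    if (totalActive < 2) {
      if (!R_finite(segEnd))
        stop("structured coalescent: lone lineage with no pending events");
      t = segEnd;
      activate(t);
      applyMerges(t);
      continue;
    }

    // bound on 1/g over [t, segEnd] (g monotone on the segment)
    double gnow = traj_N(tr, t) / tr.N0;
    double gend = R_finite(segEnd) ? traj_N(tr, segEnd) / tr.N0
                                   : traj_N(tr, tr.T + 1.0) / tr.N0;
    double supInvG = std::max(1.0 / gnow, 1.0 / gend);

    double coalMax = 0.0, migTot = 0.0;
    for (int i = 0; i < d; ++i) {
      double k = (double) active[i].size();
      coalMax += k * (k - 1.0) / 2.0 / (2.0 * demeSizes[i]) * supInvG;
      double mout = 0.0;
      for (int j = 0; j < d; ++j) mout += mig[i][j];
      migTot += k * mout;
    }
    double lamMax = coalMax + migTot;
    if (lamMax <= 0.0) {
      if (!R_finite(segEnd))
        stop("structured coalescent cannot coalesce: zero migration, ",
             "multiple demes and no merge time");
      t = segEnd;
      activate(t);
      applyMerges(t);
      continue;
    }
    double dt = exp_rand() / lamMax;
    if (t + dt >= segEnd) {
      if (!R_finite(segEnd))
        stop("structured coalescent cannot coalesce: zero migration, "
             "multiple demes and no merge time");
      t = segEnd;
      activate(t);
      applyMerges(t);
      continue;
    }
    t += dt;
    double g = traj_N(tr, t) / tr.N0;
    double u = unif_rand() * lamMax;
    bool done = false;
    for (int i = 0; i < d && !done; ++i) {
      double k = (double) active[i].size();
      double ci = k * (k - 1.0) / 2.0 / (2.0 * demeSizes[i] * g);
      if (u < ci) {
        int ai = (int) (unif_rand() * k);
        int aj = (int) (unif_rand() * (k - 1.0));
        if (aj >= ai) ++aj;
        int a = active[i][ai], b = active[i][aj];
        int pn = nextNode++;
        times[pn] = t;
        nodeDeme[pn] = i;
        parent[a] = pn;
        parent[b] = pn;
        active[i][ai] = pn;
        active[i].erase(active[i].begin() + aj);
        done = true;
      } else u -= ci;
    }
    if (!done) {
      for (int i = 0; i < d && !done; ++i) {
        for (int j = 0; j < d && !done; ++j) {
          double mij = active[i].size() * mig[i][j];
          if (u < mij) {
            int ai = (int) (unif_rand() * active[i].size());
            int v = active[i][ai];
            active[i].erase(active[i].begin() + ai);
            active[j].push_back(v);
            nodeDeme[v] = j;
            done = true;
          } else u -= mij;
        }
      }
    }
    // if still !done the proposal was thinned away: nothing happens
  }

  std::vector<int> state(nn, 0);
  mutate_tree(parent, times, state, mu, ps, q, msMin);
  state.resize(n);
  return wrap(state);
}
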