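#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of a mass-action reaction network with delayed
// product-update reactions (Gillespie algorithm with the Bratsun
// modification): delayed reactions fire at times set by their instantaneous
// propensities but their stoichiometric updates are applied only after the
// delay.  Delayed channels carry product-only stoichiometry, so nothing is
// consumed at initiation.  The piecewise-constant input K(t) is handled by
// inserting barrier events at its switch times, preserving exactness.
//
// Reactions are encoded by columns of equal length nreact:
//   rate       -- stochastic rate constant (already volume-converted)
//   order      -- 0, 1 or 2 reactant species
//   s1, s2     -- reactant species indices (1-based; 0 = unused)
//   scales_k   -- propensity multiplied by K(t) if 1
//   delay      -- completion delay in minutes (0 = instantaneous)
// Stoichiometry is a nreact x nspecies integer matrix.
//
// Random numbers come from R's RNG, so set.seed() gives bit-identical runs.

struct Completion {
  double time;
  int reaction;
  bool operator>(const Completion& o) const { return time > o.time; }
};

// [[Rcpp::export(name = ".ssa_run")]]
NumericMatrix ssa_run(IntegerVector init,
                      NumericVector rate, IntegerVector order,
                      IntegerVector s1, IntegerVector s2,
                      IntegerVector scales_k, NumericVector delay,
                      IntegerMatrix stoich,
                      NumericVector k_times, NumericVector k_values,
                      NumericVector grid,
                      NumericVector q_times, IntegerVector q_rx) {
  const int nspec = init.size();
  const int nreact = rate.size();
  const int ngrid = grid.size();
  std::vector<double> x(nspec);
  for (int i = 0; i < nspec; ++i) x[i] = init[i];

  NumericMatrix out(ngrid, nspec);
  int gi = 0;

  std::priority_queue<Completion, std::vector<Completion>,
                      std::greater<Completion> > pending;
  // pre-seeded in-flight completions (0-based reaction indices)
  for (int q = 0; q < q_times.size(); ++q) {
    Completion cm; cm.time = q_times[q]; cm.reaction = q_rx[q];
    pending.push(cm);
  }

  double t = grid[0];
  const double t_end = grid[ngrid - 1];
  int ki = 0;                      // index of current K segment
  while (ki + 1 < k_times.size() && k_times[ki + 1] <= t) ++ki;

  std::vector<double> a(nreact);
  RNGScope scope;

  while (t <= t_end) {
    double K = k_values[ki];
    double a0 = 0.0;
    for (int j = 0; j < nreact; ++j) {
      double aj = rate[j];
      if (order[j] >= 1) aj *= x[s1[j] - 1];
      if (order[j] == 2) {
        if (s2[j] == s1[j]) aj *= (x[s1[j] - 1] - 1.0) / 2.0;
        else aj *= x[s2[j] - 1];
      }
      if (scales_k[j]) aj *= K;
      if (aj < 0) stop("negative propensity encountered");
      a[j] = aj;
      a0 += aj;
    }

    double t_react = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    double t_comp = pending.empty() ? R_PosInf : pending.top().time;
    double t_switch = (ki + 1 < k_times.size()) ? k_times[ki + 1] : R_PosInf;
    double t_next = std::min(t_react, std::min(t_comp, t_switch));

    // record grid samples strictly before the next state change
    while (gi < ngrid && grid[gi] < t_next) {
      for (int i = 0; i < nspec; ++i) out(gi, i) = x[i];
      ++gi;
    }
    if (gi >= ngrid || t_next > t_end) break;

    if (t_switch <= t_comp && t_switch <= t_react) {
      t = t_switch;
      ++ki;                                   // propensity barrier only
    } else if (t_comp < t_react) {
      t = t_comp;
      int j = pending.top().reaction;
      pending.pop();
      for (int i = 0; i < nspec; ++i) x[i] += stoich(j, i);
    } else {
      t = t_react;
      double u = unif_rand() * a0, c = 0.0;
      int j = nreact - 1;
      for (int jj = 0; jj < nreact; ++jj) {
        c += a[jj];
        if (u <= c) { j = jj; break; }
      }
      if (delay[j] > 0.0) {
        Completion cm; cm.time = t + delay[j]; cm.reaction = j;
        pending.push(cm);
      } else {
        for (int i = 0; i < nspec; ++i) x[i] += stoich(j, i);
      }
    }
    for (int i = 0; i < nspec; ++i)
      if (x[i] < 0) stop("species copy number went negative");
  }
  while (gi < ngrid) {                        // tail: no further events
    for (int i = 0; i < nspec; ++i) out(gi, i) = x[i];
    ++gi;
  }
  return out;
}
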