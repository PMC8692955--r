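#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Central-place foraging step loop.
//
// Per time-step, every unit whose current patch is exhausted (k = 0) makes
// one move: a foraging move to the in-radius patch minimising d(home, p)/k_p,
// or, when the best ratio outside the radius beats the best inside (or no
// in-radius patch holds food) and an eligible new home exists at
// d(home, p) >= 2r, a residential move to the patch minimising that ratio.
// After all moves every unit removes one resource unit from its patch and
// every co-located unordered pair gains one tie-weight unit.  Ties in the
// argmins are broken toward the lowest patch id.  No randomness lives here:
// initial placement is drawn in R, everything else is deterministic.
//
// [[Rcpp::export]]
List cpf_core(NumericVector px, NumericVector py, IntegerVector k_init,
              double r, IntegerVector init_patch, int n_steps,
              int snapshot_interval) {
  const int P = px.size();
  const int n = init_patch.size();
  std::vector<int> k(k_init.begin(), k_init.end());
  std::vector<int> home(n), loc(n);
  for (int u = 0; u < n; ++u) {
    home[u] = init_patch[u];
    loc[u]  = init_patch[u];
  }

  NumericMatrix W(n, n);
  std::vector<int> log_unit, log_step, log_kind, log_to;  // kind: 0 = foraging, 1 = residential
  std::vector<double> log_dist;
  IntegerVector coloc(n_steps);
  List snaps;
  std::vector<int> snap_steps;
  const double twor = 2.0 * r;

  for (int t = 0; t < n_steps; ++t) {
    for (int u = 0; u < n; ++u) {
      if (k[loc[u]] > 0) continue;  // still food here: stay
      const double hx = px[home[u]], hy = py[home[u]];
      int best_in = -1, best_out = -1, best_home = -1;
      double rat_in = R_PosInf, rat_out = R_PosInf, rat_home = R_PosInf;
      for (int p = 0; p < P; ++p) {
        if (k[p] <= 0) continue;
        const double dx = px[p] - hx, dy = py[p] - hy;
        const double d = std::sqrt(dx * dx + dy * dy);
        const double ratio = d / k[p];
        if (d <= r) {
          if (ratio < rat_in)  { rat_in = ratio;  best_in = p; }
        } else {
          if (ratio < rat_out) { rat_out = ratio; best_out = p; }
        }
        if (d >= twor) {
          if (ratio < rat_home) { rat_home = ratio; best_home = p; }
        }
      }
      bool relocate;
      if (best_in < 0)
        relocate = (best_home >= 0);
      else
        relocate = (best_out >= 0 && rat_out < rat_in && best_home >= 0);
      if (relocate) {
        const double dx = px[best_home] - hx, dy = py[best_home] - hy;
        log_unit.push_back(u + 1);
        log_step.push_back(t + 1);
        log_kind.push_back(1);
        log_to.push_back(best_home + 1);
        log_dist.push_back(std::sqrt(dx * dx + dy * dy));
        home[u] = best_home;
        loc[u]  = best_home;
      } else if (best_in >= 0) {
        const double ox = px[loc[u]], oy = py[loc[u]];
        const double dx = px[best_in] - ox, dy = py[best_in] - oy;
        log_unit.push_back(u + 1);
        log_step.push_back(t + 1);
        log_kind.push_back(0);
        log_to.push_back(best_in + 1);
        log_dist.push_back(std::sqrt(dx * dx + dy * dy));
        loc[u] = best_in;
      }
      // else: nothing reachable, idle in place
    }
    // depletion: one unit per occupant, floored at zero
    for (int u = 0; u < n; ++u)
      if (k[loc[u]] > 0) --k[loc[u]];
    // co-location ties
    int cc = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v)
        if (loc[u] == loc[v]) {
          W(u, v) += 1.0;
          W(v, u) += 1.0;
          ++cc;
        }
    coloc[t] = cc;
    if (snapshot_interval > 0 && (t + 1) % snapshot_interval == 0) {
      snaps.push_back(clone(W));
      snap_steps.push_back(t + 1);
    }
  }

  return List::create(
    _["weights"]    = W,
    _["moves"]      = DataFrame::create(
        _["unit"] = log_unit, _["step"] = log_step,
        _["kind"] = log_kind, _["to"] = log_to,
        _["distance"] = log_dist),
    _["k_final"]    = IntegerVector(k.begin(), k.end()),
    _["home"]       = IntegerVector(home.begin(), home.end()),
    _["location"]   = IntegerVector(loc.begin(), loc.end()),
    _["coloc"]      = coloc,
    _["snapshots"]  = snaps,
    _["snap_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()));
}
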