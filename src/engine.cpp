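#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gate type codes shared with compile_network() on the R side:
//   0 insulin_level   constant, the experiment's insulin fraction
//   1 mtorc1_drug     constant, 1 - mtorc1_inhibition
//   2 mtorc1_activity (1 - inhibition) * phi^gamma, phi from the GAPDH pools
//   3 feedback        1 + beta * count[species] / sum(count[pool])
//   4 pool_fraction   sum(count[num]) / sum(count[den]) (0 when denominator 0)
//   5 saturating      S / (S + half)

struct GateDef {
  int type;
  std::vector<int> idx;   // num species (or the single species)
  std::vector<int> den;   // denominator pool
  double par;             // beta / half / gamma
};

struct ReactionDef {
  int law;                // 0 michaelis_menten, 1 mass_action
  std::vector<int> sub, sub_st, prod, prod_st;
  int enz;                // -1 when absent
  double vmax, km, k, coef;
  std::vector<int> gates; // indices into gate table
};

static double eval_gate(const GateDef &g, const std::vector<double> &cnt,
                        double insulin, double inhibition,
                        int i_free, int i_busy) {
  switch (g.type) {
  case 0: return insulin;
  case 1: return 1.0 - inhibition;
  case 2: {
    double tot = cnt[i_free] + cnt[i_busy];
    double phi = tot > 0 ? cnt[i_busy] / tot : 0.0;
    return (1.0 - inhibition) * std::pow(phi, g.par);
  }
  case 3: {
    double tot = 0.0;
    for (int j : g.den) tot += cnt[j];
    return tot > 0 ? 1.0 + g.par * cnt[g.idx[0]] / tot : 1.0;
  }
  case 4: {
    double tot = 0.0, num = 0.0;
    for (int j : g.den) tot += cnt[j];
    for (int j : g.idx) num += cnt[j];
    return tot > 0 ? num / tot : 0.0;
  }
  case 5: {
    double s = cnt[g.idx[0]];
    return s / (s + g.par);
  }
  }
  return 1.0;
}

// Simulate one cell for n_steps of size dt, recording every `stride` steps
// (plus the initial and final states). Counts are integer-valued throughout;
// transfers are binomial thinnings of the limiting substrate, applied in the
// declared reaction order so shared substrates can never go negative.
// [[Rcpp::export]]
List sim_cell_cpp(NumericVector init, List reactions, List gates,
                  LogicalVector boundary, double dt, int n_steps, int stride,
                  double insulin, double inhibition, double clamp_phi,
                  int gapdh_free, int gapdh_busy, double p_max) {
  const int n_sp = init.size();
  std::vector<double> cnt(init.begin(), init.end());

  // decode tables once per call
  std::vector<GateDef> G;
  for (int i = 0; i < gates.size(); ++i) {
    List g = gates[i];
    GateDef gd;
    gd.type = as<int>(g["type"]);
    gd.idx = as<std::vector<int>>(g["idx"]);
    gd.den = as<std::vector<int>>(g["den"]);
    gd.par = as<double>(g["par"]);
    G.push_back(gd);
  }
  std::vector<ReactionDef> R_;
  for (int i = 0; i < reactions.size(); ++i) {
    List r = reactions[i];
    ReactionDef rd;
    rd.law = as<int>(r["law"]);
    rd.sub = as<std::vector<int>>(r["sub"]);
    rd.sub_st = as<std::vector<int>>(r["sub_st"]);
    rd.prod = as<std::vector<int>>(r["prod"]);
    rd.prod_st = as<std::vector<int>>(r["prod_st"]);
    rd.enz = as<int>(r["enz"]);
    rd.vmax = as<double>(r["vmax"]);
    rd.km = as<double>(r["km"]);
    rd.k = as<double>(r["k"]);
    rd.coef = as<double>(r["coef"]);
    rd.gates = as<std::vector<int>>(r["gates"]);
    R_.push_back(rd);
  }

  const int n_rec = n_steps / stride + 1 + (n_steps % stride ? 1 : 0);
  NumericMatrix out(n_rec, n_sp);
  NumericVector times(n_rec);
  int rec = 0;
  bool clamped = false;

  std::vector<double> gv(G.size());
  RNGScope scope;

  // clamp + record initial state
  if (clamp_phi >= 0) {
    double tot = cnt[gapdh_free] + cnt[gapdh_busy];
    cnt[gapdh_busy] = std::round(clamp_phi * tot);
    cnt[gapdh_free] = tot - cnt[gapdh_busy];
  }
  for (int s = 0; s < n_sp; ++s) out(rec, s) = cnt[s];
  times[rec++] = 0.0;

  for (int step = 1; step <= n_steps; ++step) {
    for (size_t gi = 0; gi < G.size(); ++gi)
      gv[gi] = eval_gate(G[gi], cnt, insulin, inhibition, gapdh_free, gapdh_busy);

    for (size_t ri = 0; ri < R_.size(); ++ri) {
      const ReactionDef &r = R_[ri];
      double gate = 1.0;
      for (int gi : r.gates) gate *= gv[gi];
      if (gate <= 0) continue;

      double rate;
      if (r.law == 0) { // michaelis_menten, single substrate
        double S = cnt[r.sub[0]];
        if (S <= 0) continue;
        double v = r.enz >= 0 ? r.vmax * cnt[r.enz] : r.vmax;
        rate = r.coef * gate * v * S / (r.km + S);
      } else {          // mass_action
        rate = r.coef * gate * r.k;
        for (size_t si = 0; si < r.sub.size(); ++si)
          for (int m = 0; m < r.sub_st[si]; ++m) rate *= cnt[r.sub[si]];
      }
      if (rate <= 0) continue;

      double n_conv;
      if (r.sub.empty()) { // zeroth-order synthesis
        n_conv = R::rpois(rate * dt);
      } else {
        double n_lim = 0;
        for (size_t si = 0; si < r.sub.size(); ++si) {
          double avail = std::floor(cnt[r.sub[si]] / r.sub_st[si]);
          if (si == 0 || avail < n_lim) n_lim = avail;
        }
        if (n_lim <= 0) continue;
        double p = rate * dt / n_lim;
        if (p > p_max) { p = p_max; clamped = true; }
        n_conv = R::rbinom(n_lim, p);
      }
      if (n_conv <= 0) continue;

      for (size_t si = 0; si < r.sub.size(); ++si) {
        if (boundary[r.sub[si]]) continue;
        cnt[r.sub[si]] -= r.sub_st[si] * n_conv;
        if (cnt[r.sub[si]] < 0) stop("internal error: negative count");
      }
      for (size_t pi = 0; pi < r.prod.size(); ++pi) {
        if (boundary[r.prod[pi]]) continue;
        cnt[r.prod[pi]] += r.prod_st[pi] * n_conv;
      }
    }

    // the occupancy clamp is a boundary condition: re-impose it after the
    // reactions so recorded states (and the next step's gates) honour it
    if (clamp_phi >= 0) {
      double tot = cnt[gapdh_free] + cnt[gapdh_busy];
      cnt[gapdh_busy] = std::round(clamp_phi * tot);
      cnt[gapdh_free] = tot - cnt[gapdh_busy];
    }

    if (step % stride == 0 || step == n_steps) {
      for (int s = 0; s < n_sp; ++s) out(rec, s) = cnt[s];
      times[rec++] = step * dt;
    }
  }

  return List::create(_["counts"] = out, _["times"] = times,
                      _["n_recorded"] = rec, _["clamped"] = clamped);
}
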