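#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Classical fixed-step RK4 for the three-state electrode-kinetics system:
//   dS/dt = src(t) - vm * S / (S + km)          (striatal dopamine, uM)
//   dE/dt = ks * S - ke * E + kg * G            (electrode dopamine, uM)
//   dG/dt = k1 * E - k2 * E * G - k3 * G        (adsorbed dopamine, uM-equiv)
// src is the release rate, piecewise constant within each step (the caller
// samples the burst envelope at step midpoints and places grid nodes exactly
// at burst boundaries, so src is genuinely constant over every step).
// Returns the three state trajectories on the n+1 node grid, or the index of
// the first step at which any state became non-finite.

// [[Rcpp::export]]
List rk4_core(NumericVector src, double dt, NumericVector y0,
              double vm, double km, double ks, double ke, double kg,
              double k1, double k2, double k3) {
  const int n = src.size();
  NumericVector S(n + 1), E(n + 1), G(n + 1);
  double s = y0[0], e = y0[1], g = y0[2];
  S[0] = s; E[0] = e; G[0] = g;

  double ds1, de1, dg1, ds2, de2, dg2, ds3, de3, dg3, ds4, de4, dg4;
  double ts, te, tg;

  for (int i = 0; i < n; ++i) {
    const double r = src[i];

    ds1 = r - vm * s / (s + km);
    de1 = ks * s - ke * e + kg * g;
    dg1 = k1 * e - k2 * e * g - k3 * g;

    ts = s + 0.5 * dt * ds1; te = e + 0.5 * dt * de1; tg = g + 0.5 * dt * dg1;
    ds2 = r - vm * ts / (ts + km);
    de2 = ks * ts - ke * te + kg * tg;
    dg2 = k1 * te - k2 * te * tg - k3 * tg;

    ts = s + 0.5 * dt * ds2; te = e + 0.5 * dt * de2; tg = g + 0.5 * dt * dg2;
    ds3 = r - vm * ts / (ts + km);
    de3 = ks * ts - ke * te + kg * tg;
    dg3 = k1 * te - k2 * te * tg - k3 * tg;

    ts = s + dt * ds3; te = e + dt * de3; tg = g + dt * dg3;
    ds4 = r - vm * ts / (ts + km);
    de4 = ks * ts - ke * te + kg * tg;
    dg4 = k1 * te - k2 * te * tg - k3 * tg;

    s += dt / 6.0 * (ds1 + 2.0 * ds2 + 2.0 * ds3 + ds4);
    e += dt / 6.0 * (de1 + 2.0 * de2 + 2.0 * de3 + de4);
    g += dt / 6.0 * (dg1 + 2.0 * dg2 + 2.0 * dg3 + dg4);

    if (!std::isfinite(s) || !std::isfinite(e) || !std::isfinite(g)) {
      return List::create(_["ok"] = false, _["bad_step"] = i + 1);
    }
    S[i + 1] = s; E[i + 1] = e; G[i + 1] = g;
  }

  return List::create(_["ok"] = true, _["S"] = S, _["E"] = E, _["G"] = G);
}
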