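#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler integration of the four-state docking scheme
// (ES, LS, TS, TSL) over a precomputed effective-[Ca2+] grid, with the
// instantaneous per-AP release and LS->TSL transfer maps applied at the
// grid indices in `ap_steps` (0-based). ca has length n_steps + 1 where
// n_steps is the index of the last AP; release at an AP uses the state
// integrated up to that instant, and the Ca2+ increment of that AP (already
// folded into ca) only drives the kinetics afterwards.
// [[Rcpp::export]]
List sim_core_cpp(IntegerVector ap_steps, NumericVector ca, double dt,
                  double b1, double k1_max, double K_M, double k2_0,
                  double s2, double b2, double b3, double f_tsl,
                  double p_fusion, double ca_rest, NumericVector state0) {
  const int n_ap = ap_steps.size();
  const int K = ca.size() - 1;
  double es = state0[0], ls = state0[1], ts = state0[2], tsl = state0[3];

  NumericVector released(n_ap);
  NumericMatrix states(n_ap, 4);

  int ai = 0;
  for (int k = 0; k <= K; ++k) {
    if (ai < n_ap && k == ap_steps[ai]) {
      const double rel = p_fusion * (ts + tsl);
      es += rel;
      ts *= (1.0 - p_fusion);
      tsl *= (1.0 - p_fusion);
      const double moved = f_tsl * ls;
      ls -= moved;
      tsl += moved;
      released[ai] = rel;
      states(ai, 0) = es; states(ai, 1) = ls;
      states(ai, 2) = ts; states(ai, 3) = tsl;
      ++ai;
    }
    if (k < K) {
      const double c = ca[k];
      const double k1 = k1_max * c / (c + K_M);
      double k2 = k2_0 + s2 * (c - ca_rest);
      if (k2 < 0.0) k2 = 0.0;
      const double d_es = -k1 * es + b1 * ls;
      const double d_ls = k1 * es - (b1 + k2) * ls + b2 * ts + tsl / b3;
      const double d_ts = k2 * ls - b2 * ts;
      const double d_tsl = -tsl / b3;
      es += dt * d_es;
      ls += dt * d_ls;
      ts += dt * d_ts;
      tsl += dt * d_tsl;
      if (es < -1e-9 || ls < -1e-9 || ts < -1e-9 || tsl < -1e-9 ||
          es > 1.0 + 1e-9 || ls > 1.0 + 1e-9 || ts > 1.0 + 1e-9 ||
          tsl > 1.0 + 1e-9) {
        stop("state occupancy left [0, 1] during integration; reduce dt");
      }
    }
  }

  const double total = es + ls + ts + tsl;
  if (std::abs(total - 1.0) > 1e-9)
    stop("occupancy conservation drifted beyond 1e-9; reduce dt");

  return List::create(_["released"] = released, _["states"] = states,
                      _["final"] = NumericVector::create(es, ls, ts, tsl));
}
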