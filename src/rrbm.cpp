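#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Annual reserve map with three branches keyed off the season's resource
// pool y + Ps:
//   pool <  L1        : RA  (accumulate, no reproduction)
//   L1 <= pool < L2   : AR  (asexual reproduction, cost d * (pool - L1))
//   pool >= L2        : SAR (flowering p, asexual q, seed set R * p,
//                            all proportional to pool - L1)
// Branch codes: 0 = RA, 1 = AR, 2 = SAR.
//
// The same inline step feeds trajectory recording, the light-weight orbit
// used by the period classifier, and everything downstream, so every code
// path sees bit-identical arithmetic. At pool == L1 the AR cost is zero and
// the branch coincides with RA; pool == L2 flowers.

static inline int branch_of(double pool, double L1, double L2) {
  if (pool < L1) return 0;
  if (pool < L2) return 1;
  return 2;
}

static inline double step_once(double y, double L1, double L2, double Ps,
                               double p, double q, double d, double R,
                               int *b, double *cf, double *ca, double *cv) {
  double pool = y + Ps;
  *cf = 0.0; *ca = 0.0; *cv = 0.0;
  *b = branch_of(pool, L1, L2);
  if (*b == 1) {
    *cv = d * (pool - L1);
  } else if (*b == 2) {
    *cf = p * (pool - L1);
    *cv = q * (pool - L1);
    *ca = R * (*cf);
  }
  // reserves may go negative (overdraft); no clamping
  return y + Ps - (*cf + *ca + *cv);
}

// Full trajectory with per-year cost accounting. If |y| exceeds `guard`
// (or goes non-finite) the recording stops and `diverged_at` holds the
// offending 1-based year; otherwise diverged_at is -1.
// [[Rcpp::export(name = ".traj_core")]]
List traj_core(double L1, double L2, double Ps, double p, double q, double d,
               double R, double y0, int years, double guard) {
  NumericVector y_start(years), pool(years), C_f(years), C_a(years),
      C_v(years), y_next(years);
  IntegerVector branch(years);
  double y = y0;
  int diverged_at = -1, n = years;
  for (int t = 0; t < years; ++t) {
    int b;
    double cf, ca, cv;
    double nxt = step_once(y, L1, L2, Ps, p, q, d, R, &b, &cf, &ca, &cv);
    y_start[t] = y;
    pool[t] = y + Ps;
    branch[t] = b;
    C_f[t] = cf;
    C_a[t] = ca;
    C_v[t] = cv;
    y_next[t] = nxt;
    if (!R_FINITE(nxt) || std::fabs(nxt) > guard) {
      diverged_at = t + 1;
      n = t + 1;
      break;
    }
    y = nxt;
  }
  Range keep(0, n - 1);
  return List::create(
      _["y_start"] = y_start[keep], _["pool"] = pool[keep],
      _["branch"] = branch[keep], _["C_f"] = C_f[keep], _["C_a"] = C_a[keep],
      _["C_v"] = C_v[keep], _["y_next"] = y_next[keep],
      _["diverged_at"] = diverged_at);
}

// Post-burn-in orbit: reserve at the start of each window year plus the
// branch taken that year. Used by the period classifier and the numeric
// Lyapunov estimator, where per-year cost vectors are not needed.
// [[Rcpp::export(name = ".orbit_core")]]
List orbit_core(double L1, double L2, double Ps, double p, double q, double d,
                double R, double y0, int burn_in, int window, double guard) {
  double y = y0;
  int b;
  double cf, ca, cv;
  for (int t = 0; t < burn_in; ++t) {
    y = step_once(y, L1, L2, Ps, p, q, d, R, &b, &cf, &ca, &cv);
    if (!R_FINITE(y) || std::fabs(y) > guard)
      return List::create(_["y"] = NumericVector(0),
                          _["branch"] = IntegerVector(0),
                          _["diverged_at"] = t + 1);
  }
  NumericVector yw(window);
  IntegerVector bw(window);
  for (int t = 0; t < window; ++t) {
    yw[t] = y;
    double nxt = step_once(y, L1, L2, Ps, p, q, d, R, &b, &cf, &ca, &cv);
    bw[t] = b;
    if (!R_FINITE(nxt) || std::fabs(nxt) > guard)
      return List::create(_["y"] = NumericVector(0),
                          _["branch"] = IntegerVector(0),
                          _["diverged_at"] = burn_in + t + 1);
    y = nxt;
  }
  return List::create(_["y"] = yw, _["branch"] = bw, _["diverged_at"] = -1);
}
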