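#include <Rcpp.h>
using namespace Rcpp;

// Two-compartment infusion kinetics in amount space:
//   dA1/dt = R0(t) - (CL/V1) A1 - (Q/V1) A1 + (Q/V2) A2
//   dA2/dt =         (Q/V1) A1 - (Q/V2) A2,   Cp = A1/V1
// R0(t) is piecewise constant (sum of active infusions); boluses are
// instantaneous additions to A1.  Within a segment the linear system is
// propagated exactly via the 2x2 matrix exponential (Putzer form), so the
// solution is the superposition-of-biexponentials closed form without
// enumerating dose events one by one.

struct PkState {
  double a1, a2;
};

struct PkRates {
  double k10, k12, k21; // CL/V1, Q/V1, Q/V2
  double v1;
  double l1, l2;        // eigenvalues of the rate matrix (both <= 0)
};

static PkRates make_rates(const double* p) {
  // p = {CL, Q, V1, V2}
  PkRates r;
  r.k10 = p[0] / p[2];
  r.k12 = p[1] / p[2];
  r.k21 = p[1] / p[3];
  r.v1  = p[2];
  double s = r.k10 + r.k12 + r.k21;
  double det = r.k10 * r.k21;
  double disc = s * s - 4.0 * det;
  if (disc < 0.0) disc = 0.0; // numerically; analytically disc >= 0
  double root = std::sqrt(disc);
  r.l1 = 0.5 * (-s + root);
  r.l2 = 0.5 * (-s - root);
  return r;
}

// advance state by dt under constant infusion rate `rate`
static PkState advance(const PkState& x0, const PkRates& r, double rate,
                       double dt) {
  if (dt <= 0.0) return x0;
  // steady state under this rate: A1ss = rate/k10, A2ss = A1ss * k12/k21
  double a1ss = 0.0, a2ss = 0.0;
  if (rate != 0.0) {
    a1ss = rate / r.k10;
    a2ss = a1ss * r.k12 / r.k21;
  }
  double d1 = x0.a1 - a1ss, d2 = x0.a2 - a2ss;
  // exp(A dt) via Putzer: E = e1*I + r2*(A - l1*I)
  double e1 = std::exp(r.l1 * dt);
  double e2 = std::exp(r.l2 * dt);
  double dl = r.l1 - r.l2;
  double r2 = (std::fabs(dl) > 1e-12) ? (e1 - e2) / dl : dt * e1;
  // A - l1 I = [ -(k10+k12)-l1 ,  k21 ; k12 , -k21-l1 ]
  double m11 = -(r.k10 + r.k12) - r.l1;
  double m22 = -r.k21 - r.l1;
  PkState x;
  x.a1 = a1ss + e1 * d1 + r2 * (m11 * d1 + r.k21 * d2);
  x.a2 = a2ss + e1 * d2 + r2 * (r.k12 * d1 + m22 * d2);
  if (x.a1 < 0.0) x.a1 = 0.0;
  if (x.a2 < 0.0) x.a2 = 0.0;
  return x;
}

// Walk a dose grid and return central concentrations at `times` (sorted,
// non-negative).  seg_t (strictly increasing, seg_t[0] <= 0 allowed) gives
// segment start times; seg_rate[k] is the total infusion rate on
// [seg_t[k], seg_t[k+1]) (last segment extends to +Inf); seg_bolus[k] is a
// bolus amount added to the central compartment at seg_t[k].  Parameters
// p1 apply for t < switch_time, p2 from switch_time onward (occasion shift
// with state continuity); pass switch_time = R_PosInf for a single set.
// [[Rcpp::export(name = ".cpp_pk_profile")]]
NumericVector cpp_pk_profile(NumericVector seg_t, NumericVector seg_rate,
                             NumericVector seg_bolus, NumericVector p1,
                             NumericVector p2, double switch_time,
                             NumericVector times) {
  const int K = seg_t.size();
  const int n = times.size();
  NumericVector out(n);
  if (n == 0) return out;
  for (int j = 0; j < 4; ++j)
    if (!(p1[j] > 0.0) || !(p2[j] > 0.0))
      stop("PK parameters must be strictly positive");

  PkRates r1 = make_rates(REAL(p1));
  PkRates r2 = make_rates(REAL(p2));

  PkState x = {0.0, 0.0};
  double t = (K > 0 && seg_t[0] < 0.0) ? seg_t[0] : 0.0;
  bool switched = (switch_time <= t);
  int k = -1;            // current segment index (-1: before first segment)
  double rate = 0.0;
  int i = 0;
  // observations before the first event see a zero profile
  double t0 = (K > 0) ? seg_t[0] : R_PosInf;
  while (i < n && times[i] < t0) out[i++] = 0.0;
  if (K == 0) return out;
  t = t0;

  auto rates_now = [&](void) -> const PkRates& { return switched ? r2 : r1; };

  while (i < n || k < K - 1) {
    // next breakpoint: next segment start, the switch, or +Inf
    double t_next_seg = (k < K - 1) ? seg_t[k + 1] : R_PosInf;
    double t_next = t_next_seg;
    bool is_switch = false;
    if (!switched && switch_time > t && switch_time < t_next) {
      t_next = switch_time;
      is_switch = true;
    }
    if (k == -1) { // process first segment boundary at t = seg_t[0]
      k = 0;
      x.a1 += seg_bolus[0];
      rate = seg_rate[0];
      continue;
    }
    const PkRates& rr = rates_now();
    // emit observations inside (t, t_next); boundary obs are evaluated
    // after the boundary event (right-continuous dosing)
    while (i < n && times[i] < t_next) {
      PkState xo = advance(x, rr, rate, times[i] - t);
      out[i] = xo.a1 / rr.v1;
      ++i;
    }
    if (!R_finite(t_next)) break;
    x = advance(x, rr, rate, t_next - t);
    t = t_next;
    if (is_switch) {
      switched = true;
    } else {
      ++k;
      x.a1 += seg_bolus[k];
      rate = seg_rate[k];
      if (!switched && switch_time <= t) switched = true;
    }
    // observations exactly at t are handled on the next pass (post-event)
  }
  // remaining observations at/after the last breakpoint
  const PkRates& rr = rates_now();
  while (i < n) {
    PkState xo = advance(x, rr, rate, times[i] - t);
    out[i] = xo.a1 / rr.v1;
    ++i;
  }
  return out;
}

// Student-t log density sum on the log-concentration scale; returns -Inf if
// any predicted concentration is non-positive.
// [[Rcpp::export(name = ".cpp_t_loglik")]]
double cpp_t_loglik(NumericVector pred, NumericVector obs_log, double sigma,
                    double nu) {
  const int n = pred.size();
  double c = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0) -
             0.5 * std::log(nu * M_PI * sigma * sigma);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!(pred[i] > 0.0)) return R_NegInf;
    double z = (obs_log[i] - std::log(pred[i])) / sigma;
    ll += c - 0.5 * (nu + 1.0) * std::log1p(z * z / nu);
  }
  return ll;
}
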