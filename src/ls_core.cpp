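// Method-of-steps integrator for the lifespan tumor-growth DDE and its
// drug-perturbed variants.  The production rate k_in(t) is represented
// recursively (k_in(t) = p(w(t)) * k_in(t-T) * survival), with the full
// dense history of states and k_in kept as cubic Hermite data so that
// lagged lookups are O(log n).  Integration restarts at every breakpoint
// of the lattice {dose + i*T + j*T_A} where the right-hand side jumps.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct PkTerms {
  std::vector<double> td, coef, rate;
  std::vector<int> type; // 0: coef*exp(-rate*tau), 1: coef*tau*exp(-rate*tau)
  // side < 0 evaluates the left limit at a bolus time (the dose at t is
  // excluded), side >= 0 the post-dose right limit
  double conc(double t, int side = 1) const {
    double c = 0.0;
    for (size_t i = 0; i < td.size(); ++i) {
      double tau = t - td[i];
      if (tau < 0.0 || (side < 0 && tau == 0.0)) continue;
      double e = std::exp(-rate[i] * tau);
      c += (type[i] == 0) ? coef[i] * e : coef[i] * tau * e;
    }
    return c > 0.0 ? c : 0.0; // guard round-off from cancelling exponentials
  }
  double dconc(double t, int side = 1) const {
    double c = 0.0;
    for (size_t i = 0; i < td.size(); ++i) {
      double tau = t - td[i];
      if (tau < 0.0 || (side < 0 && tau == 0.0)) continue;
      double e = std::exp(-rate[i] * tau);
      c += (type[i] == 0) ? -coef[i] * rate[i] * e
                          : coef[i] * e * (1.0 - rate[i] * tau);
    }
    return c;
  }
};

// Division-efficiency forms.  threshold_power is computed on a log scale on
// both sides of w = wth so that r^psi never overflows.
struct Efficiency {
  int form; // 0 constant, 1 threshold_power, 2 switch_limit, 3 linear_phase
  double p0, wth, psi, pwth;
  double shape(double w) const { // the part multiplying (p0 - 1), in [0, 1]
    double r = w / wth;
    if (r <= 0.0) return 1.0;
    if (r <= 1.0) return std::pow(1.0 + std::pow(r, psi), -1.0 / psi);
    return (1.0 / r) * std::pow(1.0 + std::pow(r, -psi), -1.0 / psi);
  }
  double p(double w) const {
    switch (form) {
    case 0: return p0;
    case 1: return 1.0 + (p0 - 1.0) * shape(w);
    case 2: return (w <= wth) ? p0 : 1.0 + (p0 - 1.0) * wth / w;
    default: return 1.0 + pwth / w;
    }
  }
  double dp(double w) const {
    switch (form) {
    case 0: return 0.0;
    case 1: {
      double r = w / wth;
      if (r <= 0.0) return 0.0;
      // dp/dw = -(p0-1) * shape(w) / (wth * (r^(1-psi) + r))
      double denom = wth * (std::pow(r, 1.0 - psi) + r);
      return -(p0 - 1.0) * shape(w) / denom;
    }
    case 2: return (w <= wth) ? 0.0 : -(p0 - 1.0) * wth / (w * w);
    default: return -pwth / (w * w);
    }
  }
};

struct DrugSpec {
  int mechanism;   // 0 none, 1 non-cycle-specific, 2 cycle-specific
  int effect_form; // 0 linear k2*C, 1 Emax*C/(EC50+C)
  double k2, Emax, EC50, TA;
  double effect(double C) const {
    if (mechanism == 0 || C <= 0.0) return 0.0;
    return (effect_form == 0) ? k2 * C : Emax * C / (EC50 + C);
  }
  double deffect(double C, double dC) const {
    if (mechanism == 0 || C <= 0.0) return 0.0;
    if (effect_form == 0) return k2 * dC;
    double d = EC50 + C;
    return Emax * EC50 / (d * d) * dC;
  }
};

// Dense history: value + derivative at every committed step, with duplicate
// points at breakpoints carrying the right-side values.  Queries at a
// duplicated abscissa resolve to the later (right) point, which is the
// smooth continuation used on the interval being integrated.
struct History {
  std::vector<double> t;
  std::vector<double> M, dM, A, dA, X, dX, kin, dkin;
  double w0, kin0;
  void push(double tt, double m, double dm, double a, double da, double x,
            double dx, double k, double dk) {
    t.push_back(tt);
    M.push_back(m); dM.push_back(dm);
    A.push_back(a); dA.push_back(da);
    X.push_back(x); dX.push_back(dx);
    kin.push_back(k); dkin.push_back(dk);
  }
  static double hermite(double q, double t0, double t1, double y0, double y1,
                        double d0, double d1) {
    double h = t1 - t0;
    if (h <= 0.0) return y1;
    double s = (q - t0) / h, s2 = s * s, s3 = s2 * s;
    return (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * h * d0 +
           (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * h * d1;
  }
  static double dhermite(double q, double t0, double t1, double y0, double y1,
                         double d0, double d1) {
    double h = t1 - t0;
    if (h <= 0.0) return d1;
    double s = (q - t0) / h, s2 = s * s;
    return ((6 * s2 - 6 * s) * y0 + (3 * s2 - 4 * s + 1) * h * d0 +
            (-6 * s2 + 6 * s) * y1 + (3 * s2 - 2 * s) * h * d1) / h;
  }
  // side selects which smooth piece a query at an exactly-duplicated
  // breakpoint abscissa belongs to: +1 the later (right) piece -- used by
  // every stage except the one closing a segment -- and -1 the earlier
  // (left) piece, whose values were committed when its segment ended.
  // Queries are snapped to committed abscissae within `eps` because lag
  // arithmetic (e.g. n*T - T vs (n-1)*T) is not exact in floating point
  // and landing on the wrong side of a jump would cost an order of
  // accuracy.  Committed points are many orders of magnitude farther
  // apart than eps.
  static constexpr double eps = 1e-9;
  double get(const std::vector<double>& y, const std::vector<double>& dy,
             double q, double pre, int side, bool deriv = false) const {
    if (t.empty()) return pre;
    if (side >= 0) {
      if (q < t.front() - eps) return pre;
      // last index with t[i] <= q+eps (ties -> last duplicate = right)
      size_t i = std::upper_bound(t.begin(), t.end(), q + eps) - t.begin();
      if (i == 0) return pre;
      --i;
      if (i + 1 >= t.size() || t[i] >= q - eps) return deriv ? dy[i] : y[i];
      return deriv ? dhermite(q, t[i], t[i + 1], y[i], y[i + 1], dy[i],
                              dy[i + 1])
                   : hermite(q, t[i], t[i + 1], y[i], y[i + 1], dy[i],
                             dy[i + 1]);
    }
    if (q <= t.front() + eps) return pre;
    // first index with t[j] >= q-eps (ties -> first duplicate = left)
    size_t j = std::lower_bound(t.begin(), t.end(), q - eps) - t.begin();
    if (j >= t.size()) return deriv ? dy.back() : y.back();
    if (t[j] <= q + eps) return deriv ? dy[j] : y[j];
    if (j == 0) return pre;
    return deriv ? dhermite(q, t[j - 1], t[j], y[j - 1], y[j], dy[j - 1],
                            dy[j])
                 : hermite(q, t[j - 1], t[j], y[j - 1], y[j], dy[j - 1],
                           dy[j]);
  }
  double getM(double q, int side) const { return get(M, dM, q, w0, side); }
  double getA(double q, int side) const { return get(A, dA, q, 0.0, side); }
  double getX(double q, int side) const { return get(X, dX, q, 0.0, side); }
  double getkin(double q, int side) const {
    return get(kin, dkin, q, kin0, side);
  }
  double getdkin(double q, int side) const {
    return get(kin, dkin, q, 0.0, side, true);
  }
};

struct Model {
  double T, kin0, w0;
  Efficiency eff;
  DrugSpec drug;
  PkTerms pk;
  bool p_of_total;

  // derivatives of (M, A, X) at time t given state, using history for lags
  void rhs(const History& H, double t, double m, double a, double x,
           double& dm, double& da, double& dx, int side) const {
    double kinlag = H.getkin(t - T, side);
    double parg = p_of_total ? (m + a) : m;
    double p = eff.p(parg);
    switch (drug.mechanism) {
    case 0:
      dm = (p - 1.0) * kinlag;
      da = 0.0; dx = 0.0;
      return;
    case 1: {
      double C = pk.conc(t, side);
      double E = drug.effect(C);
      double Xlag = (t - T <= 0.0) ? 0.0 : H.getX(t - T, side);
      double S = std::exp(-(x - Xlag));
      double tlagA = t - drug.TA;
      double outflow = 0.0;
      if (tlagA > 0.0)
        outflow = drug.effect(pk.conc(tlagA, side)) * H.getM(tlagA, side);
      dm = (p - 1.0) * kinlag * S - E * m;
      da = E * m - outflow;
      dx = E;
      return;
    }
    default: {
      double C = pk.conc(t, side);
      double E = drug.effect(C);
      double tlagA = t - drug.TA;
      double outflow = 0.0;
      if (tlagA > 0.0)
        outflow = drug.effect(pk.conc(tlagA, side)) *
                  H.getkin(tlagA - T, side);
      dm = (p * (1.0 - E) - 1.0) * kinlag;
      da = E * kinlag - outflow;
      dx = 0.0;
      return;
    }
    }
  }

  // committed k_in(t) and its within-segment time derivative
  void kin_now(const History& H, double t, double m, double a, double dm,
               double da, double x, double& k, double& dk, int side) const {
    double kinlag = H.getkin(t - T, side);
    double dkinlag = (t - T <= 0.0) ? 0.0 : H.getdkin(t - T, side);
    double parg = p_of_total ? (m + a) : m;
    double dparg = p_of_total ? (dm + da) : dm;
    double p = eff.p(parg);
    double dpdt = eff.dp(parg) * dparg;
    switch (drug.mechanism) {
    case 0:
      k = p * kinlag;
      dk = dpdt * kinlag + p * dkinlag;
      return;
    case 1: {
      double Xlag = (t - T <= 0.0) ? 0.0 : H.getX(t - T, side);
      double S = std::exp(-(x - Xlag));
      double E = drug.effect(pk.conc(t, side));
      double Elag = (t - T <= 0.0) ? 0.0
                                   : drug.effect(pk.conc(t - T, side));
      double dS = -S * (E - Elag);
      k = p * kinlag * S;
      dk = dpdt * kinlag * S + p * dkinlag * S + p * kinlag * dS;
      return;
    }
    default: {
      double C = pk.conc(t, side);
      double E = drug.effect(C);
      double dE = drug.deffect(C, pk.dconc(t, side));
      k = p * (1.0 - E) * kinlag;
      dk = dpdt * (1.0 - E) * kinlag - p * dE * kinlag +
           p * (1.0 - E) * dkinlag;
      return;
    }
    }
  }
};

std::vector<double> build_breakpoints(double t_last, double T, double TA,
                                      int mechanism,
                                      const std::vector<double>& doses) {
  std::vector<double> base;
  base.push_back(0.0);
  for (double d : doses)
    if (d >= 0.0 && d < t_last) base.push_back(d);
  std::vector<double> pts;
  int nT = (int)std::floor(t_last / T) + 1;
  int nA = (mechanism == 0) ? 0 : 1;
  for (double s : base)
    for (int i = 0; i <= nT; ++i)
      for (int j = 0; j <= nA; ++j) {
        double t = s + i * T + j * (nA ? TA : 0.0);
        if (t < t_last - 1e-12) pts.push_back(t);
      }
  pts.push_back(0.0);
  pts.push_back(t_last);
  std::sort(pts.begin(), pts.end());
  std::vector<double> out;
  for (double t : pts) {
    if (t < 0.0) continue;
    if (out.empty() || t - out.back() > 1e-10) out.push_back(t);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List ls_core_simulate(NumericVector times_out, double t_last, double T,
                      double kin0, double w0, int eff_form, double p0,
                      double wth, double psi, double pwth, int mechanism,
                      int effect_form, double k2, double Emax, double EC50,
                      double TA, NumericMatrix pk_terms,
                      NumericVector dose_times, double hmax,
                      bool p_of_total) {
  Model mod;
  mod.T = T; mod.kin0 = kin0; mod.w0 = w0;
  mod.eff = Efficiency{eff_form, p0, wth, psi, pwth};
  mod.drug = DrugSpec{mechanism, effect_form, k2, Emax, EC50, TA};
  mod.p_of_total = p_of_total;
  for (int i = 0; i < pk_terms.nrow(); ++i) {
    mod.pk.td.push_back(pk_terms(i, 0));
    mod.pk.coef.push_back(pk_terms(i, 1));
    mod.pk.rate.push_back(pk_terms(i, 2));
    mod.pk.type.push_back((int)pk_terms(i, 3));
  }

  std::vector<double> doses(dose_times.begin(), dose_times.end());
  std::vector<double> bp =
      build_breakpoints(t_last, T, TA, mechanism, doses);

  double hcap = hmax;
  if (hcap > T) hcap = T;
  if (mechanism != 0 && hcap > TA) hcap = TA;

  History H;
  H.w0 = w0; H.kin0 = kin0;
  size_t approx = (size_t)(t_last / hcap) + 2 * bp.size() + 16;
  H.t.reserve(approx);

  double m = w0, a = 0.0, x = 0.0;
  double wscale = w0;

  for (size_t seg = 0; seg + 1 < bp.size(); ++seg) {
    double ta = bp[seg], tb = bp[seg + 1];
    int n = (int)std::ceil((tb - ta) / hcap);
    if (n < 1) n = 1;
    double h = (tb - ta) / n;
    // commit the right-side point at the segment start
    {
      double dm, da, dx, k, dk;
      mod.rhs(H, ta, m, a, x, dm, da, dx, 1);
      mod.kin_now(H, ta, m, a, dm, da, x, k, dk, 1);
      H.push(ta, m, dm, a, da, x, dx, k, dk);
    }
    for (int i = 0; i < n; ++i) {
      double t0 = ta + i * h;
      bool last = (i == n - 1);
      // the stage closing the segment evaluates the left limit of the
      // piece on (ta, tb]; every other stage uses right-side values
      int send = last ? -1 : 1;
      double k1m, k1a, k1x, k2m, k2a, k2x, k3m, k3a, k3x, k4m, k4a, k4x;
      mod.rhs(H, t0, m, a, x, k1m, k1a, k1x, 1);
      mod.rhs(H, t0 + h / 2, m + h / 2 * k1m, a + h / 2 * k1a,
              x + h / 2 * k1x, k2m, k2a, k2x, 1);
      mod.rhs(H, t0 + h / 2, m + h / 2 * k2m, a + h / 2 * k2a,
              x + h / 2 * k2x, k3m, k3a, k3x, 1);
      mod.rhs(H, t0 + h, m + h * k3m, a + h * k3a, x + h * k3x, k4m, k4a,
              k4x, send);
      m += h / 6 * (k1m + 2 * k2m + 2 * k3m + k4m);
      a += h / 6 * (k1a + 2 * k2a + 2 * k3a + k4a);
      x += h / 6 * (k1x + 2 * k2x + 2 * k3x + k4x);
      double t1 = (i == n - 1) ? tb : t0 + h;
      if (m + a > wscale) wscale = m + a;
      if (a < 0.0) {
        if (a < -1e-4 * wscale)
          stop("negative apoptotic mass A(t) = %g at t = %g (segment %d); "
               "integration step too coarse", a, t1, (int)seg + 1);
        // outflow bookkeeping round-off once the pool empties: floor at 0
        // within the solver tolerance checked above
        a = 0.0;
      }
      if (m < 0.0)
        stop("negative proliferating mass M(t) = %g at t = %g (segment %d)",
             m, t1, (int)seg + 1);
      double dm, da, dx, k, dk;
      mod.rhs(H, t1, m, a, x, dm, da, dx, send);
      mod.kin_now(H, t1, m, a, dm, da, x, k, dk, send);
      H.push(t1, m, dm, a, da, x, dx, k, dk);
    }
  }

  int nout = times_out.size();
  NumericVector Mo(nout), Ao(nout), Wo(nout), Ko(nout);
  for (int i = 0; i < nout; ++i) {
    double q = times_out[i];
    Mo[i] = H.getM(q, 1);
    Ao[i] = H.getA(q, 1);
    Wo[i] = Mo[i] + Ao[i];
    Ko[i] = H.getkin(q, 1);
  }
  return List::create(_["time"] = times_out, _["M"] = Mo, _["A"] = Ao,
                      _["w"] = Wo, _["kin"] = Ko,
                      _["n_segments"] = (int)bp.size() - 1,
                      _["n_points"] = (int)H.t.size());
}
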