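// Reduced-space evaluation of the collocation NLP for one condition:
// forward sweep of the trapezoidal defect recursion (closed-form implicit
// activation step, safeguarded Newton for the fiber length) and the
// adjoint sweep for the exact gradient. Mirrors the R reference
// implementation (.reduced_cond_eval_r); a parity test keeps them in step.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// curve constants; must match muscle_curve_constants() on the R side
static const double GAMMA_FL = 0.45;
static const double KPE = 5.0, EPS_M0 = 0.6;
static const double FTOE = 0.33, KTOE = 3.0, TOE_FRAC = 0.609;
static const double AF = 0.25, FLEN = 1.4, ECC_CLAMP = 0.95;
static const double LN_MIN = 0.05, LN_MAX = 1.8;

struct Muscle {
  double f_max, l_opt, sin_a, l_slack, eps0, v_max, tau_a, tau_d;
};

static inline double ft_norm(double eps, double eps0) {
  if (eps <= 0.0) return 0.0;
  const double eps_toe = TOE_FRAC * eps0;
  if (eps <= eps_toe)
    return FTOE / (std::exp(KTOE) - 1.0) *
           (std::exp(KTOE * eps / eps_toe) - 1.0);
  const double klin = (1.0 - FTOE) / (eps0 - eps_toe);
  return FTOE + klin * (eps - eps_toe);
}

static inline double cos_penn(double l, const Muscle& mu) {
  double h = mu.l_opt * mu.sin_a;
  double s = h / std::max(l, 1e-9);
  if (s > 0.9995) s = 0.9995;
  return std::sqrt(1.0 - s * s);
}

static inline double fl_active(double ln) {
  double d = ln - 1.0;
  return std::exp(-d * d / GAMMA_FL);
}

static inline double fl_passive(double ln) {
  if (ln <= 1.0) return 0.0;
  return (std::exp(KPE * (ln - 1.0) / EPS_M0) - 1.0) /
         (std::exp(KPE) - 1.0);
}

// tendon force, N, from normalized fiber length and muscle-tendon length
static inline double fiber_force(double lh, double lmt, const Muscle& mu) {
  double l = lh * mu.l_opt;
  double lt = lmt - l * cos_penn(l, mu);
  return mu.f_max * ft_norm(lt / mu.l_slack - 1.0, mu.eps0);
}

// normalized fiber velocity (optimal fiber lengths per second)
static inline double fv_norm(double a, double lh, double lmt,
                             const Muscle& mu) {
  double l = lh * mu.l_opt;
  double ln = lh < LN_MIN ? LN_MIN : (lh > LN_MAX ? LN_MAX : lh);
  double cosp = cos_penn(l, mu);
  double eps = (lmt - l * cosp) / mu.l_slack - 1.0;
  double fse = ft_norm(eps, mu.eps0) / cosp;
  double fl = fl_active(ln);
  double fpe = fl_passive(ln);
  double fact = fse - fpe; if (fact < 0.0) fact = 0.0;
  double afl = a * fl; if (afl < 1e-6) afl = 1e-6;
  double kap = (0.25 + 0.75 * a) * mu.v_max;
  if (fact <= afl) {
    double b = afl + fact / AF;
    return kap * (fact - afl) / b;
  }
  double cc = (2.0 + 2.0 / AF) / (FLEN - 1.0);
  double fcap = ECC_CLAMP * FLEN * afl;
  if (fact <= fcap) {
    double b = cc * (FLEN * afl - fact);
    return kap * (fact - afl) / b;
  }
  // linear extrapolation beyond the eccentric clamp, saturated at the
  // same magnitude as maximal shortening
  double b0 = cc * (FLEN * afl - fcap);
  double v0 = kap * (fcap - afl) / b0;
  double slope = kap * (b0 + cc * (fcap - afl)) / (b0 * b0);
  double v = v0 + slope * (fact - fcap);
  return v > kap ? kap : v;
}

static const double HFD = 1e-6;

// [[Rcpp::export(name = ".reduced_cond_eval_cpp")]]
List reduced_cond_eval_cpp(NumericMatrix u, NumericVector a1,
                           NumericVector l1, List par, NumericMatrix Lmt,
                           NumericMatrix Mstar, List Rj, double dt,
                           double K, double w, double hinge_w,
                           bool want_grad,
                           Nullable<NumericMatrix> A_in = R_NilValue,
                           Nullable<NumericMatrix> Lh_in = R_NilValue) {
  const int m = u.nrow(), P = u.ncol();
  const int nj = Mstar.nrow();
  NumericVector f_max = par["f_max"], l_opt = par["l_opt"],
                alpha = par["alpha_opt"], l_slack = par["l_slack"],
                eps0 = par["eps_t_max"], v_max = par["v_max"],
                tau_a = par["tau_act"], tau_d = par["tau_deact"];
  std::vector<Muscle> mus(m);
  for (int i = 0; i < m; ++i)
    mus[i] = Muscle{f_max[i], l_opt[i], std::sin(alpha[i]), l_slack[i],
                    eps0[i], v_max[i], tau_a[i], tau_d[i]};

  NumericMatrix A(m, P), Lh(m, P), taun(m, P - 1), beta(m, P - 1);
  // states computed in a previous value-only call at the same point can
  // be supplied to skip the Newton sweeps (the step bookkeeping taun and
  // beta is recomputed algebraically from the states)
  const bool have_states = A_in.isNotNull() && Lh_in.isNotNull();
  if (have_states) {
    A = clone(NumericMatrix(A_in.get()));
    Lh = clone(NumericMatrix(Lh_in.get()));
    for (int n = 0; n < P - 1; ++n)
      for (int i = 0; i < m; ++i) {
        const Muscle& mu = mus[i];
        double an = A(i, n), un = u(i, n), up = u(i, n + 1);
        double tn = (un > an) ? mu.tau_a : mu.tau_d;
        double C = an + dt / 2.0 * (un - an) / tn;
        taun(i, n) = tn;
        beta(i, n) = dt / (2.0 * ((up > C) ? mu.tau_a : mu.tau_d));
      }
  } else {
  for (int i = 0; i < m; ++i) { A(i, 0) = a1[i]; Lh(i, 0) = l1[i]; }

  // forward sweep
  for (int n = 0; n < P - 1; ++n) {
    for (int i = 0; i < m; ++i) {
      const Muscle& mu = mus[i];
      double an = A(i, n), un = u(i, n), up = u(i, n + 1);
      double tn = (un > an) ? mu.tau_a : mu.tau_d;
      double C = an + dt / 2.0 * (un - an) / tn;
      double tp = (up > C) ? mu.tau_a : mu.tau_d;
      double b = dt / (2.0 * tp);
      double ap = (C + b * up) / (1.0 + b);
      A(i, n + 1) = ap; taun(i, n) = tn; beta(i, n) = b;
      // safeguarded Newton for the implicit fiber-length step
      double fln = fv_norm(an, Lh(i, n), Lmt(i, n), mu);
      double lo = 0.02, hi = 3.5;
      double x = Lh(i, n) + dt * fln;
      if (x < lo) x = lo; if (x > hi) x = hi;
      bool ok = false;
      double df = 0.0;
      for (int it = 0; it < 120; ++it) {
        double g = x - Lh(i, n) -
          dt / 2.0 * (fln + fv_norm(ap, x, Lmt(i, n + 1), mu));
        if (std::fabs(g) < 1e-11 || hi - lo < 1e-13) { ok = true; break; }
        if (g < 0.0) { if (x > lo) lo = x; } else { if (x < hi) hi = x; }
        if (it % 2 == 1) {
          // forced bisection keeps the bracket shrinking where the
          // residual is near-vertical and Newton only creeps
          x = (lo + hi) / 2.0;
        } else {
          // chord iteration: the velocity slope is re-evaluated only
          // every third Newton step
          if (it % 6 == 0)
            df = (fv_norm(ap, x + HFD, Lmt(i, n + 1), mu) -
                  fv_norm(ap, x - HFD, Lmt(i, n + 1), mu)) / (2.0 * HFD);
          double xn = x - g / (1.0 - dt / 2.0 * df);
          if (!std::isfinite(xn) || xn <= lo || xn >= hi)
            xn = (lo + hi) / 2.0;
          x = xn;
        }
      }
      if (!ok && hi - lo > 1e-6)
        stop("fiber-length step did not converge at node %d "
             "(model-infeasible state)", n + 2);
      Lh(i, n + 1) = x;
    }
  }
  }

  // forces, moments, objective
  NumericMatrix Fm(m, P), dF_dl(m, P), M(nj, P), E(nj, P);
  for (int n = 0; n < P; ++n)
    for (int i = 0; i < m; ++i) {
      Fm(i, n) = fiber_force(Lh(i, n), Lmt(i, n), mus[i]);
      if (want_grad)
        dF_dl(i, n) = (fiber_force(Lh(i, n) + HFD, Lmt(i, n), mus[i]) -
                       fiber_force(Lh(i, n) - HFD, Lmt(i, n), mus[i])) /
                      (2.0 * HFD);
    }
  double val = 0.0;
  for (int j = 0; j < nj; ++j) {
    NumericMatrix R = Rj[j];
    for (int n = 0; n < P; ++n) {
      double s = 0.0;
      for (int i = 0; i < m; ++i) s += R(i, n) * Fm(i, n);
      M(j, n) = s;
      double e = s - Mstar(j, n);
      E(j, n) = e;
      val += w * e * e;
    }
  }
  for (int n = 0; n < P; ++n)
    for (int i = 0; i < m; ++i) {
      val += w * K * A(i, n) * A(i, n);
      double ui = u(i, n);
      double plo = 0.01 - ui > 0.0 ? 0.01 - ui : 0.0;
      double phi = ui - 1.0 > 0.0 ? ui - 1.0 : 0.0;
      val += hinge_w * (plo * plo + phi * phi);
    }

  if (!want_grad)
    return List::create(_["value"] = val, _["A"] = A, _["Lh"] = Lh,
                        _["M"] = M);

  // local partials of the contraction dynamics
  NumericMatrix DFL_da(m, P), DFL_dl(m, P), dJdl(m, P), dJdu(m, P);
  for (int n = 0; n < P; ++n)
    for (int i = 0; i < m; ++i) {
      const Muscle& mu = mus[i];
      DFL_da(i, n) = (fv_norm(A(i, n) + HFD, Lh(i, n), Lmt(i, n), mu) -
                      fv_norm(A(i, n) - HFD, Lh(i, n), Lmt(i, n), mu)) /
                     (2.0 * HFD);
      DFL_dl(i, n) = (fv_norm(A(i, n), Lh(i, n) + HFD, Lmt(i, n), mu) -
                      fv_norm(A(i, n), Lh(i, n) - HFD, Lmt(i, n), mu)) /
                     (2.0 * HFD);
      double ui = u(i, n);
      double plo = 0.01 - ui > 0.0 ? 0.01 - ui : 0.0;
      double phi = ui - 1.0 > 0.0 ? ui - 1.0 : 0.0;
      dJdu(i, n) = hinge_w * 2.0 * (phi - plo);
      double t = 0.0;
      for (int j = 0; j < nj; ++j) {
        NumericMatrix R = Rj[j];
        t += R(i, n) * E(j, n);
      }
      dJdl(i, n) = w * 2.0 * t * dF_dl(i, n);
    }

  // adjoint sweep
  NumericMatrix GU = clone(dJdu);
  NumericVector g_a1(m), g_l1(m);
  for (int i = 0; i < m; ++i) {
    double pa = w * K * 2.0 * A(i, P - 1);
    double pl = dJdl(i, P - 1);
    double Dlast = 1.0 - dt / 2.0 * DFL_dl(i, P - 1);
    double q = pa + (dt / 2.0 * DFL_da(i, P - 1) / Dlast) * pl;
    GU(i, P - 1) += (beta(i, P - 2) / (1.0 + beta(i, P - 2))) * q;
    for (int n = P - 2; n >= 0; --n) {
      double Dk = 1.0 - dt / 2.0 * DFL_dl(i, n + 1);
      double dA_dan = (1.0 - dt / (2.0 * taun(i, n))) / (1.0 + beta(i, n));
      double dA_dun = (dt / (2.0 * taun(i, n))) / (1.0 + beta(i, n));
      double dL_dan = (dt / 2.0 * DFL_da(i, n)) / Dk;
      double dL_dln = (1.0 + dt / 2.0 * DFL_dl(i, n)) / Dk;
      double pa_n = w * K * 2.0 * A(i, n) + dA_dan * q + dL_dan * pl;
      double pl_n = dJdl(i, n) + dL_dln * pl;
      GU(i, n) += dA_dun * q;
      if (n > 0) {
        double Dprev = 1.0 - dt / 2.0 * DFL_dl(i, n);
        q = pa_n + (dt / 2.0 * DFL_da(i, n) / Dprev) * pl_n;
        GU(i, n) += (beta(i, n - 1) / (1.0 + beta(i, n - 1))) * q;
      }
      pa = pa_n; pl = pl_n;
    }
    g_a1[i] = pa; g_l1[i] = pl;
  }
  return List::create(_["value"] = val, _["GU"] = GU, _["g_a1"] = g_a1,
                      _["g_l1"] = g_l1, _["A"] = A, _["Lh"] = Lh,
                      _["M"] = M);
}
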