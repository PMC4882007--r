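#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout shared with R/params.R (keep in sync):
// 0 rho_fm, 1 rho_ffm, 2 eta_fm, 3 eta_ffm, 4 beta, 5 gamma_fm,
// 6 gamma_ffm, 7 lam, 8 K, 9 alpha, 10 I0
// Drug vector layout: 0 d0, 1 dmax, 2 ed50, 3 t_start, 4 t_end

namespace {

struct Pars {
  double rho_fm, rho_ffm, eta_fm, eta_ffm, beta, gfm, gffm, lam, K, alpha, I0;
};

Pars unpack(const NumericVector& p) {
  Pars q;
  q.rho_fm = p[0]; q.rho_ffm = p[1]; q.eta_fm = p[2]; q.eta_ffm = p[3];
  q.beta = p[4]; q.gfm = p[5]; q.gffm = p[6]; q.lam = p[7];
  q.K = p[8]; q.alpha = p[9]; q.I0 = p[10];
  return q;
}

// Hill drug effect; window test done on the dosing day so the effect is
// piecewise-constant over integration days (daily oral dosing).
double drug_on_day(double day, double dose, const NumericVector& drug) {
  if (drug.size() == 0) return 0.0;
  if (day >= drug[3] && day < drug[4])
    return drug[0] + drug[1] * dose / (drug[2] + dose);
  return 0.0;
}

// Closed-form resolution of the implicit EE equation for the 2D model:
// E = (E0 + c I) / (1 + c), c = (eta_fm + alpha eta_ffm)/(rho_fm + alpha rho_ffm)
double ee2d(double fm, double ffm, double I, const Pars& q, double alpha, double d) {
  double e0 = q.K + q.beta * (I - q.I0) + q.lam * (fm + ffm) +
              q.gfm * fm + q.gffm * ffm + d;
  double c = (q.eta_fm + alpha * q.eta_ffm) / (q.rho_fm + alpha * q.rho_ffm);
  return (e0 + c * I) / (1.0 + c);
}

// dFM/dt for the 2D partition model; dFFM/dt = alpha * dFM/dt
double rhs2d(double fm, double ffm, double I, const Pars& q, double alpha,
             double d, double* imb) {
  double E = ee2d(fm, ffm, I, q, alpha, d);
  *imb = I - E;
  return (I - E) / (q.rho_fm + alpha * q.rho_ffm);
}

// Piecewise-cubic evaluation (knots x, per-interval coefs a+b s+c s^2+d s^3),
// linear extrapolation outside the knot range.
void pp_eval(double t, const NumericVector& x, const NumericMatrix& cf,
             double* val, double* der) {
  int m = x.size();
  if (t <= x[0]) {
    double s = t - x[0];
    *val = cf(0, 0) + cf(0, 1) * s;
    *der = cf(0, 1);
    return;
  }
  if (t >= x[m - 1]) {
    int i = m - 2;
    double h = x[m - 1] - x[i];
    double vr = cf(i, 0) + h * (cf(i, 1) + h * (cf(i, 2) + h * cf(i, 3)));
    double dr = cf(i, 1) + h * (2.0 * cf(i, 2) + 3.0 * h * cf(i, 3));
    *val = vr + dr * (t - x[m - 1]);
    *der = dr;
    return;
  }
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (x[mid] <= t) lo = mid; else hi = mid;
  }
  double s = t - x[lo];
  *val = cf(lo, 0) + s * (cf(lo, 1) + s * (cf(lo, 2) + s * cf(lo, 3)));
  *der = cf(lo, 1) + s * (2.0 * cf(lo, 2) + 3.0 * s * cf(lo, 3));
}

} // namespace

// [[Rcpp::export]]
List sim2d_cpp(double fm0, double ffm0, double t0, double t_end,
               NumericVector intake, double day_first,
               NumericVector params, NumericVector drug, double dose,
               int steps_per_day, NumericVector alpha_half) {
  Pars q = unpack(params);
  int n_days = (int)std::lround(t_end - t0);
  int n_out = n_days * steps_per_day + 1;
  double h = 1.0 / steps_per_day;
  bool varying = alpha_half.size() > 0;

  NumericMatrix out(n_out, 7); // t fm ffm bw ee intake cumimb
  bool clipped = false;
  double fm = fm0, ffm = ffm0, cum = 0.0;

  // alpha at RK4 stage time t (stages live on the half-step grid)
  auto alpha_at = [&](double t) -> double {
    if (!varying) return q.alpha;
    int k = (int)std::lround((t - t0) / (h / 2.0));
    if (k < 0) k = 0;
    if (k >= alpha_half.size()) k = alpha_half.size() - 1;
    return alpha_half[k];
  };

  int row = 0;
  for (int dday = 0; dday <= n_days; dday++) {
    double day_t = t0 + dday;
    int idx = (int)std::lround(day_t - day_first);
    // EE at a day's start uses that day's intake; the final output row keeps
    // the previous day's (left-limit) intake since no further day is defined.
    int idx_ee = (dday == n_days) ? idx - 1 : idx;
    if (idx_ee < 0 || idx_ee >= intake.size())
      stop("intake schedule does not cover day %g", day_t);
    double I_ee = intake[idx_ee];
    double d_ee = drug_on_day((dday == n_days) ? day_t - 1 : day_t, dose, drug);
    double a_ee = alpha_at(day_t);
    out(row, 0) = day_t;
    out(row, 1) = fm;
    out(row, 2) = ffm;
    out(row, 3) = fm + ffm;
    out(row, 4) = ee2d(fm, ffm, I_ee, q, a_ee, d_ee);
    out(row, 5) = I_ee;
    out(row, 6) = cum;
    row++;
    if (dday == n_days) break;

    double I = intake[idx];
    double d = drug_on_day(day_t, dose, drug);
    for (int s = 0; s < steps_per_day; s++) {
      double t = day_t + s * h;
      double g1, g2, g3, g4;
      double a1 = alpha_at(t), a2 = alpha_at(t + h / 2.0), a4 = alpha_at(t + h);
      double k1 = rhs2d(fm, ffm, I, q, a1, d, &g1);
      double k2 = rhs2d(fm + h / 2.0 * k1, ffm + h / 2.0 * a1 * k1, I, q, a2, d, &g2);
      double k3 = rhs2d(fm + h / 2.0 * k2, ffm + h / 2.0 * a2 * k2, I, q, a2, d, &g3);
      double k4 = rhs2d(fm + h * k3, ffm + h * a2 * k3, I, q, a4, d, &g4);
      double dfm = h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      // FFM uses the same stage slopes scaled by the stage alphas so that the
      // constant-alpha case stays on the partition line to rounding error.
      double dffm = h / 6.0 * (a1 * k1 + 2.0 * a2 * k2 + 2.0 * a2 * k3 + a4 * k4);
      cum += h / 6.0 * (g1 + 2.0 * g2 + 2.0 * g3 + g4);
      fm += dfm;
      ffm += dffm;
      if (fm < 0.0) { fm = 0.0; clipped = true; }
      if (s < steps_per_day - 1) {
        out(row, 0) = t + h;
        out(row, 1) = fm;
        out(row, 2) = ffm;
        out(row, 3) = fm + ffm;
        out(row, 4) = ee2d(fm, ffm, I, q, alpha_at(t + h), d);
        out(row, 5) = I;
        out(row, 6) = cum;
        row++;
      }
    }
  }
  return List::create(_["traj"] = out, _["clipped"] = clipped);
}

// alpha-free model: FM' = (I - E - rho_ffm B')/(rho_fm - rho_ffm) with
// E = (E0 + eta_ffm B' + c'(I - rho_ffm B'))/(1 + c'),
// c' = (eta_fm - eta_ffm)/(rho_fm - rho_ffm), FFM = S_BW(t) - FM.
// [[Rcpp::export]]
List simaf_cpp(double fm0, double t0, double t_end,
               NumericVector intake, double day_first,
               NumericVector params, NumericVector drug, double dose,
               int steps_per_day, NumericVector knots, NumericMatrix coefs) {
  Pars q = unpack(params);
  if (q.rho_fm == q.rho_ffm) stop("rho_fm must differ from rho_ffm");
  double denom_rho = q.rho_fm - q.rho_ffm;
  double cp = (q.eta_fm - q.eta_ffm) / denom_rho;
  int n_days = (int)std::lround(t_end - t0);
  int n_out = n_days * steps_per_day + 1;
  double h = 1.0 / steps_per_day;

  NumericMatrix out(n_out, 8); // t fm ffm bw ee intake cumimb dffm_dfm
  double fm = fm0, cum = 0.0;
  double viol_t = NA_REAL;

  auto rhs = [&](double fm_, double t, double I, double d,
                 double* E_out, double* bw, double* bp) -> double {
    double S, Sp;
    pp_eval(t, knots, coefs, &S, &Sp);
    double ffm = S - fm_;
    double e0 = q.K + q.beta * (I - q.I0) + q.lam * S + q.gfm * fm_ +
                q.gffm * ffm + d;
    double E = (e0 + q.eta_ffm * Sp + cp * (I - q.rho_ffm * Sp)) / (1.0 + cp);
    *E_out = E;
    *bw = S;
    *bp = Sp;
    return (I - E - q.rho_ffm * Sp) / denom_rho;
  };

  int row = 0;
  for (int dday = 0; dday <= n_days; dday++) {
    double day_t = t0 + dday;
    int idx = (int)std::lround(day_t - day_first);
    int idx_ee = (dday == n_days) ? idx - 1 : idx;
    if (idx_ee < 0 || idx_ee >= intake.size())
      stop("intake schedule does not cover day %g", day_t);
    double I_ee = intake[idx_ee];
    double d_ee = drug_on_day((dday == n_days) ? day_t - 1 : day_t, dose, drug);
    double E, bw, bp;
    double fmp = rhs(fm, day_t, I_ee, d_ee, &E, &bw, &bp);
    out(row, 0) = day_t;
    out(row, 1) = fm;
    out(row, 2) = bw - fm;
    out(row, 3) = bw;
    out(row, 4) = E;
    out(row, 5) = I_ee;
    out(row, 6) = cum;
    double dnum = I_ee - E - q.rho_fm * bp;
    double dden = I_ee - E - q.rho_ffm * bp;
    out(row, 7) = (std::abs(dden) < 1e-8) ? NA_REAL : -dnum / dden;
    row++;
    if (dday == n_days) break;

    double I = intake[idx];
    double d = drug_on_day(day_t, dose, drug);
    for (int s = 0; s < steps_per_day; s++) {
      double t = day_t + s * h;
      double E1, E2, E3, E4, bw_, bp_;
      double k1 = rhs(fm, t, I, d, &E1, &bw_, &bp_);
      double g1 = I - E1;
      double k2 = rhs(fm + h / 2.0 * k1, t + h / 2.0, I, d, &E2, &bw_, &bp_);
      double g2 = I - E2;
      double k3 = rhs(fm + h / 2.0 * k2, t + h / 2.0, I, d, &E3, &bw_, &bp_);
      double g3 = I - E3;
      double k4 = rhs(fm + h * k3, t + h, I, d, &E4, &bw_, &bp_);
      double g4 = I - E4;
      fm += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      cum += h / 6.0 * (g1 + 2.0 * g2 + 2.0 * g3 + g4);
      double S, Sp;
      pp_eval(t + h, knots, coefs, &S, &Sp);
      if ((fm < 0.0 || fm > S) && !R_finite(viol_t)) viol_t = t + h;
      if (s < steps_per_day - 1) {
        double E, bw2, bp2;
        rhs(fm, t + h, I, d, &E, &bw2, &bp2);
        out(row, 0) = t + h;
        out(row, 1) = fm;
        out(row, 2) = bw2 - fm;
        out(row, 3) = bw2;
        out(row, 4) = E;
        out(row, 5) = I;
        out(row, 6) = cum;
        double dnum = I - E - q.rho_fm * bp2;
        double dden = I - E - q.rho_ffm * bp2;
        out(row, 7) = (std::abs(dden) < 1e-8) ? NA_REAL : -dnum / dden;
        row++;
      }
    }
  }
  return List::create(_["traj"] = out, _["violation_t"] = viol_t);
}

// [[Rcpp::export]]
NumericMatrix pp_eval_cpp(NumericVector t, NumericVector knots, NumericMatrix coefs) {
  NumericMatrix res(t.size(), 2);
  for (int i = 0; i < t.size(); i++) {
    double v, d;
    pp_eval(t[i], knots, coefs, &v, &d);
    res(i, 0) = v;
    res(i, 1) = d;
  }
  return res;
}
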