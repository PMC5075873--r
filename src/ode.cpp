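#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Compact reaction system used by the integrator.  Built once per simulate()
// call from the R-side model (see .compile_reactions in R/ode_engine.R):
// every reaction contributes vmax * prod_i S_i/(Km_i + S_i), optionally
// damped by a non-competitive inhibition factor Ki/(Ki + I).
struct ReactionSystem {
  int n_species;
  int n_reactions;
  // flattened per-reaction substrate lists
  std::vector<int> sub_off, sub_len;
  std::vector<int> sub_idx;      // 0-based species index
  std::vector<double> sub_coef;
  std::vector<double> sub_km;
  std::vector<int> prod_off, prod_len;
  std::vector<int> prod_idx;
  std::vector<double> prod_coef;
  std::vector<double> vmax;
  std::vector<int> inh_idx;      // -1 if none
  std::vector<double> inh_ki;
};

static ReactionSystem build_system(const List& sys) {
  ReactionSystem rs;
  rs.n_species = as<int>(sys["n_species"]);
  IntegerVector sub_off = sys["sub_off"], sub_len = sys["sub_len"],
                sub_idx = sys["sub_idx"], prod_off = sys["prod_off"],
                prod_len = sys["prod_len"], prod_idx = sys["prod_idx"],
                inh_idx = sys["inh_idx"];
  NumericVector sub_coef = sys["sub_coef"], sub_km = sys["sub_km"],
                prod_coef = sys["prod_coef"], vmax = sys["vmax"],
                inh_ki = sys["inh_ki"];
  rs.n_reactions = vmax.size();
  rs.sub_off.assign(sub_off.begin(), sub_off.end());
  rs.sub_len.assign(sub_len.begin(), sub_len.end());
  rs.sub_idx.assign(sub_idx.begin(), sub_idx.end());
  rs.sub_coef.assign(sub_coef.begin(), sub_coef.end());
  rs.sub_km.assign(sub_km.begin(), sub_km.end());
  rs.prod_off.assign(prod_off.begin(), prod_off.end());
  rs.prod_len.assign(prod_len.begin(), prod_len.end());
  rs.prod_idx.assign(prod_idx.begin(), prod_idx.end());
  rs.prod_coef.assign(prod_coef.begin(), prod_coef.end());
  rs.vmax.assign(vmax.begin(), vmax.end());
  rs.inh_idx.assign(inh_idx.begin(), inh_idx.end());
  rs.inh_ki.assign(inh_ki.begin(), inh_ki.end());
  return rs;
}

// dx/dt = S . v(x); negative concentrations are treated as 0 inside the
// rate law so that round-off undershoot cannot produce spurious fluxes.
static void deriv(const ReactionSystem& rs, const std::vector<double>& x,
                  std::vector<double>& dx) {
  std::fill(dx.begin(), dx.end(), 0.0);
  for (int r = 0; r < rs.n_reactions; ++r) {
    double rate = rs.vmax[r];
    if (rate <= 0.0) continue;
    const int off = rs.sub_off[r], len = rs.sub_len[r];
    for (int k = 0; k < len; ++k) {
      const double s = std::max(x[rs.sub_idx[off + k]], 0.0);
      rate *= s / (rs.sub_km[off + k] + s);
    }
    if (rs.inh_idx[r] >= 0) {
      const double inh = std::max(x[rs.inh_idx[r]], 0.0);
      rate *= rs.inh_ki[r] / (rs.inh_ki[r] + inh);
    }
    if (rate == 0.0) continue;
    for (int k = 0; k < len; ++k)
      dx[rs.sub_idx[off + k]] -= rs.sub_coef[off + k] * rate;
    const int poff = rs.prod_off[r], plen = rs.prod_len[r];
    for (int k = 0; k < plen; ++k)
      dx[rs.prod_idx[poff + k]] += rs.prod_coef[poff + k] * rate;
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate from t0 to t1, overwriting x.  Returns false on step-size
// underflow (reported to R as an integrator failure).
static bool integrate_span(const ReactionSystem& rs, std::vector<double>& x,
                           double t0, double t1, double rtol, double atol,
                           long& n_steps, long max_steps) {
  const int n = rs.n_species;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      xtmp(n), xnew(n);
  double t = t0;
  double h = (t1 - t0) / 100.0;
  const double hmin = (t1 - t0) * 1e-14;
  deriv(rs, x, k1);
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    if (h < hmin) return false;
    for (int i = 0; i < n; ++i) xtmp[i] = x[i] + h * a21 * k1[i];
    deriv(rs, xtmp, k2);
    for (int i = 0; i < n; ++i)
      xtmp[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    deriv(rs, xtmp, k3);
    for (int i = 0; i < n; ++i)
      xtmp[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(rs, xtmp, k4);
    for (int i = 0; i < n; ++i)
      xtmp[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    deriv(rs, xtmp, k5);
    for (int i = 0; i < n; ++i)
      xtmp[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    deriv(rs, xtmp, k6);
    for (int i = 0; i < n; ++i)
      xnew[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    deriv(rs, xnew, k7);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(x[i]), std::fabs(xnew[i]));
      const double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (err <= 1.0) {
      t += h;
      x = xnew;
      k1 = k7;  // FSAL
      if (++n_steps > max_steps) return false;
    }
    double fac = 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
  }
  return true;
}

// [[Rcpp::export(name = ".ode_solve_cpp")]]
NumericMatrix ode_solve_cpp(List sys, NumericVector x0, NumericVector times,
                            double rtol, double atol, double neg_tol,
                            double max_steps) {
  ReactionSystem rs = build_system(sys);
  const int n = rs.n_species, nt = times.size();
  if ((int)x0.size() != n) stop("initial state length mismatch");
  NumericMatrix out(nt, n);
  std::vector<double> x(x0.begin(), x0.end());
  long n_steps = 0;
  const long max_st = (long)max_steps;
  for (int j = 0; j < nt; ++j) {
    if (j > 0) {
      if (!integrate_span(rs, x, times[j - 1], times[j], rtol, atol, n_steps,
                          max_st))
        stop("integrator failure between t=%g and t=%g (after %ld steps)",
             times[j - 1], times[j], n_steps);
    }
    for (int i = 0; i < n; ++i) {
      double v = x[i];
      if (v < 0.0) {
        if (v < -neg_tol)
          stop("negative amount %g for species %d at t=%g exceeds tolerance",
               v, i + 1, times[j]);
        v = 0.0;
        x[i] = 0.0;
      }
      out(j, i) = v;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward sensitivity integration: augments the state with S = dx/dVmax
// (n_species x n_reactions, column-major) and integrates the variational
// equations alongside the state.  Rates are linear in Vmax, so
// d(dx/dt)/dVmax_k = stoich_k * phi_k(x) with phi_k the saturation product,
// and dS/dt = J_x S + dF/dV.  Exact (to solver tolerance) Jacobians of the
// calibration residuals come from these sensitivities; finite differences
// are too noisy for the weakly constrained directions.
// ---------------------------------------------------------------------------

struct SensWork {
  std::vector<double> phi;       // per-reaction saturation product
  std::vector<double> dphi;      // per-reaction, per-substrate-slot dphi/dx
  std::vector<double> inh_fac;
};

// phi_r and its partial derivatives w.r.t. each substrate (and inhibitor)
static void rate_factors(const ReactionSystem& rs,
                         const std::vector<double>& x, SensWork& w) {
  const int nr = rs.n_reactions;
  w.phi.assign(nr, 1.0);
  w.dphi.assign(rs.sub_idx.size(), 0.0);
  w.inh_fac.assign(nr, 1.0);
  for (int r = 0; r < nr; ++r) {
    const int off = rs.sub_off[r], len = rs.sub_len[r];
    double prod = 1.0;
    for (int k = 0; k < len; ++k) {
      const double s = std::max(x[rs.sub_idx[off + k]], 0.0);
      prod *= s / (rs.sub_km[off + k] + s);
    }
    double inh = 1.0, dinh = 0.0;
    if (rs.inh_idx[r] >= 0) {
      const double I = std::max(x[rs.inh_idx[r]], 0.0);
      inh = rs.inh_ki[r] / (rs.inh_ki[r] + I);
      dinh = -inh / (rs.inh_ki[r] + I);
    }
    w.inh_fac[r] = inh * (dinh == 0.0 ? 1.0 : 1.0);  // factor applied below
    w.phi[r] = prod * inh;
    for (int k = 0; k < len; ++k) {
      const double s = std::max(x[rs.sub_idx[off + k]], 0.0);
      const double km = rs.sub_km[off + k];
      const double sat = s / (km + s);
      // product of the other saturation factors
      double rest = inh;
      for (int j = 0; j < len; ++j) {
        if (j == k) continue;
        const double sj = std::max(x[rs.sub_idx[off + j]], 0.0);
        rest *= sj / (rs.sub_km[off + j] + sj);
      }
      const double dsat = km / ((km + s) * (km + s));
      w.dphi[off + k] = rest * dsat * (x[rs.sub_idx[off + k]] >= 0.0 ? 1.0 : 0.0);
      (void)sat;
    }
  }
}

// augmented derivative: z = [x, S(:)]
static void deriv_aug(const ReactionSystem& rs, const std::vector<double>& z,
                      std::vector<double>& dz, SensWork& w) {
  const int n = rs.n_species, p = rs.n_reactions;
  std::vector<double> x(z.begin(), z.begin() + n);
  rate_factors(rs, x, w);
  std::fill(dz.begin(), dz.end(), 0.0);
  // state part
  for (int r = 0; r < p; ++r) {
    const double rate = rs.vmax[r] * w.phi[r];
    if (rate != 0.0) {
      const int off = rs.sub_off[r], len = rs.sub_len[r];
      for (int k = 0; k < len; ++k)
        dz[rs.sub_idx[off + k]] -= rs.sub_coef[off + k] * rate;
      const int poff = rs.prod_off[r], plen = rs.prod_len[r];
      for (int k = 0; k < plen; ++k)
        dz[rs.prod_idx[poff + k]] += rs.prod_coef[poff + k] * rate;
    }
  }
  // sensitivity part: for each parameter column q
  for (int q = 0; q < p; ++q) {
    const double* S = &z[n + (size_t)q * n];
    double* dS = &dz[n + (size_t)q * n];
    for (int r = 0; r < p; ++r) {
      // chain rule through every substrate of reaction r
      double drate = 0.0;
      const int off = rs.sub_off[r], len = rs.sub_len[r];
      for (int k = 0; k < len; ++k)
        drate += rs.vmax[r] * w.dphi[off + k] * S[rs.sub_idx[off + k]];
      // inhibitor dependence
      if (rs.inh_idx[r] >= 0) {
        const double I = std::max(x[rs.inh_idx[r]], 0.0);
        const double g = rs.inh_ki[r] / (rs.inh_ki[r] + I);
        double prod = 1.0;
        for (int k = 0; k < len; ++k) {
          const double s = std::max(x[rs.sub_idx[off + k]], 0.0);
          prod *= s / (rs.sub_km[off + k] + s);
        }
        drate += rs.vmax[r] * prod * (-g / (rs.inh_ki[r] + I)) *
                 S[rs.inh_idx[r]];
      }
      if (r == q) drate += w.phi[r];  // d rate_r / d Vmax_r
      if (drate != 0.0) {
        for (int k = 0; k < len; ++k)
          dS[rs.sub_idx[off + k]] -= rs.sub_coef[off + k] * drate;
        const int poff = rs.prod_off[r], plen = rs.prod_len[r];
        for (int k = 0; k < plen; ++k)
          dS[rs.prod_idx[poff + k]] += rs.prod_coef[poff + k] * drate;
      }
    }
  }
}

// [[Rcpp::export(name = ".ode_solve_sens_cpp")]]
List ode_solve_sens_cpp(List sys, NumericVector x0, NumericVector times,
                        double rtol, double atol, double atol_sens,
                        double max_steps) {
  ReactionSystem rs = build_system(sys);
  const int n = rs.n_species, p = rs.n_reactions, nt = times.size();
  const int m = n * (1 + p);
  std::vector<double> z(m, 0.0);
  for (int i = 0; i < n; ++i) z[i] = x0[i];
  NumericMatrix amounts(nt, n);
  NumericVector sens(Dimension(nt, n, p));
  SensWork w;
  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m),
      ztmp(m), znew(m);
  long n_steps = 0;
  const long max_st = (long)max_steps;
  auto store = [&](int j) {
    for (int i = 0; i < n; ++i) amounts(j, i) = z[i];
    for (int q = 0; q < p; ++q)
      for (int i = 0; i < n; ++i)
        sens[j + nt * (i + (size_t)n * q)] = z[n + (size_t)q * n + i];
  };
  store(0);
  deriv_aug(rs, z, k1, w);
  for (int j = 1; j < nt; ++j) {
    double t = times[j - 1];
    const double t1 = times[j];
    double h = (t1 - t) / 100.0;
    const double hmin = (t1 - t) * 1e-14;
    while (t < t1) {
      if (h > t1 - t) h = t1 - t;
      if (h < hmin || ++n_steps > max_st)
        stop("sensitivity integrator failure near t=%g", t);
      for (int i = 0; i < m; ++i) ztmp[i] = z[i] + h * a21 * k1[i];
      deriv_aug(rs, ztmp, k2, w);
      for (int i = 0; i < m; ++i)
        ztmp[i] = z[i] + h * (a31 * k1[i] + a32 * k2[i]);
      deriv_aug(rs, ztmp, k3, w);
      for (int i = 0; i < m; ++i)
        ztmp[i] = z[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      deriv_aug(rs, ztmp, k4, w);
      for (int i = 0; i < m; ++i)
        ztmp[i] = z[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
      deriv_aug(rs, ztmp, k5, w);
      for (int i = 0; i < m; ++i)
        ztmp[i] = z[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      deriv_aug(rs, ztmp, k6, w);
      for (int i = 0; i < m; ++i)
        znew[i] = z[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      deriv_aug(rs, znew, k7, w);
      double err = 0.0;
      for (int i = 0; i < m; ++i) {
        const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double a0 = (i < n) ? atol : atol_sens;
        const double sc =
            a0 + rtol * std::max(std::fabs(z[i]), std::fabs(znew[i]));
        const double rr = ei / sc;
        err += rr * rr;
      }
      err = std::sqrt(err / m);
      if (err <= 1.0) {
        t += h;
        z = znew;
        k1 = k7;
      }
      double fac = 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    store(j);
  }
  return List::create(_["amounts"] = amounts, _["sens"] = sens);
}

// [[Rcpp::export(name = ".reaction_rates_cpp")]]
NumericVector reaction_rates_cpp(List sys, NumericVector x0) {
  ReactionSystem rs = build_system(sys);
  std::vector<double> x(x0.begin(), x0.end());
  NumericVector out(rs.n_reactions);
  for (int r = 0; r < rs.n_reactions; ++r) {
    double rate = rs.vmax[r];
    const int off = rs.sub_off[r], len = rs.sub_len[r];
    for (int k = 0; k < len; ++k) {
      const double s = std::max(x[rs.sub_idx[off + k]], 0.0);
      rate *= s / (rs.sub_km[off + k] + s);
    }
    if (rs.inh_idx[r] >= 0) {
      const double inh = std::max(x[rs.inh_idx[r]], 0.0);
      rate *= rs.inh_ki[r] / (rs.inh_ki[r] + inh);
    }
    out[r] = rate;
  }
  return out;
}
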