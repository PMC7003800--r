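// C++ twin of R/kinetics.R derivatives() plus an adaptive L-stable
// Rosenbrock(2,3) integrator (Shampine's ode23s scheme).  The R function is
// the readable reference; this file is the fast path used by simulate_run().
// State and parameter packing order is fixed and shared with R/simulator.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NS = 15; // state dimension

// state indices
enum {
  iQA = 0, iPQ, iP700, iPH, iPSI_, iION, iS23, iPSBS, iZX,
  iCLEF, iCO2, iCPSII, iCREC, iCB6F, iCATP
};

// parameter indices (see .pack_params in R/simulator.R)
enum {
  pANT = 0, pKQAPQ, pNPQE, pKB6F, pNHILL, pPKAREG, pKR, pDESTAB, pFDIST,
  pPHI, pGATP, pCMEM, pBETA, pGION, pPSIEQ, pPKAPSBS, pNPSBS, pKPSBS,
  pPKAVDE, pNVDE, pKVDE, pKEP, pQEMAX, pS23T, pKSDEC, pSTRPH, pZ, pPMFEQ,
  pRECCAP
};

static const char *flux_names[7] = {
  "v_psii", "v_qa_pq", "v_b6f", "v_psi", "v_rec", "v_atp_h", "v_ion"
};

static double light_at(const arma::vec &light, double t) {
  int kind = (int)light[0];
  if (kind == 0) return light[1];
  if (kind == 1) { // sinusoidal: mean, amplitude, period
    return light[1] + light[2] * std::sin(2.0 * M_PI * t / light[3] - M_PI / 2.0);
  }
  // square wave: low, high, period, duty_fraction (right-continuous)
  // (floor-based modulo: fmod carries a too-new glibc symbol version on
  // conda toolchains)
  double period = light[3], duty = light[4];
  double phase = t - period * std::floor(t / period);
  if (phase < 0) phase += period;
  if (phase >= period) phase = 0;
  double low_len = (1.0 - duty) * period;
  return (phase < low_len) ? light[1] : light[2];
}

static double hillprot(double ph, double pka, double n) {
  return 1.0 / (1.0 + std::pow(10.0, n * (ph - pka)));
}

// seg_end clamps the light-evaluation time so that a step ending exactly on
// a square-wave transition sees the pre-transition intensity.
static void rhs(double t, const arma::vec &y, const arma::vec &par,
                const arma::vec &light, double seg_end, arma::vec &dy,
                bool check) {
  double te = (t > seg_end - 1e-9) ? seg_end - 1e-9 : t;
  if (te < 0) te = 0;
  double intensity = light_at(light, te);

  double qe = y[iPSBS] * y[iZX];
  double v_psii = par[pANT] * intensity * (1.0 - par[pQEMAX] * qe) * (1.0 - y[iQA]);
  double v_qa_pq = par[pKQAPQ] * y[iQA] * (1.0 - y[iPQ]);
  double kb6f = par[pKB6F] / (1.0 + std::pow(10.0, par[pNHILL] * (par[pPKAREG] - y[iPH])));
  double v_b6f = kb6f * y[iPQ] * y[iP700];
  double v_psi = par[pANT] * intensity * (1.0 - y[iP700]);
  double rec_ex = (par[pFDIST] * y[iPSI_] - par[pDESTAB]) / 0.06;
  if (rec_ex > par[pRECCAP]) rec_ex = par[pRECCAP];
  double v_rec = y[iQA] * y[iS23] * par[pKR] * std::pow(10.0, rec_ex);
  double pmf = y[iPSI_] + par[pZ] * (par[pSTRPH] - y[iPH]);
  double v_atp_h = par[pGATP] * (pmf - par[pPMFEQ]);
  double v_ion = par[pGION] * (y[iPSI_] - par[pPSIEQ]);

  if (check) {
    double fl[7] = {v_psii, v_qa_pq, v_b6f, v_psi, v_rec, v_atp_h, v_ion};
    for (int i = 0; i < 7; ++i) {
      if (!std::isfinite(fl[i])) {
        stop("non-finite flux term(s) at t = %f: %s", t, flux_names[i]);
      }
    }
  }

  dy[iQA] = v_psii - v_qa_pq - v_rec;
  dy[iPQ] = (v_qa_pq - v_b6f) / par[pNPQE];
  dy[iP700] = v_psi - v_b6f;
  dy[iPH] = -(v_psii + 2.0 * v_b6f - v_atp_h) / par[pBETA];
  dy[iPSI_] = par[pCMEM] * (v_psii + v_b6f + v_psi - v_rec - v_atp_h - v_ion);
  dy[iION] = v_ion;
  dy[iS23] = v_psii * (par[pS23T] - y[iS23]) - par[pKSDEC] * y[iS23] - v_rec;
  dy[iPSBS] = par[pKPSBS] * (hillprot(y[iPH], par[pPKAPSBS], par[pNPSBS]) - y[iPSBS]);
  double vde_act = hillprot(y[iPH], par[pPKAVDE], par[pNVDE]);
  dy[iZX] = par[pKVDE] * vde_act * (1.0 - y[iZX]) - par[pKEP] * y[iZX];
  dy[iCLEF] = v_psi;
  dy[iCO2] = par[pPHI] * v_rec;
  dy[iCPSII] = v_psii;
  dy[iCREC] = v_rec;
  dy[iCB6F] = v_b6f;
  dy[iCATP] = v_atp_h;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(double t, NumericVector y, NumericVector par,
                      NumericVector light) {
  arma::vec yv(y.begin(), NS), pv(par.begin(), par.size());
  arma::vec lv(light.begin(), light.size()), dy(NS);
  rhs(t, yv, pv, lv, R_PosInf, dy, true);
  return NumericVector(dy.begin(), dy.end());
}

static void num_jac(double t, const arma::vec &y, const arma::vec &par,
                    const arma::vec &light, double seg_end,
                    const arma::vec &f0, arma::mat &J) {
  arma::vec yp = y, fp(NS);
  for (int j = 0; j < NS; ++j) {
    double del = 1.49e-8 * std::max(std::fabs(y[j]), 1e-5);
    yp[j] = y[j] + del;
    rhs(t, yp, par, light, seg_end, fp, false);
    J.col(j) = (fp - f0) / del;
    yp[j] = y[j];
  }
}

static const int frac_idx[6] = { iQA, iPQ, iP700, iS23, iPSBS, iZX };
static const char *frac_names[6] = {
  "qa_reduced", "pq_reduced", "p700_ox", "s23_donor_frac",
  "psbs_protonated", "zeaxanthin"
};

// Integrate from grid[0] over the reporting grid.  grid must contain every
// protocol breakpoint; is_break flags grid points where the step size is
// re-initialised; seg_end[i] is the light-segment end for interval i.
// Returns the state at every grid point (row-wise) plus step diagnostics.
// [[Rcpp::export]]
List cpp_integrate(NumericVector y0, NumericVector par, NumericVector light,
                   NumericVector grid, LogicalVector is_break,
                   NumericVector seg_end, double rtol, NumericVector atol,
                   double h_init, double max_steps) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);

  arma::vec y(y0.begin(), NS), pv(par.begin(), par.size());
  arma::vec lv(light.begin(), light.size());
  arma::vec av(atol.begin(), NS);
  int ng = grid.size();
  arma::mat out(ng, NS);
  out.row(0) = y.t();

  double h = h_init;
  double n_accept = 0, n_reject = 0;
  arma::vec f0(NS), f1(NS), f2(NS), ft(NS), Tdot(NS);
  arma::vec k1(NS), k2(NS), k3(NS), ynew(NS), err(NS);
  arma::mat J(NS, NS), W(NS, NS), I_ = arma::eye(NS, NS);

  for (int i = 0; i + 1 < ng; ++i) {
    double t = grid[i], t_end = grid[i + 1], se = seg_end[i];
    if (is_break[i]) h = h_init;
    while (t < t_end - 1e-12 * std::max(1.0, t_end)) {
      if (n_accept + n_reject > max_steps) {
        stop("integrator exceeded %g steps; last good time %f", max_steps, t);
      }
      if (h > t_end - t) h = t_end - t;
      rhs(t, y, pv, lv, se, f0, true);
      double dt_t = 1e-7 * std::max(1.0, std::fabs(t));
      if (dt_t > 0.25 * h) dt_t = 0.25 * h;
      rhs(t + dt_t, y, pv, lv, se, ft, false);
      Tdot = (ft - f0) / dt_t;
      num_jac(t, y, pv, lv, se, f0, J);

      bool accepted = false;
      while (!accepted) {
        W = I_ - (h * d) * J;
        arma::mat L, U, P;
        bool lu_ok = arma::lu(L, U, P, W);
        if (lu_ok) {
          arma::vec ud = arma::abs(U.diag());
          lu_ok = ud.min() > 1e-13 * std::max(ud.max(), 1.0);
        }
        if (!lu_ok) { // near-singular: treat as a failed step, shrink h
          n_reject += 1;
          h *= 0.2;
          if (h < 1e-12 * std::max(1.0, t)) {
            stop("step size underflow (singular Rosenbrock matrix) at t = %f", t);
          }
          continue;
        }
        arma::vec hdT = (h * d) * Tdot;
        k1 = arma::solve(arma::trimatu(U),
              arma::solve(arma::trimatl(L), P * (f0 + hdT)));
        rhs(t + 0.5 * h, y + 0.5 * h * k1, pv, lv, se, f1, false);
        k2 = arma::solve(arma::trimatu(U),
              arma::solve(arma::trimatl(L), P * (f1 - k1))) + k1;
        ynew = y + h * k2;
        rhs(t + h, ynew, pv, lv, se, f2, false);
        k3 = arma::solve(arma::trimatu(U),
              arma::solve(arma::trimatl(L),
                P * (f2 - e32 * (k2 - f1) - 2.0 * (k1 - f0) + hdT)));
        err = (h / 6.0) * (k1 - 2.0 * k2 + k3);

        double en = 0.0;
        bool bad = false;
        for (int j = 0; j < NS; ++j) {
          if (!std::isfinite(ynew[j])) { bad = true; break; }
          double sk = av[j] + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
          double r = err[j] / sk;
          en += r * r;
        }
        en = std::sqrt(en / NS);
        if (!bad && en <= 1.0) {
          accepted = true;
          n_accept += 1;
          t += h;
          y = ynew;
          // invariant guard + clamp of pool fractions
          for (int j = 0; j < 6; ++j) {
            double v = y[frac_idx[j]];
            if (v < -1e-9 || v > 1.0 + 1e-9) {
              stop("state fraction %s = %g outside [0,1] at t = %f",
                   frac_names[j], v, t);
            }
            if (v < 0) y[frac_idx[j]] = 0.0;
            if (v > 1) y[frac_idx[j]] = 1.0;
          }
          if (!std::isfinite(y[iPH]) || !std::isfinite(y[iPSI_])) {
            stop("non-finite lumen_ph or delta_psi at t = %f", t);
          }
          double fac = (en > 0) ? 0.9 * std::pow(en, -1.0 / 3.0) : 5.0;
          if (fac > 5.0) fac = 5.0;
          if (fac < 0.2) fac = 0.2;
          h *= fac;
        } else {
          n_reject += 1;
          double fac = bad ? 0.2 : std::max(0.2, 0.9 * std::pow(en, -1.0 / 3.0));
          h *= fac;
          if (h < 1e-12 * std::max(1.0, t)) {
            stop("step size underflow at t = %f", t);
          }
        }
      }
    }
    out.row(i + 1) = y.t();
  }

  return List::create(
    _["states"] = wrap(out),
    _["n_accept"] = n_accept,
    _["n_reject"] = n_reject
  );
}
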