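#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Parameter layout shared by all entry points:
// p[0]=Je p[1]=Ji p[2]=Ee p[3]=Ei p[4]=eta_bar p[5]=Delta p[6]=Vth
// p[7]=gate_pi (1: half-width pi*r, 0: half-width r)
// p[8]=full coupling (1: rate equations use the summed conductance)
// p[9]=iboth (1: I_ext also drives the inhibitory mean potential)

static inline double gateS(double r, double v, double Vth, bool gate_pi) {
  if (r <= 0.0) {
    if (v < Vth) return 0.0;
    if (v > Vth) return 1.0;
    return 0.5;
  }
  double w = gate_pi ? M_PI * r : r;
  return (M_PI_2 - std::atan((Vth - v) / w)) / M_PI;
}

static inline void mf_rhs(const double *x, const double *p, double Iext,
                          double *dx) {
  const double re = x[0], ve = x[1], ri = x[2], vi = x[3];
  const bool gate_pi = p[7] != 0.0, full = p[8] != 0.0, iboth = p[9] != 0.0;
  const double Se = gateS(re, ve, p[6], gate_pi);
  const double Si = gateS(ri, vi, p[6], gate_pi);
  const double ge = full ? p[0] * Se + p[1] * Si : p[0] * Se;
  const double gi = full ? p[0] * Se + p[1] * Si : p[1] * Si;
  dx[0] = p[5] / M_PI + 2.0 * re * ve - ge * re;
  dx[1] = p[4] + ve * ve - M_PI * M_PI * re * re - p[0] * (ve - p[2]) * Se -
          p[1] * (ve - p[3]) * Si + Iext;
  dx[2] = p[5] / M_PI + 2.0 * ri * vi - gi * ri;
  dx[3] = p[4] + vi * vi - M_PI * M_PI * ri * ri - p[0] * (vi - p[2]) * Se -
          p[1] * (vi - p[3]) * Si + (iboth ? Iext : 0.0);
}

// Analytic Jacobian of the mean-field vector field (gate partials included).
static void mf_jac(const double *x, const double *p, double J[4][4]) {
  const double re = x[0], ve = x[1], ri = x[2], vi = x[3];
  const bool gate_pi = p[7] != 0.0, full = p[8] != 0.0;
  const double Vth = p[6];
  const double ce = gate_pi ? M_PI : 1.0;   // half-width = ce * r
  const double Se = gateS(re, ve, Vth, gate_pi);
  const double Si = gateS(ri, vi, Vth, gate_pi);
  // dS/dr = (1/pi) * c*(Vth-v) / ((c r)^2 + (Vth-v)^2)
  // dS/dv = (1/pi) * c*r       / ((c r)^2 + (Vth-v)^2)
  const double de = (ce * re) * (ce * re) + (Vth - ve) * (Vth - ve);
  const double di = (ce * ri) * (ce * ri) + (Vth - vi) * (Vth - vi);
  const double dSe_dr = ce * (Vth - ve) / (M_PI * de);
  const double dSe_dv = ce * re / (M_PI * de);
  const double dSi_dr = ce * (Vth - vi) / (M_PI * di);
  const double dSi_dv = ce * ri / (M_PI * di);
  const double Je = p[0], Ji = p[1], Ee = p[2], Ei = p[3];
  const double pi2 = M_PI * M_PI;

  if (!full) {
    J[0][0] = 2.0 * ve - Je * (Se + re * dSe_dr);
    J[0][1] = 2.0 * re - Je * re * dSe_dv;
    J[0][2] = 0.0;
    J[0][3] = 0.0;
    J[2][0] = 0.0;
    J[2][1] = 0.0;
    J[2][2] = 2.0 * vi - Ji * (Si + ri * dSi_dr);
    J[2][3] = 2.0 * ri - Ji * ri * dSi_dv;
  } else {
    const double g = Je * Se + Ji * Si;
    J[0][0] = 2.0 * ve - g - re * Je * dSe_dr;
    J[0][1] = 2.0 * re - re * Je * dSe_dv;
    J[0][2] = -re * Ji * dSi_dr;
    J[0][3] = -re * Ji * dSi_dv;
    J[2][0] = -ri * Je * dSe_dr;
    J[2][1] = -ri * Je * dSe_dv;
    J[2][2] = 2.0 * vi - g - ri * Ji * dSi_dr;
    J[2][3] = 2.0 * ri - ri * Ji * dSi_dv;
  }
  J[1][0] = -2.0 * pi2 * re - Je * (ve - Ee) * dSe_dr;
  J[1][1] = 2.0 * ve - Je * Se - Je * (ve - Ee) * dSe_dv - Ji * Si;
  J[1][2] = -Ji * (ve - Ei) * dSi_dr;
  J[1][3] = -Ji * (ve - Ei) * dSi_dv;
  J[3][0] = -Je * (vi - Ee) * dSe_dr;
  J[3][1] = -Je * (vi - Ee) * dSe_dv;
  J[3][2] = -2.0 * pi2 * ri - Ji * (vi - Ei) * dSi_dr;
  J[3][3] = 2.0 * vi - Ji * Si - Je * Se - Ji * (vi - Ei) * dSi_dv;
}

static inline void rk4_step(double *x, const double *p, double Iext,
                            double dt) {
  double k1[4], k2[4], k3[4], k4[4], xt[4];
  mf_rhs(x, p, Iext, k1);
  for (int j = 0; j < 4; ++j) xt[j] = x[j] + 0.5 * dt * k1[j];
  mf_rhs(xt, p, Iext, k2);
  for (int j = 0; j < 4; ++j) xt[j] = x[j] + 0.5 * dt * k2[j];
  mf_rhs(xt, p, Iext, k3);
  for (int j = 0; j < 4; ++j) xt[j] = x[j] + dt * k3[j];
  mf_rhs(xt, p, Iext, k4);
  for (int j = 0; j < 4; ++j)
    x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

// [[Rcpp::export(name = ".cpp_mf_rhs")]]
NumericVector cpp_mf_rhs(NumericVector x, NumericVector p, double Iext) {
  NumericVector out(4);
  mf_rhs(x.begin(), p.begin(), Iext, out.begin());
  return out;
}

// [[Rcpp::export(name = ".cpp_mf_jac")]]
NumericMatrix cpp_mf_jac(NumericVector x, NumericVector p) {
  double J[4][4];
  mf_jac(x.begin(), p.begin(), J);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = J[i][j];
  return out;
}

// Piecewise-constant protocol: seg_end[k] is the index of the last step
// (1-based, cumulative) integrated with current seg_I[k].
// [[Rcpp::export(name = ".cpp_mf_integrate")]]
List cpp_mf_integrate(NumericVector x0, NumericVector p, NumericVector seg_I,
                      IntegerVector seg_nstep, double t0, double dt,
                      int keep_every) {
  int nseg = seg_I.size();
  long ntot = 0;
  for (int k = 0; k < nseg; ++k) ntot += seg_nstep[k];
  long nkeep = ntot / keep_every + 1;
  NumericVector tout(nkeep), Iout(nkeep);
  NumericMatrix xout(nkeep, 4);
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  long i = 0, ki = 0;
  tout[0] = t0;
  Iout[0] = seg_I[0];
  for (int j = 0; j < 4; ++j) xout(0, j) = x[j];
  ki = 1;
  for (int k = 0; k < nseg; ++k) {
    double Iext = seg_I[k];
    for (int s = 0; s < seg_nstep[k]; ++s) {
      rk4_step(x, p.begin(), Iext, dt);
      ++i;
      for (int j = 0; j < 4; ++j) {
        if (!std::isfinite(x[j]) || std::fabs(x[j]) > 1e9)
          stop("mean-field trajectory diverged at t = %f", t0 + i * dt);
      }
      if (i % keep_every == 0 && ki < nkeep) {
        tout[ki] = t0 + i * dt;
        Iout[ki] = Iext;
        for (int j = 0; j < 4; ++j) xout(ki, j) = x[j];
        ++ki;
      }
    }
  }
  return List::create(_["t"] = tout[Range(0, ki - 1)],
                      _["x"] = xout(Range(0, ki - 1), _),
                      _["Iext"] = Iout[Range(0, ki - 1)]);
}

// Integrate state together with the 4x4 variational system; returns the
// final state and the monodromy-type matrix M(T) with M(0) = I.
// [[Rcpp::export(name = ".cpp_mf_variational")]]
List cpp_mf_variational(NumericVector x0, NumericVector p, double Iext,
                        double T, double dt) {
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double M[4][4] = {{1, 0, 0, 0}, {0, 1, 0, 0}, {0, 0, 1, 0}, {0, 0, 0, 1}};
  long n = (long)std::floor(T / dt + 0.5);
  double rem = T - n * dt;  // final fractional step
  double kx[4][4], kM[4][4][4], xt[4], Mt[4][4], J[4][4];
  for (long i = 0; i <= n; ++i) {
    double h = (i < n) ? dt : rem;
    if (h <= 1e-15) break;
    // stage 1
    mf_rhs(x, p.begin(), Iext, kx[0]);
    mf_jac(x, p.begin(), J);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        kM[0][a][b] = 0.0;
        for (int c = 0; c < 4; ++c) kM[0][a][b] += J[a][c] * M[c][b];
      }
    // stages 2..4
    const double frac[3] = {0.5, 0.5, 1.0};
    for (int st = 1; st < 4; ++st) {
      for (int j = 0; j < 4; ++j) xt[j] = x[j] + frac[st - 1] * h * kx[st - 1][j];
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          Mt[a][b] = M[a][b] + frac[st - 1] * h * kM[st - 1][a][b];
      mf_rhs(xt, p.begin(), Iext, kx[st]);
      mf_jac(xt, p.begin(), J);
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          kM[st][a][b] = 0.0;
          for (int c = 0; c < 4; ++c) kM[st][a][b] += J[a][c] * Mt[c][b];
        }
    }
    for (int j = 0; j < 4; ++j)
      x[j] += h / 6.0 * (kx[0][j] + 2 * kx[1][j] + 2 * kx[2][j] + kx[3][j]);
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        M[a][b] += h / 6.0 * (kM[0][a][b] + 2 * kM[1][a][b] + 2 * kM[2][a][b] +
                              kM[3][a][b]);
    for (int j = 0; j < 4; ++j)
      if (!std::isfinite(x[j]) || std::fabs(x[j]) > 1e9)
        stop("variational integration diverged");
  }
  NumericVector xT(4);
  NumericMatrix Mout(4, 4);
  for (int j = 0; j < 4; ++j) xT[j] = x[j];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) Mout(a, b) = M[a][b];
  return List::create(_["x"] = xT, _["M"] = Mout);
}

// Benettin two-trajectory estimate of the largest Lyapunov exponent.
// [[Rcpp::export(name = ".cpp_lyapunov")]]
double cpp_lyapunov(NumericVector x0, NumericVector dir0, NumericVector p,
                    double Iext, double t_total, double t_renorm, double d0,
                    double dt) {
  double x[4] = {x0[0], x0[1], x0[2], x0[3]};
  double nrm = 0.0;
  for (int j = 0; j < 4; ++j) nrm += dir0[j] * dir0[j];
  nrm = std::sqrt(nrm);
  double y[4];
  for (int j = 0; j < 4; ++j) y[j] = x[j] + d0 * dir0[j] / nrm;
  long steps_per = (long)std::floor(t_renorm / dt + 0.5);
  long ncycle = (long)std::floor(t_total / (steps_per * dt) + 0.5);
  double sumlog = 0.0;
  for (long c = 0; c < ncycle; ++c) {
    for (long s = 0; s < steps_per; ++s) {
      rk4_step(x, p.begin(), Iext, dt);
      rk4_step(y, p.begin(), Iext, dt);
    }
    double d = 0.0;
    for (int j = 0; j < 4; ++j) d += (y[j] - x[j]) * (y[j] - x[j]);
    d = std::sqrt(d);
    if (!std::isfinite(d)) stop("lyapunov trajectories diverged");
    if (d <= 0.0) d = 1e-300;
    sumlog += std::log(d / d0);
    for (int j = 0; j < 4; ++j) y[j] = x[j] + d0 * (y[j] - x[j]) / d;
  }
  return sumlog / (ncycle * steps_per * dt);
}

// Euler simulation of the two-population QIF network with instantaneous
// conductance synapses gated by the fraction of neurons above threshold.
// [[Rcpp::export(name = ".cpp_network_run")]]
List cpp_network_run(NumericVector Ve0, NumericVector Vi0, NumericVector eta_e,
                     NumericVector eta_i, NumericVector p, double Vpeak,
                     double Vreset, NumericVector seg_I,
                     IntegerVector seg_nstep, double t0, double dt,
                     int record_every) {
  const int Ne = Ve0.size(), Ni = Vi0.size();
  std::vector<double> Ve(Ve0.begin(), Ve0.end());
  std::vector<double> Vi(Vi0.begin(), Vi0.end());
  const double Je = p[0], Ji = p[1], Ee = p[2], Ei = p[3], Vth = p[6];
  const bool iboth = p[9] != 0.0;
  std::vector<double> sp_t_e, sp_t_i;
  std::vector<int> sp_id_e, sp_id_i;
  long ntot = 0;
  int nseg = seg_I.size();
  for (int k = 0; k < nseg; ++k) ntot += seg_nstep[k];
  long nrec = ntot / record_every + 1;
  NumericVector rec_t(nrec), rec_Se(nrec), rec_Si(nrec);
  long i = 0, ri = 0;
  for (int k = 0; k < nseg; ++k) {
    double Iext = seg_I[k];
    for (int s = 0; s < seg_nstep[k]; ++s) {
      int ce = 0, ci = 0;
      for (int j = 0; j < Ne; ++j) ce += (Ve[j] > Vth);
      for (int j = 0; j < Ni; ++j) ci += (Vi[j] > Vth);
      double Se = (double)ce / Ne, Si = (double)ci / Ni;
      if (i % record_every == 0 && ri < nrec) {
        rec_t[ri] = t0 + i * dt;
        rec_Se[ri] = Se;
        rec_Si[ri] = Si;
        ++ri;
      }
      double t_next = t0 + (i + 1) * dt;
      for (int j = 0; j < Ne; ++j) {
        double V = Ve[j];
        V += dt * (V * V + eta_e[j] + Iext - Je * (V - Ee) * Se -
                   Ji * (V - Ei) * Si);
        if (!std::isfinite(V))
          stop("network blow-up: excitatory neuron %d at t = %f", j + 1,
               t_next);
        if (V >= Vpeak) {
          sp_t_e.push_back(t_next);
          sp_id_e.push_back(j + 1);
          V = Vreset;
        }
        Ve[j] = V;
      }
      for (int j = 0; j < Ni; ++j) {
        double V = Vi[j];
        V += dt * (V * V + eta_i[j] + (iboth ? Iext : 0.0) -
                   Je * (V - Ee) * Se - Ji * (V - Ei) * Si);
        if (!std::isfinite(V))
          stop("network blow-up: inhibitory neuron %d at t = %f", j + 1,
               t_next);
        if (V >= Vpeak) {
          sp_t_i.push_back(t_next);
          sp_id_i.push_back(j + 1);
          V = Vreset;
        }
        Vi[j] = V;
      }
      ++i;
    }
  }
  return List::create(
      _["spike_t_e"] = wrap(sp_t_e), _["spike_id_e"] = wrap(sp_id_e),
      _["spike_t_i"] = wrap(sp_t_i), _["spike_id_i"] = wrap(sp_id_i),
      _["rec_t"] = rec_t[Range(0, ri - 1)],
      _["rec_Se"] = rec_Se[Range(0, ri - 1)],
      _["rec_Si"] = rec_Si[Range(0, ri - 1)], _["Ve"] = wrap(Ve),
      _["Vi"] = wrap(Vi));
}
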