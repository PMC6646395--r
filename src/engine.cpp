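// Fixed-step RK4 integrator for the coupled STN-GPe network with the
// closed-loop stimulation controllers, the online resonant LFP filter,
// the delay buffer and the on/off hysteresis gate.
//
// Layout: structure-of-arrays per population (v, Ca, n, h, r, s), the whole
// network integrated as one ODE so synaptic coupling is consistent across
// RK4 stages. The stimulation current is piecewise constant over a step
// (pulse edges snapped to the integration grid) and identical for all STN
// cells; GPe cells receive no stimulation.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// exp via 2^k * exp(f ln2) with a degree-6 polynomial on |f| <= 1/2;
// relative error ~1e-7, adequate for gating sigmoids and ~4x faster than
// libm. Monotone and deterministic.
static inline double fexp(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) return std::exp(x);
  double y = x * 1.4426950408889634;       // x / ln 2
  int64_t ki = (int64_t)(y + (y >= 0.0 ? 0.5 : -0.5));
  double k = (double)ki;
  double t = (y - k) * 0.6931471805599453; // |t| <= ln2/2
  double p = 1.0 + t * (1.0 + t * (0.5 + t * (1.0 / 6.0 + t * (1.0 / 24.0 +
              t * (1.0 / 120.0 + t * (1.0 / 720.0))))));
  union { double d; int64_t i; } u;
  u.i = (ki + 1023) << 52;
  return p * u.d;
}

static inline double logi(double v, double th, double sg) {
  return 1.0 / (1.0 + fexp(-(v - th) / sg));
}

struct CellP {
  double C_m, g_L, g_K, g_Na, g_T, g_Ca, g_AHP;
  double v_L, v_K, v_Na, v_Ca;
  double k_Ca, k_1;
  double theta_n, sigma_n, theta_h, sigma_h, theta_r, sigma_r;
  double theta_m, sigma_m, theta_s, sigma_s, theta_a, sigma_a;
  double tau0_n, tau1_n, theta_tau_n, sigma_tau_n;
  double tau0_h, tau1_h, theta_tau_h, sigma_tau_h;
  double tau0_r, tau1_r, theta_tau_r, sigma_tau_r;
  double phi_n, phi_h, phi_r;
  double theta_b, sigma_b, b_off;
  bool is_stn;
};

static CellP unpack_cell(const List& p, bool is_stn) {
  CellP c;
  c.C_m = p["C_m"]; c.g_L = p["g_L"]; c.g_K = p["g_K"]; c.g_Na = p["g_Na"];
  c.g_T = p["g_T"]; c.g_Ca = p["g_Ca"]; c.g_AHP = p["g_AHP"];
  c.v_L = p["v_L"]; c.v_K = p["v_K"]; c.v_Na = p["v_Na"]; c.v_Ca = p["v_Ca"];
  c.k_Ca = p["k_Ca"]; c.k_1 = p["k_1"];
  c.theta_n = p["theta_n"]; c.sigma_n = p["sigma_n"];
  c.theta_h = p["theta_h"]; c.sigma_h = p["sigma_h"];
  c.theta_r = p["theta_r"]; c.sigma_r = p["sigma_r"];
  c.theta_m = p["theta_m"]; c.sigma_m = p["sigma_m"];
  c.theta_s = p["theta_s"]; c.sigma_s = p["sigma_s"];
  c.theta_a = p["theta_a"]; c.sigma_a = p["sigma_a"];
  c.tau0_n = p["tau0_n"]; c.tau1_n = p["tau1_n"];
  c.theta_tau_n = p["theta_tau_n"]; c.sigma_tau_n = p["sigma_tau_n"];
  c.tau0_h = p["tau0_h"]; c.tau1_h = p["tau1_h"];
  c.theta_tau_h = p["theta_tau_h"]; c.sigma_tau_h = p["sigma_tau_h"];
  c.tau0_r = p["tau0_r"]; c.tau1_r = p["tau1_r"];
  c.theta_tau_r = p["theta_tau_r"]; c.sigma_tau_r = p["sigma_tau_r"];
  c.phi_n = p["phi_n"]; c.phi_h = p["phi_h"]; c.phi_r = p["phi_r"];
  c.theta_b = p["theta_b"]; c.sigma_b = p["sigma_b"];
  c.b_off = 1.0 / (1.0 + fexp(-c.theta_b / c.sigma_b));
  c.is_stn = is_stn;
  return c;
}

struct Net {
  int N;
  int off1, off2, off3;  // GPe->STN fan offsets on the ring
  CellP stn, gpe;
  // per-cell parameter vectors: heterogeneous I_app (STN) and eps (GPe),
  // with constant companions for the other population
  std::vector<double> Iapp_stn, eps_gpe, eps_stn, Iapp_gpe;
  double g_sg, g_gs, v_sg, v_gs;
  double alpha, beta, alpha_gpe, beta_gpe, theta_g, theta_gH, sigma_gH;
};

// One population's contribution to the derivative. Y blocks per population:
// v, Ca, n, h, r, s (each length N). I_syn precomputed per cell; I_stim
// applied to STN only. All parameters are copied to locals so the compiler
// can keep them in registers (no aliasing with the output arrays).
static void pop_rhs(const CellP& P, int N,
                    const double* __restrict v, const double* __restrict Ca,
                    const double* __restrict n, const double* __restrict h,
                    const double* __restrict r, const double* __restrict s,
                    const double* __restrict Isyn,
                    const double* __restrict Iapp,
                    const double* __restrict eps, double Istim,
                    double alpha, double beta, double theta_g,
                    double theta_gH, double sigma_gH,
                    double* __restrict dv, double* __restrict dCa,
                    double* __restrict dn, double* __restrict dh,
                    double* __restrict dr, double* __restrict ds) {
  const double inv_Cm = 1.0 / P.C_m;
  const double g_L = P.g_L, g_K = P.g_K, g_Na = P.g_Na, g_T = P.g_T,
      g_Ca = P.g_Ca, g_AHP = P.g_AHP;
  const double v_L = P.v_L, v_K = P.v_K, v_Na = P.v_Na, v_Ca = P.v_Ca;
  const double k_Ca = P.k_Ca, k_1 = P.k_1;
  const double th_m = P.theta_m, is_m = 1.0 / P.sigma_m;
  const double th_s = P.theta_s, is_s = 1.0 / P.sigma_s;
  const double th_a = P.theta_a, is_a = 1.0 / P.sigma_a;
  const double th_n = P.theta_n, is_n = 1.0 / P.sigma_n;
  const double th_h = P.theta_h, is_h = 1.0 / P.sigma_h;
  const double th_r = P.theta_r, is_r = 1.0 / P.sigma_r;
  const double tau0_n = P.tau0_n, tau1_n = P.tau1_n,
      tht_n = P.theta_tau_n, ist_n = 1.0 / P.sigma_tau_n;
  const double tau0_h = P.tau0_h, tau1_h = P.tau1_h,
      tht_h = P.theta_tau_h, ist_h = 1.0 / P.sigma_tau_h;
  const double tau0_r = P.tau0_r, tau1_r = P.tau1_r,
      tht_r = P.theta_tau_r,
      ist_r = (P.tau1_r == 0.0) ? 0.0 : 1.0 / P.sigma_tau_r;
  const double phi_n = P.phi_n, phi_h = P.phi_h, phi_r = P.phi_r;
  const double th_b = P.theta_b, is_b = 1.0 / P.sigma_b, b_off = P.b_off;
  const bool is_stn = P.is_stn, tau_r_const = (P.tau1_r == 0.0);
  const double th_gH_eff = theta_g + theta_gH, is_gH = 1.0 / sigma_gH;
  for (int j = 0; j < N; ++j) {
    const double vj = v[j];
    const double m_inf = 1.0 / (1.0 + fexp((th_m - vj) * is_m));
    const double s_inf = 1.0 / (1.0 + fexp((th_s - vj) * is_s));
    const double a_inf = 1.0 / (1.0 + fexp((th_a - vj) * is_a));
    const double n_inf = 1.0 / (1.0 + fexp((th_n - vj) * is_n));
    const double h_inf = 1.0 / (1.0 + fexp((th_h - vj) * is_h));
    const double r_inf = 1.0 / (1.0 + fexp((th_r - vj) * is_r));
    const double tau_n = tau0_n + tau1_n / (1.0 + fexp((tht_n - vj) * ist_n));
    const double tau_h = tau0_h + tau1_h / (1.0 + fexp((tht_h - vj) * ist_h));
    const double tau_r = tau_r_const ? tau0_r
        : tau0_r + tau1_r / (1.0 + fexp((tht_r - vj) * ist_r));
    const double n2 = n[j] * n[j];
    const double I_L = g_L * (vj - v_L);
    const double I_K = g_K * n2 * n2 * (vj - v_K);
    const double I_Na = g_Na * m_inf * m_inf * m_inf * h[j] * (vj - v_Na);
    const double I_Ca = g_Ca * s_inf * s_inf * (vj - v_Ca);
    const double I_AHP = g_AHP * (vj - v_K) * Ca[j] / (Ca[j] + k_1);
    double I_T;
    if (is_stn) {
      const double b = 1.0 / (1.0 + fexp((r[j] - th_b) * is_b)) - b_off;
      I_T = g_T * a_inf * a_inf * a_inf * b * b * (vj - v_Ca);
    } else {
      I_T = g_T * a_inf * a_inf * a_inf * r[j] * (vj - v_Ca);
    }
    dv[j] = (-I_L - I_K - I_Na - I_T - I_Ca - I_AHP - Isyn[j] + Iapp[j] +
             Istim) * inv_Cm;
    dCa[j] = eps[j] * (-I_Ca - I_T - k_Ca * Ca[j]);
    dn[j] = phi_n * (n_inf - n[j]) / tau_n;
    dh[j] = phi_h * (h_inf - h[j]) / tau_h;
    dr[j] = phi_r * (r_inf - r[j]) / tau_r;
    const double H = 1.0 / (1.0 + fexp((th_gH_eff - vj) * is_gH));
    ds[j] = alpha * H * (1.0 - s[j]) - beta * s[j];
  }
}

static void net_rhs(const Net& net, const std::vector<double>& Y,
                    std::vector<double>& dY, double Istim,
                    std::vector<double>& isyn_stn,
                    std::vector<double>& isyn_gpe) {
  const int N = net.N;
  const double* sv = Y.data();             // STN blocks
  const double* sCa = sv + N;
  const double* sn = sv + 2 * N;
  const double* sh = sv + 3 * N;
  const double* sr = sv + 4 * N;
  const double* ss = sv + 5 * N;
  const double* gv = sv + 6 * N;           // GPe blocks
  const double* gCa = sv + 7 * N;
  const double* gn = sv + 8 * N;
  const double* gh = sv + 9 * N;
  const double* gr = sv + 10 * N;
  const double* gs = sv + 11 * N;
  // STN j <- GPe {j+off1, j+off2, j+off3} (periodic); GPe j <- STN j
  for (int j = 0; j < N; ++j) {
    int j1 = (j + net.off1 % N + N) % N;
    int j2 = (j + net.off2 % N + N) % N;
    int j3 = (j + net.off3 % N + N) % N;
    double spre = gs[j1] + gs[j2] + gs[j3];
    isyn_stn[j] = net.g_gs * (sv[j] - net.v_gs) * spre;
    isyn_gpe[j] = net.g_sg * (gv[j] - net.v_sg) * ss[j];
  }
  double* d = dY.data();
  pop_rhs(net.stn, N, sv, sCa, sn, sh, sr, ss, isyn_stn.data(),
          net.Iapp_stn.data(), net.eps_stn.data(), Istim,
          net.alpha, net.beta, net.theta_g, net.theta_gH, net.sigma_gH,
          d, d + N, d + 2 * N, d + 3 * N, d + 4 * N, d + 5 * N);
  pop_rhs(net.gpe, N, gv, gCa, gn, gh, gr, gs, isyn_gpe.data(),
          net.Iapp_gpe.data(), net.eps_gpe.data(), 0.0,
          net.alpha_gpe, net.beta_gpe, net.theta_g, net.theta_gH,
          net.sigma_gH,
          d + 6 * N, d + 7 * N, d + 8 * N, d + 9 * N, d + 10 * N, d + 11 * N);
}

// [[Rcpp::export]]
List simulate_network_cpp(List net_cfg, List stn_par, List gpe_par,
                          NumericVector Iapp_stn, NumericVector eps_gpe,
                          NumericVector y0, List ctrl_cfg, List pulse_cfg,
                          List filt_cfg, List sim_cfg) {
  Net net;
  net.N = as<int>(net_cfg["N"]);
  const int N = net.N;
  net.stn = unpack_cell(stn_par, true);
  net.gpe = unpack_cell(gpe_par, false);
  net.g_sg = net_cfg["g_stn_gpe"]; net.g_gs = net_cfg["g_gpe_stn"];
  net.v_sg = net_cfg["v_stn_gpe"]; net.v_gs = net_cfg["v_gpe_stn"];
  {
    IntegerVector offs = net_cfg["fan_offsets"];
    if (offs.size() != 3) stop("fan_offsets must have length 3");
    net.off1 = offs[0]; net.off2 = offs[1]; net.off3 = offs[2];
  }
  net.alpha = net_cfg["alpha"]; net.beta = net_cfg["beta"];
  net.alpha_gpe = net_cfg["alpha_gpe"]; net.beta_gpe = net_cfg["beta_gpe"];
  net.theta_g = net_cfg["theta_g"]; net.theta_gH = net_cfg["theta_gH"];
  net.sigma_gH = net_cfg["sigma_gH"];
  net.Iapp_stn.assign(Iapp_stn.begin(), Iapp_stn.end());
  net.eps_gpe.assign(eps_gpe.begin(), eps_gpe.end());
  net.eps_stn.assign(N, as<double>(stn_par["eps"]));
  net.Iapp_gpe.assign(N, as<double>(gpe_par["I_app"]));
  if ((int)net.Iapp_stn.size() != N || (int)net.eps_gpe.size() != N)
    stop("heterogeneity vectors must have length N");

  // controller
  std::string mode = as<std::string>(ctrl_cfg["mode"]);
  const bool is_ldf = (mode == "cpLDF" || mode == "apLDF");
  const bool is_adaptive = (mode == "aDBS" || mode == "apLDF");
  const double K = ctrl_cfg["K"], tau = ctrl_cfg["tau"];
  const double Th_on = ctrl_cfg["Th_on"], Th_off = ctrl_cfg["Th_off"];
  const double T_ramp = ctrl_cfg["T_ramp"];

  // pulse train
  const double F_hz = pulse_cfg["F_hz"], PW = pulse_cfg["PW"];
  const double GW = pulse_cfg["GW"], ratio = pulse_cfg["ratio"];
  const double period = 1000.0 / F_hz;
  const double seg1 = PW, seg2 = PW + GW, seg3 = (ratio + 1.0) * PW + GW;

  // filter: exact per-step propagator supplied from R
  NumericMatrix E = filt_cfg["E"];
  NumericVector B = filt_cfg["B"];
  const double k_f = filt_cfg["k_f"];
  double fu = filt_cfg["u"], fud = filt_cfg["udot"];

  // simulation grid
  const double dt = sim_cfg["dt"];
  const double t_total = sim_cfg["t_total"];
  const double t_stim_on = sim_cfg["t_stim_on"];
  const int rec_stride = as<int>(sim_cfg["rec_stride"]);
  const double spike_thresh = sim_cfg["spike_threshold"];
  const double spike_lockout = sim_cfg["spike_lockout"];
  const long n_steps = (long)std::llround(t_total / dt);
  const long lag = (long)std::llround(tau / dt);

  std::vector<double> Y(y0.begin(), y0.end());
  if ((int)Y.size() != 12 * N) stop("state vector has wrong length");
  std::vector<double> k1(12 * N), k2(12 * N), k3(12 * N), k4(12 * N),
      Ytmp(12 * N);
  std::vector<double> is1(N), is2(N);

  std::vector<double> xbuf; xbuf.reserve(n_steps + 1);
  // spike raster for both populations (STN 0..N-1, GPe N..2N-1)
  std::vector<std::vector<double>> spikes(2 * N);
  std::vector<double> vprev(2 * N), last_spike(2 * N, -1e9);
  for (int j = 0; j < N; ++j) { vprev[j] = Y[j]; vprev[N + j] = Y[6 * N + j]; }

  const long n_rec = n_steps / rec_stride + 1;
  NumericVector rec_t(n_rec), rec_lfp(n_rec), rec_x(n_rec), rec_S(n_rec),
      rec_A(n_rec);
  IntegerVector rec_gate(n_rec);
  long ri = 0;

  bool gate_on = false;
  double A_cur = 0.0;
  long cur_pulse = -1;
  double x2 = 0.0, x1 = 0.0; // x_{k-2}, x_{k-1}
  double S_now = 0.0;

  for (long i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    // --- observe: LFP, filter, delay buffer, gate ---
    double lfp = 0.0;
    {
      const double* ss = Y.data() + 5 * N;
      for (int j = 0; j < N; ++j) lfp += ss[j];
      lfp /= N;
    }
    if (!std::isfinite(lfp)) stop("numerical blow-up at t = %f ms", t);
    // exact zero-order-hold advance of the damped-oscillator filter
    {
      double in = k_f * lfp;
      double nu = E(0, 0) * fu + E(0, 1) * fud + B[0] * in;
      double nud = E(1, 0) * fu + E(1, 1) * fud + B[1] * in;
      fu = nu; fud = nud;
    }
    double x0 = fud;
    xbuf.push_back(x0);
    // local maximum of x at the previous sample
    if (i >= 2 && x1 >= x2 && x1 > x0) {
      if (is_adaptive && t >= t_stim_on) {
        if (!gate_on && x1 > Th_on) gate_on = true;
        else if (gate_on && x1 < Th_off) gate_on = false;
      }
    }
    if (!is_adaptive) gate_on = (t >= t_stim_on);
    x2 = x1; x1 = x0;

    // --- controller: ramp, S(t), pulse-onset amplitude freeze ---
    double Keff = 0.0;
    if (t >= t_stim_on) {
      double ramp = (T_ramp <= 0.0) ? 1.0 :
        std::min(1.0, (t - t_stim_on) / T_ramp);
      Keff = K * ramp;
    }
    if (t >= t_stim_on) {
      if (is_ldf) {
        long idel = i - lag;
        double xdel = (idel >= 0) ? xbuf[idel] : 0.0;
        S_now = gate_on ? Keff * (xdel - x0) : 0.0;
      } else {
        S_now = gate_on ? Keff : 0.0;
      }
      long np = (long)std::floor((t - t_stim_on) / period + 1e-9);
      if (np != cur_pulse) { cur_pulse = np; A_cur = S_now; }
    } else {
      S_now = 0.0; A_cur = 0.0; cur_pulse = -1;
    }

    // stimulation current over this step (pulse edges snapped to the grid)
    double Istim = 0.0;
    if (t >= t_stim_on && A_cur != 0.0) {
      double off = t - t_stim_on - cur_pulse * period;
      if (off < seg1) Istim = -ratio * A_cur;
      else if (off >= seg2 && off < seg3 && off < period) Istim = A_cur;
    }

    // --- record ---
    if (i % rec_stride == 0 && ri < n_rec) {
      rec_t[ri] = t; rec_lfp[ri] = lfp; rec_x[ri] = x0;
      rec_gate[ri] = gate_on ? 1 : 0; rec_S[ri] = S_now; rec_A[ri] = A_cur;
      ++ri;
    }
    if (i == n_steps) break;

    // --- RK4 step ---
    net_rhs(net, Y, k1, Istim, is1, is2);
    for (int q = 0; q < 12 * N; ++q) Ytmp[q] = Y[q] + 0.5 * dt * k1[q];
    net_rhs(net, Ytmp, k2, Istim, is1, is2);
    for (int q = 0; q < 12 * N; ++q) Ytmp[q] = Y[q] + 0.5 * dt * k2[q];
    net_rhs(net, Ytmp, k3, Istim, is1, is2);
    for (int q = 0; q < 12 * N; ++q) Ytmp[q] = Y[q] + dt * k3[q];
    net_rhs(net, Ytmp, k4, Istim, is1, is2);
    for (int q = 0; q < 12 * N; ++q) {
      Y[q] += dt / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
    }

    // --- spike detection (upward crossing with lockout), both populations
    double tn = t + dt;
    for (int q = 0; q < 2 * N; ++q) {
      double vj = (q < N) ? Y[q] : Y[5 * N + q]; // GPe v block starts at 6N
      if (vj >= spike_thresh && vprev[q] < spike_thresh &&
          tn - last_spike[q] > spike_lockout) {
        spikes[q].push_back(tn);
        last_spike[q] = tn;
      }
      vprev[q] = vj;
    }
  }

  List spikes_out(N), spikes_gpe(N);
  for (int j = 0; j < N; ++j) {
    spikes_out[j] = NumericVector(spikes[j].begin(), spikes[j].end());
    spikes_gpe[j] = NumericVector(spikes[N + j].begin(), spikes[N + j].end());
  }
  return List::create(
    _["t"] = rec_t, _["lfp"] = rec_lfp, _["x"] = rec_x,
    _["gate"] = rec_gate, _["S"] = rec_S, _["A"] = rec_A,
    _["spikes"] = spikes_out, _["spikes_gpe"] = spikes_gpe,
    _["state"] = NumericVector(Y.begin(), Y.end()),
    _["filter_u"] = fu, _["filter_udot"] = fud);
}

// [[Rcpp::export]]
NumericVector filter_trace_cpp(NumericVector lfp, NumericMatrix E,
                               NumericVector B, double k_f, double u,
                               double udot) {
  const R_xlen_t n = lfp.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double in = k_f * lfp[i];
    double nu = E(0, 0) * u + E(0, 1) * udot + B[0] * in;
    double nud = E(1, 0) * u + E(1, 1) * udot + B[1] * in;
    u = nu; udot = nud;
    out[i] = udot;
  }
  return out;
}
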