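// Core fixed-step integrator for the retino-thalamo-cortical circuit.
//
// Single-compartment Hodgkin-Huxley-type cells (thalamocortical relay cell:
// leak + I_Na + I_K + I_T + I_h; layer-4 cortical cell: leak + I_Na + I_K +
// I_M), alpha-function conductance synapses, dual Ornstein-Uhlenbeck
// background conductances with exc-inh and across-cell correlation schemas.
//
// Units: mV, ms, nS, nF, pA (nS * mV = pA; nF * mV/ms = pA). Injected
// currents cross the R boundary in nA and are converted here.
//
// Gates and V are advanced with exponential Euler at a fixed dt; synaptic
// alpha kernels are integrated exactly through their two-state linear form.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// parameter vector layout (see pack_params() on the R side)
enum {
  P_CM = 0, P_GL, P_EL,
  P_GNA, P_ENA, P_GK, P_EK, P_VT,
  P_GT, P_ECA,
  P_GH, P_EH,
  P_GM, P_EM, P_MVH, P_MK, P_MTAU,
  P_CATAU, P_CAREST, P_CAGAIN,
  NPAR
};

// x / (1 - exp(-x/y)), with the removable singularity at x = 0 -> y
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct GateK { double inf, tau; };

// Traub-Miles style spike currents, threshold shifted by vt
static inline GateK na_m(double v, double vt) {
  double v2 = v - vt;
  double a = 0.32 * vtrap(v2 - 13.0, 4.0);
  double b = 0.28 * vtrap(40.0 - v2, 5.0);
  return { a / (a + b), 1.0 / (a + b) };
}
static inline GateK na_h(double v, double vt) {
  double v2 = v - vt;
  double a = 0.128 * std::exp(-(v2 - 17.0) / 18.0);
  double b = 4.0 / (1.0 + std::exp(-(v2 - 40.0) / 5.0));
  return { a / (a + b), 1.0 / (a + b) };
}
static inline GateK k_n(double v, double vt) {
  double v2 = v - vt;
  double a = 0.032 * vtrap(v2 - 15.0, 5.0);
  double b = 0.5 * std::exp(-(v2 - 10.0) / 40.0);
  return { a / (a + b), 1.0 / (a + b) };
}

// Low-threshold Ca current (T-type), 2 mV screening shift, 36 C rates
static inline GateK t_m(double v) {
  double inf = 1.0 / (1.0 + std::exp(-(v + 59.0) / 6.2));
  double tau = (0.612 + 1.0 / (std::exp(-(v + 134.0) / 16.7) +
                               std::exp((v + 18.8) / 18.2))) / 3.0;
  return { inf, tau };
}
static inline GateK t_h(double v) {
  double inf = 1.0 / (1.0 + std::exp((v + 83.0) / 4.0));
  double tau;
  if (v + 2.0 < -80.0) tau = std::exp((v + 469.0) / 66.6) / 3.73;
  else tau = (28.0 + std::exp(-(v + 24.0) / 10.5)) / 3.73;
  return { inf, tau };
}

// Hyperpolarization-activated cation current
static inline GateK h_m(double v) {
  double inf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
  double tau = 1.0 / (std::exp(-14.59 - 0.086 * v) +
                      std::exp(-1.87 + 0.0701 * v));
  return { inf, tau };
}

// Slow non-inactivating K current (M-type form, calibrated midpoint/slope)
static inline GateK m_p(double v, double vh, double k, double taumax) {
  double inf = 1.0 / (1.0 + std::exp(-(v - vh) / k));
  double tau = taumax / (3.3 * std::exp((v - vh) / 20.0) +
                         std::exp(-(v - vh) / 20.0));
  return { inf, tau };
}

// gate codes: 0 na_m, 1 na_h, 2 k_n, 3 t_m, 4 t_h, 5 h_m, 6 m_p
// [[Rcpp::export]]
NumericVector gate_kinetics_cpp(int gate, double v, NumericVector par) {
  GateK g;
  switch (gate) {
    case 0: g = na_m(v, par[P_VT]); break;
    case 1: g = na_h(v, par[P_VT]); break;
    case 2: g = k_n(v, par[P_VT]); break;
    case 3: g = t_m(v); break;
    case 4: g = t_h(v); break;
    case 5: g = h_m(v); break;
    case 6: g = m_p(v, par[P_MVH], par[P_MK], par[P_MTAU]); break;
    default: stop("unknown gate code");
  }
  return NumericVector::create(_["alpha"] = g.inf / g.tau,
                               _["beta"]  = (1.0 - g.inf) / g.tau,
                               _["inf"]   = g.inf,
                               _["tau"]   = g.tau);
}

struct CellState {
  double v, nam, nah, kn, tm, th, hm, mp, ca;
};

static void init_state(CellState &s, const double *p, double v0) {
  s.v = v0;
  s.nam = na_m(v0, p[P_VT]).inf;
  s.nah = na_h(v0, p[P_VT]).inf;
  s.kn  = k_n(v0, p[P_VT]).inf;
  s.tm  = t_m(v0).inf;
  s.th  = t_h(v0).inf;
  s.hm  = h_m(v0).inf;
  s.mp  = m_p(v0, p[P_MVH], p[P_MK], p[P_MTAU]).inf;
  s.ca  = p[P_CAREST];
}

static inline void gate_step(double &x, const GateK &g, double dt) {
  x += (g.inf - x) * (-std::expm1(-dt / g.tau));
  if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
}

// advance one cell by dt; g_ampa/g_gaba/g_e/g_i in nS, i_inj in pA
// returns new V
static inline double cell_step(CellState &s, const double *p, double dt,
                               double g_ampa, double g_gaba,
                               double g_e, double g_i,
                               double e_e, double e_i, double i_inj) {
  double v = s.v;
  gate_step(s.nam, na_m(v, p[P_VT]), dt);
  gate_step(s.nah, na_h(v, p[P_VT]), dt);
  gate_step(s.kn,  k_n(v, p[P_VT]), dt);
  double gT = 0.0, gH = 0.0, gM = 0.0;
  if (p[P_GT] > 0.0) {
    gate_step(s.tm, t_m(v), dt);
    gate_step(s.th, t_h(v), dt);
    gT = p[P_GT] * s.tm * s.tm * s.th;
    double i_t = gT * (v - p[P_ECA]);                    // pA, inward < 0
    s.ca += dt * (-p[P_CAGAIN] * i_t - (s.ca - p[P_CAREST]) / p[P_CATAU]);
    if (s.ca < 0.0) s.ca = 0.0;
  }
  if (p[P_GH] > 0.0) {
    gate_step(s.hm, h_m(v), dt);
    gH = p[P_GH] * s.hm;
  }
  if (p[P_GM] > 0.0) {
    gate_step(s.mp, m_p(v, p[P_MVH], p[P_MK], p[P_MTAU]), dt);
    gM = p[P_GM] * s.mp;
  }
  double gNa = p[P_GNA] * s.nam * s.nam * s.nam * s.nah;
  double gK  = p[P_GK] * s.kn * s.kn * s.kn * s.kn;
  double G = p[P_GL] + gNa + gK + gT + gH + gM + g_ampa + g_gaba + g_e + g_i;
  double N = p[P_GL] * p[P_EL] + gNa * p[P_ENA] + gK * p[P_EK] +
             gT * p[P_ECA] + gH * p[P_EH] + gM * p[P_EM] +
             g_gaba * (-75.0) + g_e * e_e + g_i * e_i + i_inj;
  // AMPA reversal is 0 mV: no numerator term
  double vinf = N / G;
  s.v = vinf + (v - vinf) * std::exp(-G * dt / p[P_CM]);
  return s.v;
}

// two-state alpha synapse: on spike x1 += w*exp(1); g = x2 peaks at w
struct AlphaSyn {
  double x1 = 0.0, x2 = 0.0, tau;
  void step(double dt) {
    double d = std::exp(-dt / tau);
    x2 = d * (x2 + x1 * dt / tau);
    x1 *= d;
  }
  void spike(double w) { x1 += w * M_E; }
};

struct PendEv { long step; int kind; double w; };  // kind 0 AMPA, 1 GABA
struct PendCmp {
  bool operator()(const PendEv &a, const PendEv &b) const {
    return a.step > b.step;
  }
};

// noise_par: g0e sige taue Ee g0i sigi taui Ei cpop schema cei lag_ei clip
// schema: 0 homogeneous, 1 heterogeneous
// noise_mode: 0 none, 1 internal OU, 2 supplied traces (noise_tr)
// [[Rcpp::export]]
List sim_network_cpp(NumericMatrix par_tc, NumericVector par_ctx,
                     List ret_ev_t, List ret_ev_w,
                     NumericMatrix ctx_ev,
                     NumericVector noise_par, NumericMatrix noise_tr,
                     int noise_mode,
                     NumericVector i_const, NumericMatrix sine_par,
                     NumericMatrix iprot,
                     NumericVector w_tc,
                     double ffi_w, double ffi_lag, double thal_jitter,
                     double duration, double dt,
                     double v_spike, double v_rearm, double v0_tc,
                     double v0_ctx,
                     int record_every, IntegerVector record_idx) {
  const int ntc = par_tc.nrow();
  const bool has_ctx = par_ctx.size() > 0;
  const long nsteps = (long)std::llround(duration / dt);

  std::vector<CellState> tc(ntc);
  std::vector<AlphaSyn> ret_syn(ntc);
  // NumericMatrix is column-major; build row-wise copies of parameters
  std::vector<std::vector<double>> ptc(ntc, std::vector<double>(NPAR));
  for (int i = 0; i < ntc; ++i)
    for (int j = 0; j < NPAR; ++j) ptc[i][j] = par_tc(i, j);
  for (int i = 0; i < ntc; ++i) init_state(tc[i], ptc[i].data(), v0_tc);
  for (int i = 0; i < ntc; ++i) ret_syn[i].tau = 1.0;

  CellState cx;
  std::vector<double> pcx(NPAR, 0.0);
  AlphaSyn ctx_ampa, ctx_gaba;
  ctx_ampa.tau = 1.0; ctx_gaba.tau = 2.0;
  if (has_ctx) {
    for (int j = 0; j < NPAR; ++j) pcx[j] = par_ctx[j];
    init_state(cx, pcx.data(), v0_ctx);
  }

  // retinal event cursors
  std::vector<NumericVector> rev_t(ntc), rev_w(ntc);
  std::vector<int> rcur(ntc, 0);
  for (int i = 0; i < ntc; ++i) {
    rev_t[i] = as<NumericVector>(ret_ev_t[i]);
    rev_w[i] = as<NumericVector>(ret_ev_w[i]);
  }
  int ccur = 0;  // external ctx event cursor

  // OU noise setup
  double g0e = 0, sige = 0, taue = 1, Ee = 0;
  double g0i = 0, sigi = 0, taui = 1, Ei = -75;
  double cpop = 0, cei = 0;
  int schema = 0, lag_steps = 0, Mhet = 0;
  bool clip = true;
  double ae = 0, be = 0, ai = 0, bi = 0, sq_ind = 1, sq_com = 0;
  std::vector<double> oue, oui;      // per-cell independent OU states
  double ouce = 0, ouci = 0;         // common OU states
  std::vector<std::vector<double>> ebuf;  // exc innovation ring buffers
  int ebuf_pos = 0;
  if (noise_mode == 1) {
    g0e = noise_par[0]; sige = noise_par[1]; taue = noise_par[2];
    Ee = noise_par[3];
    g0i = noise_par[4]; sigi = noise_par[5]; taui = noise_par[6];
    Ei = noise_par[7];
    cpop = noise_par[8]; schema = (int)noise_par[9];
    cei = noise_par[10];
    lag_steps = (int)std::llround(noise_par[11] / dt);
    clip = noise_par[12] != 0.0;
    if (dt >= taue || dt >= taui) stop("dt must be < noise correlation times");
    ae = std::exp(-dt / taue); be = sige * std::sqrt(1.0 - ae * ae);
    ai = std::exp(-dt / taui); bi = sigi * std::sqrt(1.0 - ai * ai);
    oue.assign(ntc, g0e); oui.assign(ntc, g0i);
    ouce = g0e; ouci = g0i;
    sq_ind = std::sqrt(1.0 - cpop); sq_com = std::sqrt(cpop);
    Mhet = ntc > 1 ? 1 + (int)std::floor(cpop * (ntc - 1) + 0.5) : 1;
    ebuf.assign(ntc + 1, std::vector<double>(lag_steps + 1, 0.0));
  } else if (noise_mode == 2) {
    Ee = noise_par[3]; Ei = noise_par[7];
    clip = noise_par[12] != 0.0;
    if (noise_tr.nrow() < nsteps) stop("supplied noise traces too short");
  }

  // current protocol cursor (applies to every TC cell, or ctx if ntc == 0)
  int pcur = 0;
  double iprot_now = 0.0;

  std::priority_queue<PendEv, std::vector<PendEv>, PendCmp> pend;

  // recording
  const int nrec_cells = record_idx.size();
  const long nrec = record_every > 0 ? nsteps / record_every : 0;
  NumericMatrix vrec(nrec_cells > 0 ? nrec : 0, nrec_cells);
  std::vector<int> rec0(nrec_cells);
  for (int k = 0; k < nrec_cells; ++k) rec0[k] = record_idx[k] - 1;

  std::vector<std::vector<double>> spikes(ntc + 1);
  std::vector<bool> armed(ntc, true);
  bool armed_cx = true;
  long irec = 0;

  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    // piecewise-constant injected current protocol
    while (pcur < iprot.nrow() && iprot(pcur, 0) <= t + 0.5 * dt) {
      iprot_now = iprot(pcur, 1); ++pcur;
    }
    // OU update (common streams first, then per cell, fixed order)
    if (noise_mode == 1) {
      int dpos = (ebuf_pos + 1) % (lag_steps + 1);  // oldest entry = delayed
      double xe = norm_rand();
      double xi;
      if (cei > 0.0) {
        double del = ebuf[ntc][dpos];
        xi = std::sqrt(1.0 - cei) * norm_rand() + std::sqrt(cei) * del;
        ebuf[ntc][ebuf_pos] = xe;
      } else xi = norm_rand();
      ouce = g0e + (ouce - g0e) * ae + be * xe;
      ouci = g0i + (ouci - g0i) * ai + bi * xi;
      for (int i = 0; i < ntc; ++i) {
        double ye = norm_rand();
        double yi;
        if (cei > 0.0) {
          double del = ebuf[i][dpos];
          yi = std::sqrt(1.0 - cei) * norm_rand() + std::sqrt(cei) * del;
          ebuf[i][ebuf_pos] = ye;
        } else yi = norm_rand();
        oue[i] = g0e + (oue[i] - g0e) * ae + be * ye;
        oui[i] = g0i + (oui[i] - g0i) * ai + bi * yi;
      }
      ebuf_pos = dpos;
    }
    // deliver retinal events due in [t, t+dt)
    for (int i = 0; i < ntc; ++i) {
      ret_syn[i].step(dt);
      while (rcur[i] < rev_t[i].size() && rev_t[i][rcur[i]] < t + dt) {
        ret_syn[i].spike(rev_w[i][rcur[i]]); ++rcur[i];
      }
    }
    if (has_ctx) {
      ctx_ampa.step(dt); ctx_gaba.step(dt);
      while (ccur < ctx_ev.nrow() && ctx_ev(ccur, 0) < t + dt) {
        if (ctx_ev(ccur, 2) != 0.0) ctx_gaba.spike(ctx_ev(ccur, 1));
        else ctx_ampa.spike(ctx_ev(ccur, 1));
        ++ccur;
      }
      while (!pend.empty() && pend.top().step <= s) {
        const PendEv &e = pend.top();
        if (e.kind == 1) ctx_gaba.spike(e.w); else ctx_ampa.spike(e.w);
        pend.pop();
      }
    }
    // integrate TC cells
    for (int i = 0; i < ntc; ++i) {
      double ge = 0.0, gi = 0.0;
      if (noise_mode == 1) {
        if (schema == 0) {
          ge = g0e + sq_ind * (oue[i] - g0e) + sq_com * (ouce - g0e);
          gi = g0i + sq_ind * (oui[i] - g0i) + sq_com * (ouci - g0i);
        } else {
          ge = i < Mhet ? ouce : oue[i];
          gi = i < Mhet ? ouci : oui[i];
        }
      } else if (noise_mode == 2) {
        ge = noise_tr(s, 2 * i); gi = noise_tr(s, 2 * i + 1);
      }
      if (clip) { if (ge < 0.0) ge = 0.0; if (gi < 0.0) gi = 0.0; }
      double inj = i_const[i];
      if (sine_par(i, 0) > 0.0)
        inj += sine_par(i, 0) *
               std::sin(2.0 * M_PI * sine_par(i, 1) * t / 1000.0 +
                        sine_par(i, 2));
      inj = (inj + iprot_now) * 1000.0;  // nA -> pA
      double vold = tc[i].v;
      double vnew = cell_step(tc[i], ptc[i].data(), dt,
                              ret_syn[i].x2, 0.0, ge, gi, Ee, Ei, inj);
      if (!std::isfinite(vnew) || std::fabs(vnew) > 200.0)
        stop("numerical blow-up in TC cell %d at t = %.3f ms", i + 1, t);
      if (armed[i] && vnew >= v_spike && vold < v_spike) {
        spikes[i].push_back(t + dt);
        armed[i] = false;
        if (has_ctx) {
          double jit = thal_jitter > 0.0 ? exp_rand() * thal_jitter : 0.0;
          long ds = s + 1 + (long)std::llround(jit / dt);
          pend.push({ds, 0, w_tc[i]});
          if (ffi_w > 0.0)
            pend.push({ds + (long)std::llround(ffi_lag / dt), 1, ffi_w});
        }
      } else if (!armed[i] && vnew < v_rearm) armed[i] = true;
    }
    // integrate cortical cell
    if (has_ctx) {
      double inj = ntc == 0 ? iprot_now * 1000.0 : 0.0;
      double vold = cx.v;
      double vnew = cell_step(cx, pcx.data(), dt, ctx_ampa.x2, ctx_gaba.x2,
                              0.0, 0.0, Ee, Ei, inj);
      if (!std::isfinite(vnew) || std::fabs(vnew) > 200.0)
        stop("numerical blow-up in cortical cell at t = %.3f ms", t);
      if (armed_cx && vnew >= v_spike && vold < v_spike) {
        spikes[ntc].push_back(t + dt);
        armed_cx = false;
      } else if (!armed_cx && vnew < v_rearm) armed_cx = true;
    }
    // record
    if (record_every > 0 && (s + 1) % record_every == 0 && irec < nrec) {
      for (int k = 0; k < nrec_cells; ++k) {
        int c = rec0[k];
        vrec(irec, k) = c < ntc ? tc[c].v : cx.v;
      }
      ++irec;
    }
  }

  List spk(ntc + 1);
  for (int i = 0; i <= ntc; ++i) spk[i] = wrap(spikes[i]);
  return List::create(_["spikes"] = spk, _["v"] = vrec,
                      _["dt_record"] = record_every * dt,
                      _["n_steps"] = (double)nsteps);
}

// exact-discretization OU path (shared by R-level generator); z: N(0,1) draws
// [[Rcpp::export]]
NumericVector ou_path_cpp(double g0, double sigma, double tau, double dt,
                          NumericVector z, double ginit) {
  int n = z.size();
  NumericVector g(n + 1);
  double a = std::exp(-dt / tau), b = sigma * std::sqrt(1.0 - a * a);
  g[0] = ginit;
  for (int i = 0; i < n; ++i) g[i + 1] = g0 + (g[i] - g0) * a + b * z[i];
  return g;
}
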