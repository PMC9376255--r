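// Fixed-step RK4 core for the closed-loop lumped-parameter model.
//
// State layout: [V_LA, V_LV, s_MV, s_AV, P_term_1..P_term_nt]  (nt terminals)
// Node pressures of the rigid resistive tree are algebraic: p = Ginv %*% rhs,
// where G is the (constant) nodal conductance matrix assembled in R and
// Ginv its inverse.  The aortic valve flow is obtained in closed form from
// the Bernoulli law against the Thevenin equivalent seen at the root node.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Chamber {
  double Emax, V0, A, B, t_onset, t_sys, rise;
};

struct Valve {
  double Kopen, Kclose, Bq, L;
};

struct Device {
  bool active;
  double lam, Csr, k1, k2, t_on, t_off, dt_act, p_act;
  double a1, a2, a3, a4, a5;
};

const double S_FLOOR = 1e-6;

// Raised-cosine activation bump: rises over `rise * t_sys`, falls over the
// remainder; C1 everywhere, exactly 1 at the peak.  rise = 0.5 is the
// symmetric half-cosine; smaller values give the fast-contraction /
// slow-relaxation shape of impaired relaxation.
inline double activation(double t_cycle, const Chamber& ch, double T) {
  double x = t_cycle - ch.t_onset;
  if (x < 0.0) x += T;
  if (x < 0.0 || x > ch.t_sys) return 0.0;
  double xr = ch.rise * ch.t_sys;
  if (x <= xr) return 0.5 * (1.0 - std::cos(M_PI * x / xr));
  return 0.5 * (1.0 + std::cos(M_PI * (x - xr) / (ch.t_sys - xr)));
}

inline double chamber_pressure(double V, double e, const Chamber& ch) {
  double pas = ch.A * (std::exp(ch.B * (V - ch.V0)) - 1.0);
  return pas + e * ch.Emax * (V - ch.V0);
}

inline double clamp_gain(double g) {
  if (g < 0.0) return 0.0;
  if (g >= 1.0) return 1.0 - 1e-9;
  return g;
}

// Pressure source p_sr(t_norm) and its time derivative.  Contraction is a
// saturating exponential with rate k1; relaxation decays at rate k2 with
// continuity constants (c, d) pinning p_sr(t_on+) = p_sr(t_on-) and
// p_sr(t_off) = 0; identically zero beyond t_off.
inline void psr_eval(double tn, double g, double pa, const Device& dv,
                     double& p, double& dp) {
  double amp = g * pa;
  if (amp <= 0.0 || tn > dv.t_off) { p = 0.0; dp = 0.0; return; }
  if (tn <= dv.t_on) {
    double ex = std::exp(-dv.k1 * tn);
    p  = amp * (1.0 - ex);
    dp = amp * dv.k1 * ex;
  } else {
    double P_on = amp * (1.0 - std::exp(-dv.k1 * dv.t_on));
    double E = std::exp(-dv.k2 * (dv.t_off - dv.t_on));
    double c = P_on / (1.0 - E);
    double d = -P_on * E / (1.0 - E);
    double ex = std::exp(-dv.k2 * (tn - dv.t_on));
    p  = c * ex + d;
    dp = -dv.k2 * c * ex;
  }
}

inline double norm_time(double t, double dt_act, double hr) {
  double T = 60.0 / hr;
  return t - std::floor((t - dt_act) * hr / 60.0) * T - dt_act;
}

struct Model {
  int n_nodes, nt;
  NumericMatrix Ginv;          // n_nodes x n_nodes
  std::vector<int> term_node;  // 0-based node per terminal
  std::vector<double> Rp, Cc, Rd;
  double R_ven, sum_invRd;
  int device_node;             // -1 when absent
  Chamber la, lv;
  Valve mv, av;
  Device dev;
  double hr, T;
  bool has_qav;
  std::vector<double> zcol;    // Ginv[, root]
  double R_eq_root;

  // scratch
  mutable std::vector<double> rhs, pn;

  struct Aux {
    double P_LA, P_LV, P_ao, Q_MV, Q_AV, P_ven, p_sr, Q_dev, e_LA, e_LV;
    std::vector<double> Q_br, P_br;
  };

  // g_act is refreshed once per cycle from the running mean root pressure,
  // mirroring the static-loop bench characterization.
  double g_act;

  void deriv(double t, const double* y, double* dy, Aux* aux) const {
    double T_ = T;
    double tc = t - std::floor(t / T_) * T_;

    double V_LA = y[0], V_LV = y[1], s_MV = y[2], s_AV = y[3];
    const double* P_term = y + 4;

    double e_la = activation(tc, la, T_);
    double e_lv = activation(tc, lv, T_);
    double P_LA = chamber_pressure(V_LA, e_la, la);
    double P_LV = chamber_pressure(V_LV, e_lv, lv);

    // device flow source at the insertion node
    double p_sr = 0.0, dpsr = 0.0, Q_dev = 0.0;
    if (dev.active) {
      double tn = norm_time(t, dev.dt_act, hr);
      psr_eval(tn, g_act, pa_ref_, dev, p_sr, dpsr);
      Q_dev = dev.lam * dev.Csr * dpsr;
    }

    // open-circuit node pressures (no AV inflow yet)
    for (int i = 0; i < n_nodes; ++i) rhs[i] = 0.0;
    for (int k = 0; k < nt; ++k) rhs[term_node[k]] += P_term[k] / Rp[k];
    if (dev.active && device_node >= 0) rhs[device_node] += Q_dev;
    for (int i = 0; i < n_nodes; ++i) {
      double s = 0.0;
      for (int j = 0; j < n_nodes; ++j) s += Ginv(i, j) * rhs[j];
      pn[i] = s;
    }
    double P_open = pn[0];

    // aortic valve: gated Bernoulli law against the Thevenin equivalent
    // (P_open, R_eq) at the root; with inertance the flow is a state
    double Q_AV = 0.0, dQ_AV = 0.0;
    double D = P_LV - P_open;
    if (has_qav) {
      double q = y[4 + nt];
      if (s_AV <= S_FLOOR) {
        Q_AV = q;
        dQ_AV = -q / 1e-3;  // closed valve: flow relaxes to zero
      } else {
        // the quadratic drag uses an orifice floor: full closure is
        // enforced by the gated branch above, and capping Bq/sf^2 at 1e-2
        // keeps the closing transient integrable at the fixed 0.1 ms step
        double sf = std::max(s_AV, std::sqrt(av.Bq / 1e-2));
        Q_AV = q;
        dQ_AV = (D - R_eq_root * q -
                 av.Bq / (sf * sf) * q * std::fabs(q)) / av.L;
      }
    } else if (s_AV > S_FLOOR) {
      double Beff = av.Bq / (s_AV * s_AV);
      double disc = R_eq_root * R_eq_root + 4.0 * Beff * std::fabs(D);
      double rt = std::sqrt(disc);
      Q_AV = (D >= 0.0) ? (-R_eq_root + rt) / (2.0 * Beff)
                        : ( R_eq_root - rt) / (2.0 * Beff);
    }
    for (int i = 0; i < n_nodes; ++i) pn[i] += zcol[i] * Q_AV;
    double P_ao = pn[0];

    // mitral valve: direct Bernoulli between LA and LV
    double Q_MV = 0.0;
    double dpm = P_LA - P_LV;
    if (s_MV > S_FLOOR) {
      double q = s_MV * std::sqrt(std::fabs(dpm) / mv.Bq);
      Q_MV = (dpm >= 0.0) ? q : -q;
    }

    // venous node (algebraic, no storage)
    double num = P_LA / R_ven, den = 1.0 / R_ven + sum_invRd;
    for (int k = 0; k < nt; ++k) num += P_term[k] / Rd[k];
    double P_ven = num / den;

    // valve state dynamics (cannot leave [0,1] by construction)
    double dpa = P_LV - P_ao;
    dy[2] = (dpm > 0.0) ? (1.0 - s_MV) * mv.Kopen * dpm : s_MV * mv.Kclose * dpm;
    dy[3] = (dpa > 0.0) ? (1.0 - s_AV) * av.Kopen * dpa : s_AV * av.Kclose * dpa;

    dy[0] = (P_ven - P_LA) / R_ven - Q_MV;
    dy[1] = Q_MV - Q_AV;
    if (has_qav) dy[4 + nt] = dQ_AV;
    for (int k = 0; k < nt; ++k) {
      double Q_in = (pn[term_node[k]] - P_term[k]) / Rp[k];
      double Q_out = (P_term[k] - P_ven) / Rd[k];
      dy[4 + k] = (Q_in - Q_out) / Cc[k];
      if (aux) { aux->Q_br[k] = Q_in; aux->P_br[k] = pn[term_node[k]]; }
    }

    if (aux) {
      aux->P_LA = P_LA; aux->P_LV = P_LV; aux->P_ao = P_ao;
      aux->Q_MV = Q_MV; aux->Q_AV = Q_AV; aux->P_ven = P_ven;
      aux->p_sr = p_sr; aux->Q_dev = Q_dev;
      aux->e_LA = e_la; aux->e_LV = e_lv;
    }
    last_P_ao_ = P_ao;
  }

  mutable double last_P_ao_;
  double pa_ref_;
};

Chamber as_chamber(const NumericVector& v) {
  Chamber c; c.Emax = v[0]; c.V0 = v[1]; c.A = v[2]; c.B = v[3];
  c.t_onset = v[4]; c.t_sys = v[5];
  c.rise = (v.size() > 6) ? v[6] : 0.5;
  return c;
}

Valve as_valve(const NumericVector& v) {
  Valve w; w.Kopen = v[0]; w.Kclose = v[1]; w.Bq = v[2];
  w.L = (v.size() > 3) ? v[3] : 0.0;
  return w;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix sim_core(List net, List chambers, List valves, List device,
                       NumericVector state0, double hr, double dt,
                       int n_cycles, int record_stride) {
  Model m;
  m.Ginv = as<NumericMatrix>(net["Ginv"]);
  m.n_nodes = m.Ginv.nrow();
  IntegerVector tn = net["term_node"];
  m.nt = tn.size();
  m.term_node.assign(tn.begin(), tn.end());
  NumericVector Rp = net["Rp"], Cc = net["C"], Rd = net["Rd"];
  m.Rp.assign(Rp.begin(), Rp.end());
  m.Cc.assign(Cc.begin(), Cc.end());
  m.Rd.assign(Rd.begin(), Rd.end());
  m.R_ven = as<double>(net["R_ven"]);
  m.device_node = as<int>(net["device_node"]);
  m.sum_invRd = 0.0;
  for (int k = 0; k < m.nt; ++k) m.sum_invRd += 1.0 / m.Rd[k];
  m.zcol.resize(m.n_nodes);
  for (int i = 0; i < m.n_nodes; ++i) m.zcol[i] = m.Ginv(i, 0);
  m.R_eq_root = m.zcol[0];

  m.la = as_chamber(chambers["la"]);
  m.lv = as_chamber(chambers["lv"]);
  m.mv = as_valve(valves["mv"]);
  m.av = as_valve(valves["av"]);

  m.dev.active = as<bool>(device["active"]);
  if (m.dev.active) {
    m.dev.lam = as<double>(device["lambda"]);
    m.dev.Csr = as<double>(device["C_sr"]);
    m.dev.k1 = as<double>(device["k1"]);
    m.dev.k2 = as<double>(device["k2"]);
    m.dev.t_on = as<double>(device["t_on"]);
    m.dev.t_off = as<double>(device["t_off"]);
    m.dev.dt_act = as<double>(device["dt_act"]);
    m.dev.p_act = as<double>(device["p_act"]);
    NumericVector a = device["coeffs"];
    m.dev.a1 = a[0]; m.dev.a2 = a[1]; m.dev.a3 = a[2];
    m.dev.a4 = a[3]; m.dev.a5 = a[4];
    m.pa_ref_ = as<double>(device["pa_ref0"]);
    m.g_act = clamp_gain(m.dev.a1 * m.pa_ref_ * m.pa_ref_ +
                         m.dev.a2 * m.pa_ref_ + m.dev.a3 * m.dev.p_act +
                         m.dev.a4 + m.dev.a5 * m.pa_ref_ * m.dev.p_act);
  } else {
    m.dev = Device{false, 0, 0, 1, 1, 0.1, 0.2, 0, 0, 0, 0, 0, 0, 0};
    m.pa_ref_ = 0.0;
    m.g_act = 0.0;
  }

  m.hr = hr;
  m.T = 60.0 / hr;
  m.has_qav = m.av.L > 0;
  m.rhs.resize(m.n_nodes);
  m.pn.resize(m.n_nodes);

  int ns = 4 + m.nt + (m.has_qav ? 1 : 0);
  if (state0.size() != ns) stop("state vector has wrong length");

  double T = m.T;
  long steps_per_cycle = std::lround(T / dt);
  long n_steps = steps_per_cycle * n_cycles;
  long n_rec = n_steps / record_stride + 1;

  // columns: time, states, P_LA, P_LV, P_ao, Q_MV, Q_AV, P_ven,
  //          Q_br x nt, P_br x nt, p_sr, Q_dev, V_dev, e_LA, e_LV
  int ncol = 1 + ns + 6 + 2 * m.nt + 5;
  NumericMatrix out(n_rec, ncol);

  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), yt(ns);
  Model::Aux aux;
  aux.Q_br.resize(m.nt);
  aux.P_br.resize(m.nt);

  double pa_sum = 0.0;
  long rec_i = 0;

  auto record = [&](double t) {
    m.deriv(t, y.data(), k1.data(), &aux);
    int c = 0;
    out(rec_i, c++) = t;
    for (int i = 0; i < ns; ++i) out(rec_i, c++) = y[i];
    out(rec_i, c++) = aux.P_LA; out(rec_i, c++) = aux.P_LV;
    out(rec_i, c++) = aux.P_ao; out(rec_i, c++) = aux.Q_MV;
    out(rec_i, c++) = aux.Q_AV; out(rec_i, c++) = aux.P_ven;
    for (int k = 0; k < m.nt; ++k) out(rec_i, c++) = aux.Q_br[k];
    for (int k = 0; k < m.nt; ++k) out(rec_i, c++) = aux.P_br[k];
    out(rec_i, c++) = aux.p_sr;
    out(rec_i, c++) = aux.Q_dev;
    out(rec_i, c++) = -m.dev.lam * m.dev.Csr * aux.p_sr;  // stored volume (rel.)
    out(rec_i, c++) = aux.e_LA;
    out(rec_i, c++) = aux.e_LV;
    ++rec_i;
  };

  record(0.0);

  for (long step = 0; step < n_steps; ++step) {
    double t = step * dt;

    m.deriv(t, y.data(), k1.data(), nullptr);
    pa_sum += m.last_P_ao_;
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    m.deriv(t + 0.5 * dt, yt.data(), k2.data(), nullptr);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    m.deriv(t + 0.5 * dt, yt.data(), k3.data(), nullptr);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * k3[i];
    m.deriv(t + dt, yt.data(), k4.data(), nullptr);
    for (int i = 0; i < ns; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if ((step + 1) % 1000 == 0) {
      for (int i = 0; i < ns; ++i)
        if (!std::isfinite(y[i]))
          stop("simulation diverged (non-finite state) at t = %f s",
               (step + 1) * dt);
    }

    // refresh the device gain from the completed cycle's mean root pressure
    if ((step + 1) % steps_per_cycle == 0) {
      double pa_mean = pa_sum / steps_per_cycle;
      pa_sum = 0.0;
      if (m.dev.active) {
        m.pa_ref_ = pa_mean;
        m.g_act = clamp_gain(m.dev.a1 * pa_mean * pa_mean +
                             m.dev.a2 * pa_mean + m.dev.a3 * m.dev.p_act +
                             m.dev.a4 + m.dev.a5 * pa_mean * m.dev.p_act);
      }
    }

    if ((step + 1) % record_stride == 0) record((step + 1) * dt);
  }

  return out;
}

// Single derivative evaluation (used by tests and by assemble()'s R surface).
// [[Rcpp::export]]
List sim_deriv(List net, List chambers, List valves, List device,
               NumericVector state, double t, double hr, double g_act,
               double pa_ref) {
  Model m;
  m.Ginv = as<NumericMatrix>(net["Ginv"]);
  m.n_nodes = m.Ginv.nrow();
  IntegerVector tn = net["term_node"];
  m.nt = tn.size();
  m.term_node.assign(tn.begin(), tn.end());
  NumericVector Rp = net["Rp"], Cc = net["C"], Rd = net["Rd"];
  m.Rp.assign(Rp.begin(), Rp.end());
  m.Cc.assign(Cc.begin(), Cc.end());
  m.Rd.assign(Rd.begin(), Rd.end());
  m.R_ven = as<double>(net["R_ven"]);
  m.device_node = as<int>(net["device_node"]);
  m.sum_invRd = 0.0;
  for (int k = 0; k < m.nt; ++k) m.sum_invRd += 1.0 / m.Rd[k];
  m.zcol.resize(m.n_nodes);
  for (int i = 0; i < m.n_nodes; ++i) m.zcol[i] = m.Ginv(i, 0);
  m.R_eq_root = m.zcol[0];
  m.la = as_chamber(chambers["la"]);
  m.lv = as_chamber(chambers["lv"]);
  m.mv = as_valve(valves["mv"]);
  m.av = as_valve(valves["av"]);
  m.dev.active = as<bool>(device["active"]);
  if (m.dev.active) {
    m.dev.lam = as<double>(device["lambda"]);
    m.dev.Csr = as<double>(device["C_sr"]);
    m.dev.k1 = as<double>(device["k1"]);
    m.dev.k2 = as<double>(device["k2"]);
    m.dev.t_on = as<double>(device["t_on"]);
    m.dev.t_off = as<double>(device["t_off"]);
    m.dev.dt_act = as<double>(device["dt_act"]);
    m.dev.p_act = as<double>(device["p_act"]);
    NumericVector a = device["coeffs"];
    m.dev.a1 = a[0]; m.dev.a2 = a[1]; m.dev.a3 = a[2];
    m.dev.a4 = a[3]; m.dev.a5 = a[4];
  } else {
    m.dev = Device{false, 0, 0, 1, 1, 0.1, 0.2, 0, 0, 0, 0, 0, 0, 0};
  }
  m.g_act = g_act;
  m.pa_ref_ = pa_ref;
  m.hr = hr;
  m.T = 60.0 / hr;
  m.has_qav = m.av.L > 0;
  m.rhs.resize(m.n_nodes);
  m.pn.resize(m.n_nodes);

  int ns = 4 + m.nt + (m.has_qav ? 1 : 0);
  if (state.size() != ns) stop("state vector has wrong length");
  std::vector<double> y(state.begin(), state.end()), dy(ns);
  Model::Aux aux;
  aux.Q_br.resize(m.nt);
  aux.P_br.resize(m.nt);
  m.deriv(t, y.data(), dy.data(), &aux);

  return List::create(
    _["dstate"] = NumericVector(dy.begin(), dy.end()),
    _["P_LA"] = aux.P_LA, _["P_LV"] = aux.P_LV, _["P_ao"] = aux.P_ao,
    _["Q_MV"] = aux.Q_MV, _["Q_AV"] = aux.Q_AV, _["P_ven"] = aux.P_ven,
    _["Q_br"] = NumericVector(aux.Q_br.begin(), aux.Q_br.end()),
    _["P_br"] = NumericVector(aux.P_br.begin(), aux.P_br.end()),
    _["p_sr"] = aux.p_sr, _["Q_dev"] = aux.Q_dev);
}
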