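#include <Rcpp.h>
using namespace Rcpp;

// Scaled Boltzmann equilibrium gate x_inf(V) = A / (1 + exp(-k (V - V*)))
static inline double gate_inf(double V, double A, double k, double Vs) {
  return A / (1.0 + std::exp(-k * (V - Vs)));
}

// Piecewise-constant theta_inf(V): value beta[j] on [edge[j], edge[j+1]),
// clamped to the first/last value outside the covered range.
static inline double theta_inf_c(double V, const std::vector<double> &edges,
                                 const std::vector<double> &beta) {
  if (beta.empty()) return 0.0;
  const int nb = beta.size();
  if (V < edges[1]) return beta[0];
  for (int j = 1; j < nb; ++j) {
    if (V < edges[j + 1]) return beta[j];
  }
  return beta[nb - 1];
}

struct GifPars {
  double C, gl, El, Vt, DV, lambda0, Vreset, Tref;
  std::vector<double> eta_w, eta_dec, gam_w, gam_dec;
  double gA, gK, EK, tauh;
  double mA, mk, mV, hA, hk, hV, nA, nk, nV;
  std::vector<double> th_beta, th_edges;
  double tau_theta;
  bool has_theta;
};

static GifPars unpack_pars(const List &pars, double dt) {
  GifPars p;
  p.C = as<double>(pars["C"]);
  p.gl = as<double>(pars["g_l"]);
  p.El = as<double>(pars["E_l"]);
  p.Vt = as<double>(pars["V_T_star"]);
  p.DV = as<double>(pars["DeltaV"]);
  p.lambda0 = as<double>(pars["lambda_0"]);
  p.Vreset = as<double>(pars["V_reset"]);
  p.Tref = as<double>(pars["T_ref"]);
  NumericVector ew = pars["eta_w"], et = pars["eta_tau"];
  NumericVector gw = pars["gamma_w"], gt = pars["gamma_tau"];
  for (int j = 0; j < ew.size(); ++j) {
    p.eta_w.push_back(ew[j]);
    p.eta_dec.push_back(std::exp(-dt / et[j]));
  }
  for (int j = 0; j < gw.size(); ++j) {
    p.gam_w.push_back(gw[j]);
    p.gam_dec.push_back(std::exp(-dt / gt[j]));
  }
  p.gA = as<double>(pars["g_A"]);
  p.gK = as<double>(pars["g_K"]);
  p.EK = as<double>(pars["E_K"]);
  p.tauh = as<double>(pars["tau_h"]);
  NumericVector m = pars["m_gate"], h = pars["h_gate"], n = pars["n_gate"];
  p.mA = m[0]; p.mk = m[1]; p.mV = m[2];
  p.hA = h[0]; p.hk = h[1]; p.hV = h[2];
  p.nA = n[0]; p.nk = n[1]; p.nV = n[2];
  NumericVector tb = pars["theta_beta"];
  p.has_theta = tb.size() > 0;
  if (p.has_theta) {
    NumericVector te = pars["theta_edges"];
    for (int j = 0; j < tb.size(); ++j) p.th_beta.push_back(tb[j]);
    for (int j = 0; j < te.size(); ++j) p.th_edges.push_back(te[j]);
    p.tau_theta = as<double>(pars["tau_theta"]);
  } else {
    p.tau_theta = 1.0;
  }
  return p;
}

// Euler integration of the GIF / aGIF / iGIF subthreshold dynamics with
// escape-rate spiking.  In forced mode the supplied spike times are imposed
// and the stochastic rule is bypassed (used to reconstruct the subthreshold
// voltage with spikes clamped to the data).
// [[Rcpp::export]]
List sim_gif_cpp(List pars, NumericVector I, double dt, double V0,
                 bool stochastic, NumericVector forced_spike_times,
                 bool record) {
  GifPars p = unpack_pars(pars, dt);
  const int nt = I.size();
  const int nref = (int)std::lround(p.Tref / dt);
  const int J = p.eta_w.size(), Jg = p.gam_w.size();

  std::vector<double> E(J, 0.0), G(Jg, 0.0);
  bool spiked_prev = false;

  const double hdec = std::exp(-dt / p.tauh);
  const double thdec = std::exp(-dt / p.tau_theta);

  double V = V0;
  double h = gate_inf(V0, p.hA, p.hk, p.hV);
  double theta = p.has_theta ? theta_inf_c(V0, p.th_edges, p.th_beta) : 0.0;

  std::vector<bool> forced(stochastic ? 0 : nt, false);
  if (!stochastic) {
    for (int i = 0; i < forced_spike_times.size(); ++i) {
      int k = (int)std::lround(forced_spike_times[i] / dt);
      if (k >= 0 && k < nt) forced[k] = true;
    }
  }

  NumericVector Vout(record ? nt : 0), hout(record ? nt : 0),
      etaout(record ? nt : 0), gamout(record ? nt : 0),
      thout(record && p.has_theta ? nt : 0);
  std::vector<double> spikes;
  int refrac = 0;

  for (int k = 0; k < nt; ++k) {
    // spike-triggered filter states: sum_j w_j exp(-(k - s) dt / tau_j) over s < k
    for (int j = 0; j < J; ++j)
      E[j] = p.eta_dec[j] * (E[j] + (spiked_prev ? p.eta_w[j] : 0.0));
    for (int j = 0; j < Jg; ++j)
      G[j] = p.gam_dec[j] * (G[j] + (spiked_prev ? p.gam_w[j] : 0.0));
    spiked_prev = false;

    double eta_sum = 0.0, gam_sum = 0.0;
    for (int j = 0; j < J; ++j) eta_sum += E[j];
    for (int j = 0; j < Jg; ++j) gam_sum += G[j];

    if (record) {
      Vout[k] = V; hout[k] = h; etaout[k] = eta_sum; gamout[k] = gam_sum;
      if (p.has_theta) thout[k] = theta;
    }

    if (!std::isfinite(V))
      stop("non-finite voltage at step %d", k + 1);

    // spiking rule; one uniform is consumed per step in stochastic mode
    // (also during the refractory period) so that RNG streams stay
    // aligned across conditions that share a seed
    bool spike = false;
    if (stochastic) {
      double draw = unif_rand();
      if (refrac == 0) {
        double u = (V - p.Vt - gam_sum + theta) / p.DV;
        if (u > 700.0) u = 700.0;
        double lam = p.lambda0 * std::exp(u);       // Hz
        double prob = -std::expm1(-lam * dt * 1e-3);
        if (draw < prob) spike = true;
      }
    } else if (refrac == 0 && forced[k]) {
      spike = true;
    }

    if (spike) {
      spikes.push_back(k * dt);
      spiked_prev = true;
      refrac = nref;
      V = p.Vreset;
    }

    // subthreshold Euler step (voltage held at V_reset while refractory)
    double m = gate_inf(V, p.mA, p.mk, p.mV);
    double n = gate_inf(V, p.nA, p.nk, p.nV);
    double IA = p.gA * m * h * (V - p.EK);
    double IK = p.gK * n * (V - p.EK);
    double hinf = gate_inf(V, p.hA, p.hk, p.hV);

    if (refrac > 0) {
      --refrac;
      V = p.Vreset;
    } else {
      V += dt / p.C * (-p.gl * (V - p.El) - IA - IK - eta_sum + I[k]);
    }
    h = hinf + (h - hinf) * hdec;
    if (p.has_theta) {
      double thinf = theta_inf_c(V, p.th_edges, p.th_beta);
      theta = thinf + (theta - thinf) * thdec;
    }
  }

  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["V"] = Vout, _["h"] = hout, _["eta_sum"] = etaout,
      _["gamma_sum"] = gamout, _["theta"] = thout);
  return out;
}

// h-gate trajectory implied by an observed voltage trace (exponential update
// at the recording time step); used to build the I_A regressor when fitting.
// [[Rcpp::export]]
NumericVector h_from_v_cpp(NumericVector V, double dt, double tauh,
                           double hA, double hk, double hV) {
  const int nt = V.size();
  NumericVector h(nt);
  const double hdec = std::exp(-dt / tauh);
  double hs = gate_inf(V[0], hA, hk, hV);
  for (int k = 0; k < nt; ++k) {
    h[k] = hs;
    double hinf = gate_inf(V[k], hA, hk, hV);
    hs = hinf + (hs - hinf) * hdec;
  }
  return h;
}

// Exponential-basis regressors driven by a spike train:
// X[k, j] = sum_{s < k} exp(-(k - s) dt / tau_j) for spike steps s.
// [[Rcpp::export]]
NumericMatrix spike_basis_cpp(NumericVector spike_times, NumericVector tau,
                              double dt, int nt) {
  const int J = tau.size();
  NumericMatrix X(nt, J);
  std::vector<double> dec(J), st(J, 0.0);
  for (int j = 0; j < J; ++j) dec[j] = std::exp(-dt / tau[j]);
  std::vector<bool> sp(nt, false);
  for (int i = 0; i < spike_times.size(); ++i) {
    int k = (int)std::lround(spike_times[i] / dt);
    if (k >= 0 && k < nt) sp[k] = true;
  }
  bool prev = false;
  for (int k = 0; k < nt; ++k) {
    for (int j = 0; j < J; ++j) {
      st[j] = dec[j] * (st[j] + (prev ? 1.0 : 0.0));
      X(k, j) = st[j];
    }
    prev = sp[k];
  }
  return X;
}

// Low-pass filtered voltage-bin indicators for the iGIF threshold coupling:
// X[k, j] tracks 1[V in bin j] with time constant tau_theta.
// [[Rcpp::export]]
NumericMatrix theta_basis_cpp(NumericVector V, NumericVector edges,
                              double tau_theta, double dt) {
  const int nt = V.size();
  const int nb = edges.size() - 1;
  NumericMatrix X(nt, nb);
  const double dec = std::exp(-dt / tau_theta);
  std::vector<double> st(nb, 0.0);
  // initialize at the equilibrium for V[0]
  {
    int j0 = nb - 1;
    if (V[0] < edges[1]) j0 = 0;
    else for (int j = 1; j < nb; ++j) if (V[0] < edges[j + 1]) { j0 = j; break; }
    st[j0] = 1.0;
  }
  for (int k = 0; k < nt; ++k) {
    for (int j = 0; j < nb; ++j) X(k, j) = st[j];
    int jk = nb - 1;
    if (V[k] < edges[1]) jk = 0;
    else for (int j = 1; j < nb; ++j) if (V[k] < edges[j + 1]) { jk = j; break; }
    for (int j = 0; j < nb; ++j)
      st[j] = (j == jk ? 1.0 : 0.0) + (st[j] - (j == jk ? 1.0 : 0.0)) * dec;
  }
  return X;
}

// Nondimensional toy LIF with an inactivating potassium current.
// Time is in units of the membrane time constant; voltage in mV.
// [[Rcpp::export]]
List sim_toy_cpp(double El, double EK, double gA_eff, double tauh_eff,
                 NumericVector m_gate, NumericVector h_gate,
                 double Vt, double Vreset, NumericVector Vinj, double V0,
                 double dt, double noise_sd, bool record) {
  const int nt = Vinj.size();
  const double hdec = std::exp(-dt / tauh_eff);
  const double sq = std::sqrt(dt);
  double V = V0;
  double h = gate_inf(V0, h_gate[0], h_gate[1], h_gate[2]);
  NumericVector Vout(record ? nt : 0), hout(record ? nt : 0);
  std::vector<double> spikes;
  for (int k = 0; k < nt; ++k) {
    if (record) { Vout[k] = V; hout[k] = h; }
    if (V >= Vt) {
      spikes.push_back(k * dt);
      V = Vreset;
    }
    double m = gate_inf(V, m_gate[0], m_gate[1], m_gate[2]);
    double hinf = gate_inf(V, h_gate[0], h_gate[1], h_gate[2]);
    double dV = (El - V - gA_eff * m * h * (V - EK) + Vinj[k]) * dt;
    if (noise_sd > 0.0) dV += noise_sd * sq * norm_rand();
    V += dV;
    h = hinf + (h - hinf) * hdec;
  }
  double latency = spikes.empty() ? NA_REAL : spikes.front();
  return List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["latency"] = latency, _["V"] = Vout, _["h"] = hout);
}

// Population of GIF/aGIF neurons sharing one input trace, each with
// independent OU background noise and (optionally) conductance-based
// GABA synapses whose presynaptic arrival times are supplied per neuron.
// pars: one row per neuron with columns
//   C, g_l, E_l, V_T_star, DeltaV, V_reset, T_ref, g_A, g_K, E_K, tau_h
// eta_w / gamma_w: per-neuron filter weights (columns follow eta_tau / gamma_tau).
// [[Rcpp::export]]
List sim_population_cpp(NumericMatrix pars, NumericMatrix eta_w,
                        NumericVector eta_tau, NumericMatrix gamma_w,
                        NumericVector gamma_tau, NumericVector m_gate,
                        NumericVector h_gate, NumericVector n_gate,
                        NumericVector I, double dt,
                        double noise_sd, double noise_tau,
                        List presyn_arrivals, double syn_Erev,
                        double syn_gpeak, double syn_taur, double syn_taud,
                        double lambda0) {
  const int n = pars.nrow(), nt = I.size();
  const int J = eta_tau.size(), Jg = gamma_tau.size();
  std::vector<double> eta_dec(J), gam_dec(Jg);
  for (int j = 0; j < J; ++j) eta_dec[j] = std::exp(-dt / eta_tau[j]);
  for (int j = 0; j < Jg; ++j) gam_dec[j] = std::exp(-dt / gamma_tau[j]);

  // biexponential conductance: unit-peak normalization
  const double sstar = syn_taur * syn_taud / (syn_taud - syn_taur) *
                       std::log(syn_taud / syn_taur);
  const double norm = std::exp(-sstar / syn_taud) - std::exp(-sstar / syn_taur);
  const double gdecd = std::exp(-dt / syn_taud);
  const double gdecr = std::exp(-dt / syn_taur);

  const double ndec = noise_tau > 0 ? std::exp(-dt / noise_tau) : 0.0;
  const double ninn = noise_tau > 0 ? noise_sd * std::sqrt(1.0 - ndec * ndec)
                                    : noise_sd;

  List out(n);
  for (int i = 0; i < n; ++i) {
    const double Ci = pars(i, 0), gl = pars(i, 1), El = pars(i, 2),
                 Vt = pars(i, 3), DV = pars(i, 4), Vreset = pars(i, 5),
                 Tref = pars(i, 6), gA = pars(i, 7), gK = pars(i, 8),
                 EK = pars(i, 9), tauh = pars(i, 10);
    const int nref = (int)std::lround(Tref / dt);
    const double hdec = std::exp(-dt / tauh);

    std::vector<double> E(J, 0.0), G(Jg, 0.0);
    bool spiked_prev = false;
    double V = El, h = gate_inf(El, h_gate[0], h_gate[1], h_gate[2]);
    double noise = 0.0;
    if (noise_sd > 0.0) noise = noise_sd * norm_rand();
    double ga = 0.0, gb = 0.0; // decay / rise conductance states
    int refrac = 0;

    NumericVector arr = presyn_arrivals.size() > 0
                            ? as<NumericVector>(presyn_arrivals[i])
                            : NumericVector(0);
    int ai = 0;

    std::vector<double> spikes;
    for (int k = 0; k < nt; ++k) {
      for (int j = 0; j < J; ++j)
        E[j] = eta_dec[j] * (E[j] + (spiked_prev ? eta_w(i, j) : 0.0));
      for (int j = 0; j < Jg; ++j)
        G[j] = gam_dec[j] * (G[j] + (spiked_prev ? gamma_w(i, j) : 0.0));
      spiked_prev = false;

      double eta_sum = 0.0, gam_sum = 0.0;
      for (int j = 0; j < J; ++j) eta_sum += E[j];
      for (int j = 0; j < Jg; ++j) gam_sum += G[j];

      // register synaptic arrivals scheduled at or before this step
      double t = k * dt;
      while (ai < arr.size() && arr[ai] <= t + 0.5 * dt) {
        ga += syn_gpeak / norm;
        gb += syn_gpeak / norm;
        ++ai;
      }
      double gsyn = ga - gb;

      bool spike = false;
      double draw = unif_rand(); // consumed every step: keeps RNG streams
                                 // aligned across manipulated conditions
      if (refrac == 0) {
        double u = (V - Vt - gam_sum) / DV;
        if (u > 700.0) u = 700.0;
        double lam = lambda0 * std::exp(u);
        double prob = -std::expm1(-lam * dt * 1e-3);
        if (draw < prob) spike = true;
      }
      if (spike) {
        spikes.push_back(t);
        spiked_prev = true;
        refrac = nref;
        V = Vreset;
      }

      double m = gate_inf(V, m_gate[0], m_gate[1], m_gate[2]);
      double nn = gate_inf(V, n_gate[0], n_gate[1], n_gate[2]);
      double IA = gA * m * h * (V - EK);
      double IK = gK * nn * (V - EK);
      double hinf = gate_inf(V, h_gate[0], h_gate[1], h_gate[2]);

      if (refrac > 0) {
        --refrac;
        V = Vreset;
      } else {
        V += dt / Ci * (-gl * (V - El) - IA - IK - eta_sum -
                        gsyn * (V - syn_Erev) + I[k] + noise);
      }
      h = hinf + (h - hinf) * hdec;
      ga *= gdecd;
      gb *= gdecr;
      if (noise_sd > 0.0) noise = noise * ndec + ninn * norm_rand();
    }
    out[i] = NumericVector(spikes.begin(), spikes.end());
  }
  return out;
}
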