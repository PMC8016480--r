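// Fixed-step spiking-network engine.
//
// Integration scheme per engine step m (time t = m*dt .. (m+1)*dt):
//   1. apply external input spikes scheduled for step m and network spikes
//      emitted delay_steps earlier as impulses to synapse states;
//   2. compute the exact step-averaged synaptic conductances from the
//      post-impulse states (closed-form integral of the linear kinetics;
//      NMDA with the Mg block at the current postsynaptic voltage), sum
//      coupling currents and injected currents;
//   3. advance each enabled, non-refractory membrane by the exact
//      exponential solution with the current held constant; threshold
//      crossings are recorded as spikes at (m+1)*dt;
//   4. advance synapse states by their exact linear decay (matrix
//      exponential for the alpha synapse).
//
// Linear subsystems are therefore advanced exactly; the only first-order
// couplings are conductance-voltage (current frozen over a step) and the
// NMDA block.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NMDA_BETA = 0.062;   // per mV
static const double NMDA_GAMMA = 3.56;   // mM

// Arguments: neuron membrane arrays; synapse arrays (network plus external
// input synapses appended, pre = -1 for external, indices 0-based, kind
// 0 = alpha / 1 = exp / 2 = nmda); external spike events sorted by step;
// injected-current matrix (n_steps x n_driven) with target indices;
// engine configuration.
// [[Rcpp::export]]
List cx_engine_run(
    NumericVector C, NumericVector R, NumericVector V0, NumericVector Vth,
    NumericVector Vr, NumericVector t_ref, LogicalVector enabled,
    IntegerVector pre, IntegerVector post, IntegerVector kind,
    NumericVector g_bar, NumericVector reversal, IntegerVector sign_pm,
    NumericVector a_r, NumericVector a_d, NumericVector tau,
    NumericVector alpha, NumericVector mg,
    IntegerVector ev_step, IntegerVector ev_syn,
    NumericMatrix I_ext, IntegerVector driven,
    double dt, int n_steps, int delay_steps, int coupling_mode,
    IntegerVector record_v_idx) {

  const int nn = C.size();
  const int ns = pre.size();

  std::vector<double> V(nn), ref(nn, 0.0);
  for (int i = 0; i < nn; ++i) V[i] = V0[i];

  // synapse states
  std::vector<double> s(ns, 0.0), h(ns, 0.0);

  // precomputed per-synapse decay operators and exact step-average
  // operators: the coupling current uses the mean conductance over the
  // step, mean_s = Q11 s0 + Q12 h0 (alpha) or mean_s = Qe s0 (exp/NMDA),
  // which is the exact integral of the linear kinetics
  std::vector<double> M11(ns), M12(ns), M21(ns), M22(ns), dec(ns);
  std::vector<double> Q11(ns), Q12(ns), Qe(ns);
  for (int j = 0; j < ns; ++j) {
    if (kind[j] == 0) {
      double ar = a_r[j], ad = a_d[j];
      if (std::abs(ar - ad) < 1e-9 * ar) {
        double a = ar, E = std::exp(-a * dt);
        // repeated root: [s;h] -> E * [[1 + a dt, dt], [-a^2 dt, 1 - a dt]]
        M11[j] = E * (1 + a * dt); M12[j] = E * dt;
        M21[j] = -E * a * a * dt;  M22[j] = E * (1 - a * dt);
      } else {
        double E1 = std::exp(-ar * dt), E2 = std::exp(-ad * dt);
        double den = ad - ar;
        M11[j] = (ad * E1 - ar * E2) / den;
        M12[j] = (E1 - E2) / den;
        M21[j] = ar * ad * (E2 - E1) / den;
        M22[j] = (ad * E2 - ar * E1) / den;
      }
      // row 1 of A^{-1} (M - I) / dt for A = [[0,1],[-ar ad, -(ar+ad)]]
      double b = ar + ad, c = ar * ad;
      Q11[j] = (-b * (M11[j] - 1.0) - M21[j]) / (c * dt);
      Q12[j] = (-b * M12[j] - (M22[j] - 1.0)) / (c * dt);
    } else {
      dec[j] = std::exp(-dt / tau[j]);
      Qe[j] = tau[j] * (1.0 - dec[j]) / dt;
    }
  }

  // adjacency: synapses by presynaptic neuron
  std::vector<std::vector<int>> pre_syn(nn);
  for (int j = 0; j < ns; ++j) {
    if (pre[j] >= 0) pre_syn[pre[j]].push_back(j);
  }

  // ring buffer of spiking neurons per step for the synaptic delay
  const int D = delay_steps;
  std::vector<std::vector<int>> buf(D);

  // recording
  std::vector<int> spike_neuron, spike_step;
  const int nrec = record_v_idx.size();
  NumericMatrix Vrec(nrec > 0 ? n_steps : 0, nrec);

  const int n_ev = ev_step.size();
  int ev_ptr = 0;
  const int n_driven = driven.size();

  std::vector<double> I(nn);

  for (int m = 0; m < n_steps; ++m) {
    // 1. impulses: external events for this step
    while (ev_ptr < n_ev && ev_step[ev_ptr] == m) {
      int j = ev_syn[ev_ptr];
      if (kind[j] == 0) h[j] += a_r[j] * a_d[j];
      else if (kind[j] == 1) s[j] += 1.0;
      else s[j] = 1.0 - (1.0 - s[j]) * std::exp(-alpha[j]);
      ++ev_ptr;
    }
    //    network spikes emitted delay_steps ago
    std::vector<int>& slot = buf[m % D];
    for (size_t q = 0; q < slot.size(); ++q) {
      int i = slot[q];
      const std::vector<int>& out = pre_syn[i];
      for (size_t k = 0; k < out.size(); ++k) {
        int j = out[k];
        if (kind[j] == 0) h[j] += a_r[j] * a_d[j];
        else if (kind[j] == 1) s[j] += 1.0;
        else s[j] = 1.0 - (1.0 - s[j]) * std::exp(-alpha[j]);
      }
    }
    slot.clear();

    // 2. currents
    std::fill(I.begin(), I.end(), 0.0);
    for (int j = 0; j < ns; ++j) {
      if (pre[j] >= 0 && !enabled[pre[j]]) continue; // silenced source
      double mean_s = (kind[j] == 0) ? (Q11[j] * s[j] + Q12[j] * h[j])
                                     : (Qe[j] * s[j]);
      double g = g_bar[j] * mean_s;
      if (g == 0.0) continue;
      int p_ = post[j];
      if (kind[j] == 2) {
        g /= 1.0 + mg[j] * std::exp(-NMDA_BETA * V[p_] * 1e3) / NMDA_GAMMA;
      }
      if (coupling_mode == 0) I[p_] += g * (reversal[j] - V[p_]);
      else I[p_] += sign_pm[j] * g;
    }
    for (int k = 0; k < n_driven; ++k) I[driven[k]] += I_ext(m, k);

    // 3. membranes
    for (int i = 0; i < nn; ++i) {
      if (!enabled[i]) continue;
      if (ref[i] > 1e-12) { V[i] = Vr[i]; ref[i] -= dt; continue; }
      double vinf = V0[i] + R[i] * I[i];
      double vn = vinf + (V[i] - vinf) * std::exp(-dt / (R[i] * C[i]));
      if (!std::isfinite(vn)) {
        stop("NaN/Inf membrane state: neuron index %d at step %d", i + 1, m + 1);
      }
      if (vn >= Vth[i]) {
        V[i] = Vr[i]; ref[i] = t_ref[i];
        spike_neuron.push_back(i + 1);  // 1-based for R
        spike_step.push_back(m + 1);
        buf[m % D].push_back(i);        // delivered at step m + D
      } else {
        V[i] = vn;
      }
    }
    if (nrec > 0) {
      for (int k = 0; k < nrec; ++k) Vrec(m, k) = V[record_v_idx[k]];
    }

    // 4. synapse decay
    for (int j = 0; j < ns; ++j) {
      if (kind[j] == 0) {
        double s0 = s[j], h0 = h[j];
        s[j] = M11[j] * s0 + M12[j] * h0;
        h[j] = M21[j] * s0 + M22[j] * h0;
      } else {
        s[j] *= dec[j];
      }
    }
  }

  return List::create(
    _["spike_neuron"] = wrap(spike_neuron),
    _["spike_step"] = wrap(spike_step),
    _["V"] = Vrec);
}
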