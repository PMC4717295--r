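// Exponential integrate-and-fire network integrator.
//
// Cortical neurons are single-compartment EIF somata; V1 excitatory cells
// may carry a passive 5-compartment dendritic chain (6 compartments in
// total) attached to the soma.  Synapses are conductance-based (AMPA-like
// excitatory, GABA-A-like inhibitory) with exponential decay, and land on a
// designated compartment (0 = soma, 1..5 = dendrite, proximal to distal).
// Input-layer neurons are inhomogeneous Poisson sources: baseline rate
// before stimulus onset, baseline + stimulus rate afterwards.
//
// Integration: forward Euler at dt (default 0.1 ms) with exponentially
// decayed conductances; the EIF spike term is clamped to avoid overflow and
// a crossing of v_peak triggers reset + refractory clamp.  Uses R's RNG so
// runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List eif_simulate_cpp(int n_cortical,
                      IntegerVector n_comp,     // 1 or 6 per cortical neuron
                      IntegerVector in_ptr,     // CSR over input neurons
                      IntegerVector in_post,
                      NumericVector in_w,
                      IntegerVector in_comp,
                      IntegerVector c_ptr,      // CSR over cortical neurons
                      IntegerVector c_post,
                      NumericVector c_w,
                      IntegerVector c_inh,
                      IntegerVector c_comp,
                      NumericVector rate_base_hz,
                      NumericVector rate_stim_hz,
                      List par) {
  const double dt      = as<double>(par["dt_ms"]);
  const double t_total = as<double>(par["t_total_ms"]);
  const double t_stim  = as<double>(par["t_stim_on_ms"]);
  const double t_rec   = as<double>(par["t_record_from_ms"]);
  const double C       = as<double>(par["C_pF"]);
  const double gL      = as<double>(par["gL_nS"]);
  const double EL      = as<double>(par["EL_mV"]);
  const double DeltaT  = as<double>(par["DeltaT_mV"]);
  const double VT      = as<double>(par["VT_mV"]);
  const double Vreset  = as<double>(par["Vreset_mV"]);
  const double Vpeak   = as<double>(par["Vpeak_mV"]);
  const double t_ref   = as<double>(par["t_ref_ms"]);
  const double tau_e   = as<double>(par["tau_e_ms"]);
  const double tau_i   = as<double>(par["tau_i_ms"]);
  const double Ee      = as<double>(par["Ee_mV"]);
  const double Ei      = as<double>(par["Ei_mV"]);
  const double g_ax    = as<double>(par["g_ax_nS"]);
  const double C_d     = as<double>(par["C_d_pF"]);
  const double gL_d    = as<double>(par["gL_d_nS"]);
  const double I_const = as<double>(par["I_const_pA"]);  // test/probe drive

  const int n_input = rate_base_hz.size();
  const int n_steps = (int)std::lround(t_total / dt);
  const int ref_steps = (int)std::lround(t_ref / dt);
  const double de = std::exp(-dt / tau_e);
  const double di = std::exp(-dt / tau_i);

  // dendrite bookkeeping: neurons with n_comp == 6 get 5 chained passive
  // compartments stored contiguously
  std::vector<int> dend_off(n_cortical, -1);
  int n_dend = 0;
  for (int i = 0; i < n_cortical; ++i)
    if (n_comp[i] == 6) { dend_off[i] = n_dend; n_dend += 5; }

  std::vector<double> V(n_cortical, EL), ge0(n_cortical, 0.0), gi0(n_cortical, 0.0);
  std::vector<double> Vd(n_dend, EL), ged(n_dend, 0.0), gid(n_dend, 0.0);
  std::vector<int> refr(n_cortical, 0);
  std::vector<int> counts(n_cortical, 0);
  std::vector<int> spiking; spiking.reserve(256);
  long input_spikes_total = 0, input_spikes_rec = 0;
  long n_spikes_total = 0;

  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const bool stim_on = t >= t_stim;
    const bool recording = t >= t_rec;

    // conductance decay
    for (int i = 0; i < n_cortical; ++i) { ge0[i] *= de; gi0[i] *= di; }
    for (int j = 0; j < n_dend; ++j) { ged[j] *= de; gid[j] *= di; }

    // Poisson input layer
    for (int j = 0; j < n_input; ++j) {
      double rate = stim_on ? rate_stim_hz[j] : rate_base_hz[j];
      if (rate <= 0.0) continue;
      if (unif_rand() < rate * dt * 1e-3) {
        ++input_spikes_total;
        if (recording) ++input_spikes_rec;
        for (int s = in_ptr[j]; s < in_ptr[j + 1]; ++s) {
          int p = in_post[s], cmp = in_comp[s];
          if (cmp > 0 && dend_off[p] >= 0) ged[dend_off[p] + cmp - 1] += in_w[s];
          else ge0[p] += in_w[s];
        }
      }
    }

    // passive dendritic chain (compartment 1 couples to the soma)
    for (int i = 0; i < n_cortical; ++i) {
      int off = dend_off[i];
      if (off < 0) continue;
      double Vnew[5];
      for (int cmp = 0; cmp < 5; ++cmp) {
        int j = off + cmp;
        double Vprev = (cmp == 0) ? V[i] : Vd[j - 1];
        double I = gL_d * (EL - Vd[j]) + g_ax * (Vprev - Vd[j]);
        if (cmp < 4) I += g_ax * (Vd[j + 1] - Vd[j]);
        I += ged[j] * (Ee - Vd[j]) + gid[j] * (Ei - Vd[j]);
        Vnew[cmp] = Vd[j] + dt * I / C_d;
      }
      for (int cmp = 0; cmp < 5; ++cmp) Vd[off + cmp] = Vnew[cmp];
    }

    // somata
    spiking.clear();
    for (int i = 0; i < n_cortical; ++i) {
      if (refr[i] > 0) { --refr[i]; V[i] = Vreset; continue; }
      double ex_arg = (V[i] - VT) / DeltaT;
      if (ex_arg > 20.0) ex_arg = 20.0;   // clamp the spike term
      double I = -gL * (V[i] - EL) + gL * DeltaT * std::exp(ex_arg)
               + ge0[i] * (Ee - V[i]) + gi0[i] * (Ei - V[i]) + I_const;
      if (dend_off[i] >= 0) I += g_ax * (Vd[dend_off[i]] - V[i]);
      V[i] += dt * I / C;
      if (V[i] >= Vpeak) {
        V[i] = Vreset;
        refr[i] = ref_steps;
        ++n_spikes_total;
        if (recording) ++counts[i];
        spiking.push_back(i);
      }
    }

    // propagate cortical spikes
    for (size_t k = 0; k < spiking.size(); ++k) {
      int i = spiking[k];
      for (int s = c_ptr[i]; s < c_ptr[i + 1]; ++s) {
        int p = c_post[s], cmp = c_comp[s];
        if (c_inh[s]) {
          if (cmp > 0 && dend_off[p] >= 0) gid[dend_off[p] + cmp - 1] += c_w[s];
          else gi0[p] += c_w[s];
        } else {
          if (cmp > 0 && dend_off[p] >= 0) ged[dend_off[p] + cmp - 1] += c_w[s];
          else ge0[p] += c_w[s];
        }
      }
    }

    // numerical-stability guard
    if (step % 500 == 0) {
      for (int i = 0; i < n_cortical; ++i)
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential in neuron %d at t = %.2f ms",
               i + 1, t);
    }
  }

  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["input_spikes_recorded"] = (double)input_spikes_rec,
                      _["input_spikes_total"] = (double)input_spikes_total,
                      _["spikes_total"] = (double)n_spikes_total);
}
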