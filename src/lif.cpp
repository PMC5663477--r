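#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of one 50 ms stimulation trial of the
// conductance-based LIF network. Conductances are stored in units of each
// target neuron's leak conductance, so the membrane equation is
//   dV/dt = (ge*(Ee - V) + gi*(Ei - V) - (V - Vrest)) / taum.
//
// Presynaptic units are indexed 0..(n_l4-1) for the L4 spike sources and
// n_l4..(n_l4+n_neurons-1) for the L2/3 neurons. Synapses are in CSR layout
// over presynaptic units. Each presynaptic spike gates every outgoing
// synapse through an independent Bernoulli release draw (R's RNG, so runs
// are reproducible under set.seed).
//
// [[Rcpp::export]]
IntegerVector lif_trial_cpp(int n_neurons, int n_l4,
                            IntegerVector syn_ptr, IntegerVector syn_post,
                            NumericVector syn_g, NumericVector syn_prel,
                            IntegerVector syn_inh,
                            IntegerVector l4_spike_step,
                            NumericVector vrest, NumericVector vth,
                            NumericVector taum, NumericVector tref,
                            NumericVector tausyn_e, NumericVector tausyn_i,
                            NumericVector erev_e, NumericVector erev_i,
                            double dt, int n_steps) {
  std::vector<double> V(n_neurons), ge(n_neurons, 0.0), gi(n_neurons, 0.0);
  std::vector<int> ref_until(n_neurons, -1);
  IntegerVector n_spikes(n_neurons);
  for (int i = 0; i < n_neurons; ++i) V[i] = vrest[i];

  // L4 spikes bucketed by integration step
  std::vector< std::vector<int> > l4_by_step(n_steps);
  for (int u = 0; u < n_l4; ++u) {
    int s = l4_spike_step[u];
    if (s >= 0 && s < n_steps) l4_by_step[s].push_back(u);
  }

  for (int t = 0; t < n_steps; ++t) {
    // deliver L4 volley spikes scheduled for this step
    const std::vector<int>& arrivals = l4_by_step[t];
    for (size_t k = 0; k < arrivals.size(); ++k) {
      int u = arrivals[k];
      for (int j = syn_ptr[u]; j < syn_ptr[u + 1]; ++j) {
        if (unif_rand() < syn_prel[j]) {
          if (syn_inh[j]) gi[syn_post[j]] += syn_g[j];
          else            ge[syn_post[j]] += syn_g[j];
        }
      }
    }

    // membrane update, spike detection, recurrent propagation
    for (int i = 0; i < n_neurons; ++i) {
      if (t < ref_until[i]) {
        V[i] = vrest[i];
      } else {
        double dv = (ge[i] * (erev_e[i] - V[i]) + gi[i] * (erev_i[i] - V[i]) -
                     (V[i] - vrest[i])) / taum[i];
        V[i] += dt * dv;
        if (V[i] >= vth[i]) {
          n_spikes[i] += 1;
          V[i] = vrest[i];
          ref_until[i] = t + (int)(tref[i] / dt);
          int u = n_l4 + i;
          for (int j = syn_ptr[u]; j < syn_ptr[u + 1]; ++j) {
            if (unif_rand() < syn_prel[j]) {
              if (syn_inh[j]) gi[syn_post[j]] += syn_g[j];
              else            ge[syn_post[j]] += syn_g[j];
            }
          }
        }
      }
      // exponential conductance decay (forward Euler)
      ge[i] -= dt * ge[i] / tausyn_e[i];
      gi[i] -= dt * gi[i] / tausyn_i[i];
    }
  }
  return n_spikes;
}

// Voltage trace of a single passive neuron receiving given conductance
// waveforms; used for invariant checks (relaxation to rest, no drive).
// [[Rcpp::export]]
NumericVector lif_passive_trace_cpp(double v0, double vrest, double taum,
                                    double dt, int n_steps) {
  NumericVector V(n_steps);
  double v = v0;
  for (int t = 0; t < n_steps; ++t) {
    v += dt * (-(v - vrest)) / taum;
    V[t] = v;
  }
  return V;
}
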