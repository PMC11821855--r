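#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step exponential-Euler leaky integrate-and-fire network.
//
// State per neuron: membrane potential v (mV) relaxing to v_rest with
// tau_mem, and synaptic drive g (mV) decaying with tau_syn. A presynaptic
// spike at step t adds the connection weight to the target's g at step
// t + delay_steps (ring buffer). The drive enters the membrane as a current
// term (g / tau_syn) * dt, so an isolated weight w produces a peak
// depolarization of ~w when tau_mem >> tau_syn. Threshold crossing emits a
// spike, resets v and holds it for the refractory period. Stimulated
// neurons fire exactly at their supplied spike steps and are not
// integrated.
//
// [[Rcpp::export]]
List lif_run_cpp(int n_neurons,
                 IntegerVector edge_pre,   // 0-based presynaptic index
                 IntegerVector edge_post,  // 0-based postsynaptic index
                 NumericVector edge_w,     // weight in mV (signed)
                 IntegerVector stim_idx,   // 0-based stimulated neuron index
                 List stim_steps,          // per stim neuron: 0-based spike steps
                 double v_rest, double v_reset, double v_threshold,
                 double tau_mem, double tau_syn,
                 int refr_steps, int delay_steps,
                 double dt, int n_steps, bool record_spikes) {
  const int n_edges = edge_pre.size();

  // CSR adjacency over presynaptic index
  std::vector<int> out_off(n_neurons + 1, 0);
  for (int e = 0; e < n_edges; ++e) out_off[edge_pre[e] + 1]++;
  for (int i = 0; i < n_neurons; ++i) out_off[i + 1] += out_off[i];
  std::vector<int> out_tgt(n_edges);
  std::vector<double> out_w(n_edges);
  {
    std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int p = edge_pre[e];
      out_tgt[cur[p]] = edge_post[e];
      out_w[cur[p]] = edge_w[e];
      ++cur[p];
    }
  }

  std::vector<bool> is_stim(n_neurons, false);
  for (int j = 0; j < stim_idx.size(); ++j) is_stim[stim_idx[j]] = true;

  // forced spikes per step
  std::vector< std::vector<int> > forced(n_steps);
  for (int j = 0; j < stim_idx.size(); ++j) {
    IntegerVector st = stim_steps[j];
    for (int s = 0; s < st.size(); ++s) {
      if (st[s] >= 0 && st[s] < n_steps) forced[st[s]].push_back(stim_idx[j]);
    }
  }

  const int D = delay_steps + 1;
  std::vector<double> buf((size_t)D * n_neurons, 0.0);
  std::vector<double> v(n_neurons, v_rest), g(n_neurons, 0.0);
  std::vector<int> refr(n_neurons, 0);
  IntegerVector spike_count(n_neurons, 0);
  std::vector< std::vector<int> > spike_log;
  if (record_spikes) spike_log.resize(n_neurons);

  const double em = std::exp(-dt / tau_mem);
  const double eg = std::exp(-dt / tau_syn);
  const double drive = dt / tau_syn;
  std::vector<int> spikers;

  for (int t = 0; t < n_steps; ++t) {
    // deliver delayed increments
    double *slot = &buf[(size_t)(t % D) * n_neurons];
    for (int i = 0; i < n_neurons; ++i) {
      g[i] += slot[i];
      slot[i] = 0.0;
    }
    // integrate
    spikers.clear();
    for (int i = 0; i < n_neurons; ++i) {
      if (is_stim[i]) continue;
      if (refr[i] > 0) {
        --refr[i];
        v[i] = v_reset;
        continue;
      }
      v[i] = v_rest + (v[i] - v_rest) * em + g[i] * drive;
      if (v[i] >= v_threshold) spikers.push_back(i);
    }
    for (int i = 0; i < n_neurons; ++i) g[i] *= eg;
    // forced stimulus spikes
    for (size_t s = 0; s < forced[t].size(); ++s) spikers.push_back(forced[t][s]);
    // emit
    double *future = &buf[(size_t)((t + delay_steps) % D) * n_neurons];
    for (size_t s = 0; s < spikers.size(); ++s) {
      int i = spikers[s];
      spike_count[i]++;
      if (record_spikes) spike_log[i].push_back(t);
      if (!is_stim[i]) {
        v[i] = v_reset;
        refr[i] = refr_steps;
      }
      for (int e = out_off[i]; e < out_off[i + 1]; ++e) {
        future[out_tgt[e]] += out_w[e];
      }
    }
  }

  List out = List::create(Named("spike_count") = spike_count);
  if (record_spikes) {
    List logs(n_neurons);
    for (int i = 0; i < n_neurons; ++i) logs[i] = wrap(spike_log[i]);
    out["spike_steps"] = logs;
  }
  return out;
}
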