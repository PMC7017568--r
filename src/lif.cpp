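#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of a leaky integrate-and-fire network.
//
// Membrane equation per neuron i:
//   tau_m dV_i/dt = E_m - V_i(t) + R_m I_i(t)
// with I_i(t) = background noise + sum_j w_ij * s_j(t), where s_j is the
// presynaptic spike trace: s_j jumps by 1 when neuron j fires and decays as
// exp(-t/tau_s) (so the synaptic kernel is a unit-height negative
// exponential). A spike fired at step k first contributes current at step
// k+1 (one-step synaptic delay; keeps the coupling strictly causal).
//
// noise_sd is expressed per sqrt(ms): the per-step deviate has standard
// deviation noise_sd / sqrt(dt), making the integrated drive invariant
// under refinement of dt.
//
// Uses R's RNG (norm_rand) so set.seed() on the R side makes the whole
// simulation reproducible. One deviate is drawn per neuron per step in a
// fixed order, including during refractoriness, to keep the stream stable.
// [[Rcpp::export(name = ".lif_simulate_cpp")]]
List lif_simulate_cpp(NumericMatrix W, double duration, double dt,
                      double tau_m, double E_m, double R_m,
                      double V_th, double V_reset, double t_ref,
                      double tau_s, double noise_mean, double noise_sd,
                      double v0, bool record_v) {
  const int n = W.nrow();
  const int nsteps = (int) std::floor(duration / dt + 1e-9);
  std::vector<double> V(n, v0), syn(n, 0.0), refr(n, 0.0);
  NumericMatrix Vtrace = record_v ? NumericMatrix(nsteps, n)
                                  : NumericMatrix(0, 0);
  std::vector< std::vector<double> > spikes(n);
  const double decay = std::exp(-dt / tau_s);
  const double step_sd = noise_sd / std::sqrt(dt);

  // cache nonzero inputs per postsynaptic neuron (W is typically sparse)
  std::vector< std::vector<int> > pre(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (W(i, j) != 0.0) pre[i].push_back(j);

  for (int step = 0; step < nsteps; ++step) {
    const double t = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double I = noise_mean + step_sd * norm_rand();
      const std::vector<int>& pr = pre[i];
      for (size_t q = 0; q < pr.size(); ++q)
        I += W(i, pr[q]) * syn[pr[q]];
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = V_reset;
      } else {
        V[i] += dt / tau_m * (E_m - V[i] + R_m * I);
      }
    }
    if (record_v)
      for (int i = 0; i < n; ++i) Vtrace(step, i) = V[i];
    for (int j = 0; j < n; ++j) syn[j] *= decay;
    for (int i = 0; i < n; ++i) {
      if (refr[i] <= 0.0 && V[i] >= V_th) {
        spikes[i].push_back(t);
        V[i] = V_reset;
        refr[i] = t_ref;
        syn[i] += 1.0;
      }
    }
  }

  List st(n);
  for (int i = 0; i < n; ++i) st[i] = wrap(spikes[i]);
  return List::create(_["spikes"] = st, _["voltage"] = Vtrace);
}
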