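// Euler-Maruyama integration of a recurrent network of multi-timescale
// adaptive threshold (MAT) neurons.
//
// Membrane (no reset):  dvm/dt = -(vm-VL)/tau_m - [ge(vm-VE)+gi(vm-VI)] - RIbg/tau_m
// with RIbg = ge_bg(vm-VE) + gi_bg(vm-VI); the recurrent conductance term is
// integrated exactly as typeset (not divided by tau_m) while the background
// term is. Conductances decay exponentially and jump by the synaptic weight
// when a delayed spike arrives. A spike is emitted when vm >= theta(t),
// theta = omega + h1 + h2, where h_k += alpha_k at each own spike and decays
// with tau_k. An absolute refractory period suppresses re-triggering since vm
// is never reset. Background conductances follow per-neuron OU processes
// advanced with their exact Gaussian transition and clipped at zero.
//
// All time constants are in ms; output spike times are in seconds.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".mat_simulate")]]
List mat_simulate(const NumericMatrix& weights,     // [source, target], A applied
                  const NumericMatrix& delays_ms,   // same shape
                  const IntegerVector& is_exc,      // per source neuron
                  const NumericVector& tau_m,
                  const NumericVector& omega_rest,
                  const NumericVector& alpha1,
                  const NumericVector& alpha2,
                  double VL, double VE, double VI,
                  double tau_se, double tau_si,
                  double tau1, double tau2,
                  double refractory_ms,
                  double tau_bge, double tau_bgi,
                  double g0e, double g0i,
                  double sig_e, double sig_i,
                  double dt_ms, double duration_s) {
  const int n = weights.nrow();
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt_ms);

  // adjacency lists with delay steps
  std::vector<std::vector<int>> tgt(n);
  std::vector<std::vector<double>> wgt(n);
  std::vector<std::vector<int>> dstep(n);
  int max_ds = 1;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      double w = weights(j, i);
      if (w != 0.0 && i != j) {
        int ds = (int)std::lround(delays_ms(j, i) / dt_ms);
        if (ds < 1) ds = 1;
        tgt[j].push_back(i);
        wgt[j].push_back(w);
        dstep[j].push_back(ds);
        if (ds > max_ds) max_ds = ds;
      }
    }
  }
  const int slots = max_ds + 1;
  std::vector<std::vector<std::pair<int, double>>> ring_e(slots), ring_i(slots);

  std::vector<double> vm(n, VL), ge(n, 0.0), gi(n, 0.0);
  std::vector<double> gbe(n, g0e), gbi(n, g0i);
  std::vector<double> h1(n, 0.0), h2(n, 0.0);
  std::vector<long> last_spike(n, -1000000000L);

  const double d1 = std::exp(-dt_ms / tau1);
  const double d2 = std::exp(-dt_ms / tau2);
  const double dec_e = 1.0 - dt_ms / tau_se;
  const double dec_i = 1.0 - dt_ms / tau_si;
  const double ee = std::exp(-dt_ms / tau_bge);
  const double ei = std::exp(-dt_ms / tau_bgi);
  const double sde = sig_e * std::sqrt(1.0 - ee * ee);
  const double sdi = sig_i * std::sqrt(1.0 - ei * ei);
  const long refr_steps = (long)std::llround(refractory_ms / dt_ms);

  std::vector<double> sp_time;
  std::vector<int> sp_unit;
  sp_time.reserve(1 << 16);
  sp_unit.reserve(1 << 16);

  RNGScope scope;

  for (long s = 0; s < n_steps; ++s) {
    const int idx = (int)(s % slots);
    for (auto& pr : ring_e[idx]) ge[pr.first] += pr.second;
    for (auto& pr : ring_i[idx]) gi[pr.first] += pr.second;
    ring_e[idx].clear();
    ring_i[idx].clear();

    for (int i = 0; i < n; ++i) {
      gbe[i] = g0e + (gbe[i] - g0e) * ee + sde * norm_rand();
      if (gbe[i] < 0.0) gbe[i] = 0.0;
      gbi[i] = g0i + (gbi[i] - g0i) * ei + sdi * norm_rand();
      if (gbi[i] < 0.0) gbi[i] = 0.0;

      const double ribg = gbe[i] * (vm[i] - VE) + gbi[i] * (vm[i] - VI);
      const double dv = -(vm[i] - VL) / tau_m[i]
                        - (ge[i] * (vm[i] - VE) + gi[i] * (vm[i] - VI))
                        - ribg / tau_m[i];
      vm[i] += dt_ms * dv;
      if (!(vm[i] > -1000.0 && vm[i] < 1000.0)) {
        stop("numerical blow-up: |vm| exceeded 1000 mV at t = %f s (neuron %d)",
             s * dt_ms / 1000.0, i + 1);
      }
      ge[i] *= dec_e;
      gi[i] *= dec_i;
      h1[i] *= d1;
      h2[i] *= d2;

      const double theta = omega_rest[i] + h1[i] + h2[i];
      if (vm[i] >= theta && (s - last_spike[i]) >= refr_steps) {
        last_spike[i] = s;
        sp_time.push_back((s + 1) * dt_ms / 1000.0);
        sp_unit.push_back(i + 1);
        h1[i] += alpha1[i];
        h2[i] += alpha2[i];
        const bool exc = is_exc[i] != 0;
        const auto& ti = tgt[i];
        for (size_t k = 0; k < ti.size(); ++k) {
          const int slot = (int)((s + dstep[i][k]) % slots);
          if (exc) ring_e[slot].push_back({ti[k], wgt[i][k]});
          else     ring_i[slot].push_back({ti[k], wgt[i][k]});
        }
      }
    }
  }

  return List::create(_["time"] = wrap(sp_time), _["unit"] = wrap(sp_unit));
}
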