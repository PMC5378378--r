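#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of a network of leaky integrate-and-fire neurons
// with spike-frequency adaptation (calcium-like variable c integrating the
// neuron's own spikes):
//   dV/dt = -V/tau + sum_j J_ij sum_k delta(t - t_k^j - d_ij)
//           - g_SFA * c + I_dc + Poisson external jumps
//   dc/dt = -c/tau_SFA + sum_k delta(t - t_k)   (unit increment per spike)
// Threshold crossing (V >= V_th) records a spike; V is clamped to H_reset
// for the refractory period (inputs arriving meanwhile are discarded).
// Delayed synaptic deltas are accumulated in a circular future buffer;
// delays are rounded to the integration grid. External drive per neuron is
// a merged Poisson train: per step a Poisson(nu_ext * dt) count of jumps,
// each of size j_ext. Uses R's RNG throughout.
// [[Rcpp::export(name = ".lif_simulate")]]
List lif_simulate_cpp(int n_neurons,
                      IntegerVector syn_ptr,    // length n_neurons + 1, 0-based
                      IntegerVector syn_target, // 0-based
                      NumericVector syn_w,      // mV
                      NumericVector syn_delay,  // ms
                      NumericVector tau,        // ms, per neuron
                      NumericVector t_ref,      // ms
                      NumericVector g_sfa,      // mV/ms per unit c
                      NumericVector tau_sfa,    // ms
                      NumericVector nu_ext,     // kHz = events/ms
                      NumericVector j_ext,      // mV
                      NumericVector i_dc,       // mV/ms
                      IntegerVector module,     // 0-based module index
                      LogicalVector is_exc,
                      int n_modules,
                      double v_th, double h_reset,
                      double duration, double dt,
                      bool record_raster, double rate_bin) {
  const int n_steps = (int)std::llround(duration / dt);
  // delay steps (>= 1 so a spike is never delivered within its own step)
  const int n_syn = syn_w.size();
  std::vector<int> dstep(n_syn);
  int max_d = 1;
  for (int s = 0; s < n_syn; ++s) {
    int d = (int)std::llround(syn_delay[s] / dt);
    if (d < 1) d = 1;
    dstep[s] = d;
    if (d > max_d) d = d; // keep below
    if (dstep[s] > max_d) max_d = dstep[s];
  }
  const int nbuf = max_d + 1;
  std::vector<double> buf((size_t)nbuf * n_neurons, 0.0);
  std::vector<double> V(n_neurons, 0.0), C(n_neurons, 0.0);
  std::vector<int> refr_until(n_neurons, -1);
  std::vector<double> eV(n_neurons), eC(n_neurons);
  for (int i = 0; i < n_neurons; ++i) {
    eV[i] = std::exp(-dt / tau[i]);
    eC[i] = std::exp(-dt / tau_sfa[i]);
  }
  std::vector<int> tref_steps(n_neurons);
  for (int i = 0; i < n_neurons; ++i)
    tref_steps[i] = (int)std::llround(t_ref[i] / dt);
  // per-module excitatory spike counts per rate bin
  const int bin_steps = std::max(1, (int)std::llround(rate_bin / dt));
  const int n_bins = (n_steps + bin_steps - 1) / bin_steps;
  IntegerMatrix ecounts(n_bins, n_modules);
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % nbuf;
    double* in = &buf[(size_t)slot * n_neurons];
    const int bin = t / bin_steps;
    for (int i = 0; i < n_neurons; ++i) {
      const double inc = in[i];
      in[i] = 0.0;
      // calcium decays regardless of refractoriness
      C[i] *= eC[i];
      if (t < refr_until[i]) continue; // clamped at H_reset, inputs lost
      double v = V[i] * eV[i] + (i_dc[i] - g_sfa[i] * C[i]) * tau[i] * (1.0 - eV[i]);
      v += inc;
      if (nu_ext[i] > 0) {
        double k = R::rpois(nu_ext[i] * dt);
        if (k > 0) v += j_ext[i] * k;
      }
      if (v >= v_th) {
        // spike
        if (record_raster) { sp_t.push_back((t + 1) * dt); sp_id.push_back(i + 1); }
        if (is_exc[i]) ecounts(bin, module[i]) += 1;
        C[i] += 1.0;
        refr_until[i] = t + 1 + tref_steps[i];
        V[i] = h_reset;
        for (int s = syn_ptr[i]; s < syn_ptr[i + 1]; ++s) {
          int dslot = (t + dstep[s]) % nbuf;
          buf[(size_t)dslot * n_neurons + syn_target[s]] += syn_w[s];
        }
      } else {
        V[i] = v;
      }
    }
  }
  List raster;
  if (record_raster) {
    raster = List::create(_["time"] = NumericVector(sp_t.begin(), sp_t.end()),
                          _["id"] = IntegerVector(sp_id.begin(), sp_id.end()));
  } else {
    raster = R_NilValue;
  }
  return List::create(_["ecounts"] = ecounts,
                      _["rate_bin"] = bin_steps * dt,
                      _["raster"] = raster,
                      _["n_steps"] = n_steps);
}

// Draw network connectivity. Synaptic weights are Gaussian around the class
// mean with 25% (configurable) relative sd; the Gaussian multiplier
// (1 + rel_sd * z) is resampled until positive so a weight always keeps the
// sign of its mean. Delays ~ exponential with scale (d_max - d_min),
// shifted by d_min and truncated to [d_min, d_max] by rejection.
// Returns flat synapse arrays (source-major) plus, for inter-module
// synapses, the (p, q) module pair and the frozen multiplier so the weights
// can be recomputed when the mean efficacies J_pq change during learning.
// [[Rcpp::export(name = ".build_synapses")]]
List build_synapses_cpp(int n_modules, int n_e, int n_i,
                        NumericMatrix c_intra,   // 2x2: [post E/I][pre E/I]
                        NumericMatrix j_intra,   // 2x2 mean efficacies (mV)
                        NumericMatrix dmax_intra,// 2x2 (ms)
                        double d_min,
                        double c_inter, NumericMatrix j_inter, // n_mod x n_mod
                        double dmax_inter, double rel_sd) {
  const int per_mod = n_e + n_i;
  const int n_neurons = n_modules * per_mod;
  std::vector<std::vector<int> > tgt(n_neurons);
  std::vector<std::vector<double> > wgt(n_neurons), dly(n_neurons);
  std::vector<std::vector<double> > mult(n_neurons); // frozen multiplier
  std::vector<std::vector<int> > ipq(n_neurons);     // inter pair code, -1 intra
  auto draw_mult = [&]() {
    double m;
    do { m = 1.0 + rel_sd * norm_rand(); } while (m <= 0.0);
    return m;
  };
  auto draw_delay = [&](double dmax) {
    if (dmax <= d_min) return d_min;
    double d;
    do { d = d_min + exp_rand() * (dmax - d_min); } while (d > dmax);
    return d;
  };
  // intra-module
  for (int m = 0; m < n_modules; ++m) {
    const int base = m * per_mod;
    for (int post = 0; post < per_mod; ++post) {
      const int X = (post < n_e) ? 0 : 1; // post type
      for (int pre = 0; pre < per_mod; ++pre) {
        if (pre == post) continue;
        const int Y = (pre < n_e) ? 0 : 1;
        if (unif_rand() >= c_intra(X, Y)) continue;
        double mu = j_intra(X, Y);
        double mlt = draw_mult();
        int src = base + pre, dst = base + post;
        tgt[src].push_back(dst);
        wgt[src].push_back(mu * mlt);
        dly[src].push_back(draw_delay(dmax_intra(X, Y)));
        mult[src].push_back(mlt);
        ipq[src].push_back(-1);
      }
    }
  }
  // inter-module (E -> E only)
  for (int p = 0; p < n_modules; ++p) {
    for (int q = 0; q < n_modules; ++q) {
      if (p == q) continue;
      double mu = j_inter(p, q); // efficacy onto module p from module q
      for (int post = 0; post < n_e; ++post) {
        for (int pre = 0; pre < n_e; ++pre) {
          if (unif_rand() >= c_inter) continue;
          double mlt = draw_mult();
          int src = q * per_mod + pre, dst = p * per_mod + post;
          tgt[src].push_back(dst);
          wgt[src].push_back(mu * mlt);
          dly[src].push_back(draw_delay(dmax_inter));
          mult[src].push_back(mlt);
          ipq[src].push_back(p * n_modules + q);
        }
      }
    }
  }
  // flatten, source-major
  int n_syn = 0;
  for (int i = 0; i < n_neurons; ++i) n_syn += (int)tgt[i].size();
  IntegerVector ptr(n_neurons + 1), target(n_syn), pair(n_syn);
  NumericVector w(n_syn), d(n_syn), ml(n_syn);
  int pos = 0;
  for (int i = 0; i < n_neurons; ++i) {
    ptr[i] = pos;
    for (size_t s = 0; s < tgt[i].size(); ++s) {
      target[pos] = tgt[i][s];
      w[pos] = wgt[i][s];
      d[pos] = dly[i][s];
      ml[pos] = mult[i][s];
      pair[pos] = ipq[i][s];
      ++pos;
    }
  }
  ptr[n_neurons] = pos;
  return List::create(_["syn_ptr"] = ptr, _["syn_target"] = target,
                      _["syn_w"] = w, _["syn_delay"] = d,
                      _["syn_mult"] = ml, _["syn_pair"] = pair);
}
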