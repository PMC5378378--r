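#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Glauber (heat-bath) single-spin-flip dynamics for the Ising energy
// H[s] = -(1/N) sum_{i<j} s_i J_ij s_j = -(1/(2N)) s' J s
// (J symmetric, zero diagonal).
// One Monte Carlo sweep = N attempted flips at uniformly random sites.
// Flipping spin k changes the energy by dH = (2/N) s_k (J s)_k.
// Records one row per sweep after burn_in; uses R's RNG.
// [[Rcpp::export(name = ".glauber_mc")]]
IntegerMatrix glauber_mc_cpp(NumericMatrix J, IntegerVector init, double beta,
                             int sweeps, int burn_in) {
  const int N = J.nrow();
  std::vector<double> h(N, 0.0);
  std::vector<int> s(N);
  for (int i = 0; i < N; ++i) s[i] = init[i];
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int j = 0; j < N; ++j) acc += J(i, j) * s[j];
    h[i] = acc;
  }
  IntegerMatrix out(sweeps, N);
  const int total = sweeps + burn_in;
  for (int sw = 0; sw < total; ++sw) {
    for (int a = 0; a < N; ++a) {
      int k = (int)(unif_rand() * N);
      if (k == N) k = N - 1;
      double dH = 2.0 / N * s[k] * h[k];
      double pflip = 1.0 / (1.0 + std::exp(beta * dH));
      if (unif_rand() < pflip) {
        s[k] = -s[k];
        const double two_sk = 2.0 * s[k];
        for (int i = 0; i < N; ++i) h[i] += J(i, k) * two_sk;
      }
    }
    if (sw >= burn_in) {
      for (int i = 0; i < N; ++i) out(sw - burn_in, i) = s[i];
    }
  }
  return out;
}

// Strict zero-temperature descent: sequential sweeps in a fresh random
// order; a spin is flipped only if it strictly lowers the energy
// (dH = (2/N) s_k (J s)_k < 0). Stops when a full sweep makes no flip.
static void descend_one(const NumericMatrix& J, std::vector<int>& s,
                        int max_sweeps, bool& converged) {
  const int N = J.nrow();
  std::vector<double> h(N);
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    for (int j = 0; j < N; ++j) acc += J(i, j) * s[j];
    h[i] = acc;
  }
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  converged = false;
  for (int sw = 0; sw < max_sweeps; ++sw) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    bool flipped = false;
    for (int a = 0; a < N; ++a) {
      int k = ord[a];
      if (s[k] * h[k] < 0.0) { // dH < 0
        s[k] = -s[k];
        const double two_sk = 2.0 * s[k];
        for (int i = 0; i < N; ++i) h[i] += J(i, k) * two_sk;
        flipped = true;
      }
    }
    if (!flipped) { converged = true; break; }
  }
}

// [[Rcpp::export(name = ".zt_descent")]]
List zt_descent_cpp(NumericMatrix J, IntegerVector state, int max_sweeps) {
  const int N = J.nrow();
  std::vector<int> s(N);
  for (int i = 0; i < N; ++i) s[i] = state[i];
  bool conv = false;
  descend_one(J, s, max_sweeps, conv);
  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = s[i];
  return List::create(_["state"] = out, _["converged"] = conv);
}

// Descent from every row of `states`; returns final states and flags.
// [[Rcpp::export(name = ".zt_descent_many")]]
List zt_descent_many_cpp(NumericMatrix J, IntegerMatrix states, int max_sweeps) {
  const int N = J.nrow(), M = states.nrow();
  IntegerMatrix out(M, N);
  LogicalVector conv(M);
  std::vector<int> s(N);
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < N; ++i) s[i] = states(m, i);
    bool c = false;
    descend_one(J, s, max_sweeps, c);
    conv[m] = c;
    for (int i = 0; i < N; ++i) out(m, i) = s[i];
  }
  return List::create(_["states"] = out, _["converged"] = conv);
}
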