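#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Modified mean-shift on the {-1,+1}^N hypercube (N <= 256).
// Positions are packed into 64-bit words; Hamming distances via popcount.
// A hash multiset of unique current positions (count + weight per position)
// makes each sequential update O(#unique) instead of O(M).

typedef std::array<uint64_t, 4> Key; // supports N <= 256

struct KeyHash {
  size_t operator()(const Key& k) const {
    uint64_t h = 1469598103934665603ULL;
    for (int w = 0; w < 4; ++w) {
      h ^= k[w];
      h *= 1099511628211ULL;
    }
    return (size_t)h;
  }
};

struct Bucket { int count; double wsum; };

static inline int popcnt64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int keydist(const Key& a, const Key& b) {
  return popcnt64(a[0] ^ b[0]) + popcnt64(a[1] ^ b[1]) +
         popcnt64(a[2] ^ b[2]) + popcnt64(a[3] ^ b[3]);
}

static Key pack_row(const IntegerMatrix& m, int row) {
  Key k; k.fill(0ULL);
  const int N = m.ncol();
  for (int j = 0; j < N; ++j)
    if (m(row, j) > 0) k[j >> 6] |= (1ULL << (j & 63));
  return k;
}

// Adaptive flat-kernel radius for point i: over n >= n0, minimize the
// standard deviation sigma(n) of the distances from x_i to its n nearest
// neighbors; radius = distance to the argmin-th nearest neighbor
// (ties broken by the smallest n).
static double adaptive_radius_counts(const std::vector<double>& distw,
                                     const std::vector<int>& distc,
                                     int n_other, int n0, int N) {
  // distc[d] = number of other points at distance d (d = 0..N)
  double S1 = 0.0, S2 = 0.0;
  int n = 0;
  double best_var = R_PosInf;
  int best_d = -1;
  for (int d = 0; d <= N; ++d) {
    int c = distc[d];
    for (int t = 0; t < c; ++t) {
      ++n;
      S1 += d;
      S2 += (double)d * d;
      if (n >= n0) {
        double var = S2 / n - (S1 / n) * (S1 / n);
        if (var < best_var - 1e-12) { best_var = var; best_d = d; }
      }
    }
  }
  (void)distw;
  return (double)best_d;
}

// [[Rcpp::export(name = ".ms_adaptive_radius")]]
double ms_adaptive_radius_cpp(IntegerMatrix data, int i, int n0) {
  const int M = data.nrow(), N = data.ncol();
  if (M - 1 < n0) stop("need at least n0 + 1 points");
  std::vector<Key> keys(M);
  for (int r = 0; r < M; ++r) keys[r] = pack_row(data, r);
  std::vector<int> distc(N + 1, 0);
  for (int r = 0; r < M; ++r) {
    if (r == i - 1) continue; // i is 1-based
    ++distc[keydist(keys[i - 1], keys[r])];
  }
  std::vector<double> dummy;
  return adaptive_radius_counts(dummy, distc, M - 1, n0, N);
}

// Core sequential mean-shift iteration.
// fixed_radius < 0 => adaptive radius recomputed from current positions at
// every update. Convergence: fraction of position-changing updates among
// the last `window` updates drops below conv_frac (checked once at least
// `window` updates have been made).
// [[Rcpp::export(name = ".ms_core")]]
List ms_core_cpp(IntegerMatrix data, NumericVector weights, int n0,
                 double conv_frac, double fixed_radius, int max_updates,
                 int window) {
  const int M = data.nrow(), N = data.ncol();
  if (N > 256) stop("binary mean-shift supports at most 256 channels");
  std::vector<Key> pos(M);
  std::unordered_map<Key, Bucket, KeyHash> uniq;
  uniq.reserve(2 * M);
  for (int r = 0; r < M; ++r) {
    pos[r] = pack_row(data, r);
    Bucket& b = uniq[pos[r]];
    b.count += 1;
    b.wsum += weights[r];
  }
  std::vector<int> changed(window, 0);
  int chsum = 0, chpos = 0;
  std::vector<int> distc(N + 1, 0);
  std::vector<const Key*> inkeys;   // unique keys within radius
  std::vector<double> inw;          // their weight sums
  std::vector<double> possum(N, 0.0);
  bool converged = false;
  long long t = 0;
  for (; t < max_updates; ++t) {
    int i = (int)(unif_rand() * M);
    if (i == M) i = M - 1;
    const Key cur = pos[i];
    // distance census over unique positions
    std::fill(distc.begin(), distc.end(), 0);
    for (auto& kv : uniq) {
      int d = keydist(cur, kv.first);
      distc[d] += kv.second.count;
    }
    distc[0] -= 1; // exclude the point itself
    double r;
    if (fixed_radius >= 0) {
      r = fixed_radius;
    } else {
      if (M - 1 < n0) stop("need at least n0 + 1 points");
      std::vector<double> dummy;
      r = adaptive_radius_counts(dummy, distc, M - 1, n0, N);
    }
    // weighted neighbourhood mean (flat kernel, j != i)
    inkeys.clear(); inw.clear();
    double wtot = 0.0;
    for (auto& kv : uniq) {
      int d = keydist(cur, kv.first);
      if (d <= r) {
        double w = kv.second.wsum;
        // exclude the moving sample itself: one unit of its weight (a
        // centroid of mass m stands for m samples and contributes m - 1)
        if (d == 0) w -= 1.0;
        if (w > 0) {
          inkeys.push_back(&kv.first);
          inw.push_back(w);
          wtot += w;
        }
      }
    }
    bool moved = false;
    if (wtot > 0) {
      std::fill(possum.begin(), possum.end(), 0.0);
      for (size_t u = 0; u < inkeys.size(); ++u) {
        const Key& k = *inkeys[u];
        const double w = inw[u];
        for (int j = 0; j < N; ++j)
          if (k[j >> 6] & (1ULL << (j & 63))) possum[j] += w;
      }
      Key nk = cur;
      for (int j = 0; j < N; ++j) {
        double mean = 2.0 * possum[j] - wtot; // weighted sum of +/-1 coords
        if (mean > 0) nk[j >> 6] |= (1ULL << (j & 63));
        else if (mean < 0) nk[j >> 6] &= ~(1ULL << (j & 63));
        // mean == 0: keep the current coordinate
      }
      if (!(nk == cur)) {
        moved = true;
        auto it = uniq.find(cur);
        it->second.count -= 1;
        it->second.wsum -= weights[i];
        if (it->second.count == 0) uniq.erase(it);
        Bucket& nb = uniq[nk];
        nb.count += 1;
        nb.wsum += weights[i];
        pos[i] = nk;
      }
    }
    chsum += (moved ? 1 : 0) - changed[chpos];
    changed[chpos] = moved ? 1 : 0;
    chpos = (chpos + 1) % window;
    if (t + 1 >= window && (double)chsum / window < conv_frac) {
      converged = true;
      ++t;
      break;
    }
  }
  IntegerMatrix out(M, N);
  for (int rI = 0; rI < M; ++rI)
    for (int j = 0; j < N; ++j)
      out(rI, j) = (pos[rI][j >> 6] & (1ULL << (j & 63))) ? 1 : -1;
  return List::create(_["positions"] = out,
                      _["converged"] = converged,
                      _["n_updates"] = (double)t);
}
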