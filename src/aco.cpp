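#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Package-internal xorshift64* generator. The ant-system loop must be
// bit-reproducible for a given seed and independent of R's RNG stream, so we
// do not touch unif_rand() here.
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) {
    s = seed ? seed : UINT64_C(0x9E3779B97F4A7C15);
    // warm up: low-entropy seeds (small integers) otherwise start correlated
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * UINT64_C(2685821657736338717);
  }
  // uniform in [0, 1)
  double unif() {
    return (double)(next() >> 11) / 9007199254740992.0;
  }
};

static double tour_length(const std::vector<int> &order,
                          const NumericMatrix &d, bool cycle) {
  double len = 0.0;
  const int n = (int)order.size();
  for (int k = 0; k + 1 < n; ++k) len += d(order[k], order[k + 1]);
  if (cycle && n > 1) len += d(order[n - 1], order[0]);
  return len;
}

// Canonical ant system over a symmetric distance matrix. Each ant starts at a
// uniformly random node and extends its path by sampling the next unvisited
// node j with probability proportional to tau(i,j)^alpha * (1/(d+eps))^beta.
// After every iteration pheromone evaporates by (1-rho) and each ant deposits
// q / length on the edges of its own path (both directions). Returns the
// best-so-far order after n_iter iterations plus the best-length trajectory.
// [[Rcpp::export(name = ".aco_run_cpp")]]
List aco_run_cpp(NumericMatrix d, int n_ants, double alpha, double beta,
                 double rho, double q, double tau0, int n_iter,
                 bool cycle, double eps, double seed) {
  const int n = d.nrow();
  if (n < 2) stop("distance matrix must have at least 2 genes");

  XorShift64 rng((uint64_t)seed);

  // heuristic desirability, precomputed with the configured exponent
  std::vector<double> eta(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) eta[i * n + j] = std::pow(1.0 / (d(i, j) + eps), beta);

  std::vector<double> tau(n * n, tau0);

  std::vector<int> best_order;
  double best_len = R_PosInf;
  NumericVector trajectory(n_iter);

  std::vector<std::vector<int>> ant_orders(n_ants, std::vector<int>(n));
  std::vector<double> ant_lens(n_ants);
  std::vector<char> visited(n);
  std::vector<double> w(n);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int a = 0; a < n_ants; ++a) {
      std::fill(visited.begin(), visited.end(), 0);
      int cur = (int)(rng.unif() * n);
      if (cur >= n) cur = n - 1;
      ant_orders[a][0] = cur;
      visited[cur] = 1;
      for (int step = 1; step < n; ++step) {
        double total = 0.0;
        for (int j = 0; j < n; ++j) {
          if (visited[j]) { w[j] = 0.0; continue; }
          double tw = (alpha == 1.0) ? tau[cur * n + j]
                                     : std::pow(tau[cur * n + j], alpha);
          w[j] = tw * eta[cur * n + j];
          total += w[j];
        }
        int nxt = -1;
        if (total > 0.0 && std::isfinite(total)) {
          double u = rng.unif() * total, acc = 0.0;
          for (int j = 0; j < n; ++j) {
            if (visited[j]) continue;
            acc += w[j];
            if (u <= acc) { nxt = j; break; }
          }
        }
        if (nxt < 0) { // numeric fallback: first unvisited
          for (int j = 0; j < n; ++j) if (!visited[j]) { nxt = j; break; }
        }
        ant_orders[a][step] = nxt;
        visited[nxt] = 1;
        cur = nxt;
      }
      ant_lens[a] = tour_length(ant_orders[a], d, cycle);
      if (ant_lens[a] < best_len) {
        best_len = ant_lens[a];
        best_order = ant_orders[a];
      }
    }

    for (int k = 0; k < n * n; ++k) tau[k] *= (1.0 - rho);
    for (int a = 0; a < n_ants; ++a) {
      double dep = q / std::max(ant_lens[a], 1e-300);
      const std::vector<int> &ord = ant_orders[a];
      for (int k = 0; k + 1 < n; ++k) {
        tau[ord[k] * n + ord[k + 1]] += dep;
        tau[ord[k + 1] * n + ord[k]] += dep;
      }
      if (cycle && n > 1) {
        tau[ord[n - 1] * n + ord[0]] += dep;
        tau[ord[0] * n + ord[n - 1]] += dep;
      }
    }
    trajectory[iter] = best_len;
  }

  IntegerVector order(n);
  for (int i = 0; i < n; ++i) order[i] = best_order[i] + 1; // 1-based
  return List::create(_["order"] = order,
                      _["length"] = best_len,
                      _["trajectory"] = trajectory);
}
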