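#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Counter-based RNG: one independent substream per (seed, iteration, ant),
// so changing the ant count or iteration budget never reshuffles draws
// belonging to other (iteration, ant) pairs.
namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct SubStream {
  uint64_t state;
  SubStream(uint64_t seed, uint64_t iter, uint64_t ant) {
    // mix the three keys into one 64-bit state
    uint64_t s = seed;
    state = splitmix64(s) ^ (iter * 0xA24BAED4963EE407ULL)
                          ^ (ant  * 0x9FB21C651E98DF25ULL);
    splitmix64(state); // warm up
  }
  // uniform double in [0, 1)
  double unif() {
    return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) { // 0 .. n-1
    int r = (int)(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

// Weighted draw from log-weights (robust to large alpha/beta); ties and
// degenerate all-zero totals resolve to the lowest candidate index.
int sample_logw(const std::vector<double> &logw,
                const std::vector<int> &cand, SubStream &rng) {
  int nc = (int)cand.size();
  if (nc == 1) return cand[0];
  double mx = *std::max_element(logw.begin(), logw.end());
  std::vector<double> w(nc);
  double tot = 0.0;
  for (int i = 0; i < nc; ++i) { w[i] = std::exp(logw[i] - mx); tot += w[i]; }
  double u = rng.unif() * tot, cum = 0.0;
  for (int i = 0; i < nc; ++i) {
    cum += w[i];
    if (u < cum) return cand[i];
  }
  return cand[nc - 1];
}

void build_path(const NumericMatrix &tau, const NumericMatrix &dist,
                double alpha, double beta, double eps_d,
                SubStream &rng, std::vector<int> &path) {
  int n = tau.nrow();
  path.resize(n);
  std::vector<bool> visited(n, false);
  int cur = rng.unif_int(n);
  path[0] = cur; visited[cur] = true;
  std::vector<int> cand; cand.reserve(n);
  std::vector<double> logw; logw.reserve(n);
  for (int step = 1; step < n; ++step) {
    cand.clear(); logw.clear();
    for (int j = 0; j < n; ++j) {
      if (visited[j]) continue;
      cand.push_back(j);
      logw.push_back(alpha * std::log(tau(cur, j))
                     - beta * std::log(dist(cur, j) + eps_d));
    }
    cur = sample_logw(logw, cand, rng);
    path[step] = cur; visited[cur] = true;
  }
}

// Cut the k-1 largest consecutive edges (ties -> earliest position);
// contiguous segments become clusters labelled 1..k in path order.
void cut_path(const std::vector<int> &path, const NumericMatrix &dist,
              int k, std::vector<int> &labels, std::vector<int> &cuts) {
  int n = (int)path.size();
  std::vector<std::pair<double, int> > edges(n - 1);
  for (int i = 0; i < n - 1; ++i)
    edges[i] = std::make_pair(dist(path[i], path[i + 1]), i);
  std::sort(edges.begin(), edges.end(),
            [](const std::pair<double, int> &a, const std::pair<double, int> &b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  std::vector<bool> cut(n - 1, false);
  cuts.clear();
  for (int i = 0; i < k - 1; ++i) cut[edges[i].second] = true;
  for (int i = 0; i < n - 1; ++i) if (cut[i]) cuts.push_back(i + 1); // 1-based
  labels.assign(n, 0);
  int seg = 1;
  labels[path[0]] = 1;
  for (int i = 1; i < n; ++i) {
    if (cut[i - 1]) ++seg;
    labels[path[i]] = seg;
  }
}

// Size-weighted within-cluster cohesion: the mean over samples of the
// mean distance to own-cluster peers, (1/n) sum_c |c| * meanpair(c).
// Singletons contribute 0 but carry only their own 1/n weight, so the
// objective cannot be gamed by shaving single points off a large blob.
double partition_cost(const std::vector<int> &labels,
                      const NumericMatrix &dist, int k) {
  int n = (int)labels.size();
  std::vector<double> sum(k + 1, 0.0);
  std::vector<int> cnt(k + 1, 0);
  for (int i = 0; i < n; ++i) ++cnt[labels[i]];
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (labels[i] == labels[j]) sum[labels[i]] += dist(i, j);
  double cost = 0.0;
  for (int c = 1; c <= k; ++c)
    if (cnt[c] >= 2) cost += cnt[c] * (sum[c] / (0.5 * cnt[c] * (cnt[c] - 1.0)));
  return cost / n;
}

// Evaporate, deposit Q/(cost+eps_d) on every uncut path edge of every ant,
// floor at tau_min; returns max relative entry change.
double pheromone_step(NumericMatrix &tau,
                      const std::vector<std::vector<int> > &paths,
                      const std::vector<std::vector<int> > &cutsets,
                      const std::vector<double> &costs,
                      double rho, double Q, double eps_d, double tau_min) {
  int n = tau.nrow(), m = (int)paths.size();
  NumericMatrix old = clone(tau);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) tau(i, j) *= (1.0 - rho);
  for (int a = 0; a < m; ++a) {
    double dep = Q / (costs[a] + eps_d);
    const std::vector<int> &p = paths[a];
    std::vector<bool> cut(n, false);
    for (size_t c = 0; c < cutsets[a].size(); ++c) cut[cutsets[a][c] - 1] = true;
    for (int e = 0; e < n - 1; ++e) {
      if (cut[e]) continue;
      tau(p[e], p[e + 1]) += dep;
      tau(p[e + 1], p[e]) += dep;
    }
  }
  double max_change = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (tau(i, j) < tau_min) tau(i, j) = tau_min;
      double rel = std::fabs(tau(i, j) - old(i, j)) / old(i, j);
      if (rel > max_change) max_change = rel;
    }
  return max_change;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_construct_path(NumericMatrix tau, NumericMatrix dist,
                                 double alpha, double beta, double eps_d,
                                 int seed, int iter, int ant) {
  SubStream rng((uint64_t)seed, (uint64_t)iter, (uint64_t)ant);
  std::vector<int> path;
  build_path(tau, dist, alpha, beta, eps_d, rng, path);
  IntegerVector out(path.size());
  for (size_t i = 0; i < path.size(); ++i) out[i] = path[i] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_path_to_partition(IntegerVector path, NumericMatrix dist, int k) {
  std::vector<int> p(path.size()), labels, cuts;
  for (int i = 0; i < path.size(); ++i) p[i] = path[i] - 1;
  cut_path(p, dist, k, labels, cuts);
  return List::create(_["labels"] = wrap(labels), _["cut_edges"] = wrap(cuts));
}

// [[Rcpp::export]]
double cpp_solution_cost(IntegerVector labels, NumericMatrix dist) {
  std::vector<int> lab(labels.size());
  int k = 0;
  for (int i = 0; i < labels.size(); ++i) {
    lab[i] = labels[i];
    if (lab[i] > k) k = lab[i];
  }
  return partition_cost(lab, dist, k);
}

// [[Rcpp::export]]
List cpp_update_pheromone(NumericMatrix tau, List paths, List cutsets,
                          NumericVector costs, double rho, double Q,
                          double eps_d, double tau_min) {
  int m = paths.size();
  std::vector<std::vector<int> > ps(m), cs(m);
  std::vector<double> co(m);
  for (int a = 0; a < m; ++a) {
    IntegerVector p = paths[a], c = cutsets[a];
    ps[a].resize(p.size());
    for (int i = 0; i < p.size(); ++i) ps[a][i] = p[i] - 1;
    cs[a] = as<std::vector<int> >(c);
    co[a] = costs[a];
  }
  NumericMatrix out = clone(tau);
  double mc = pheromone_step(out, ps, cs, co, rho, Q, eps_d, tau_min);
  return List::create(_["tau"] = out, _["max_change"] = mc);
}

// [[Rcpp::export]]
List cpp_aco_run(NumericMatrix dist, int m, int T, double rho, double tau0,
                 double alpha, double beta, double Q, int k, double epsilon,
                 int seed, double tau_min, double eps_d, bool init_jitter) {
  int n = dist.nrow();
  NumericMatrix tau(n, n);
  if (init_jitter) {
    SubStream jrng((uint64_t)seed, 0xFFFFFFFFULL, 0ULL);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double v = tau0 * (1.0 + 0.2 * (jrng.unif() - 0.5));
        tau(i, j) = v; tau(j, i) = v;
      }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) tau(i, j) = tau0;
  }

  std::vector<std::vector<int> > paths(m), cutsets(m);
  std::vector<std::vector<int> > labsets(m);
  std::vector<double> costs(m);
  double best_cost = R_PosInf;
  std::vector<int> best_path, best_labels, best_cuts;
  int best_iter = NA_INTEGER, converged_at = NA_INTEGER;

  NumericMatrix history(T, 3);
  int t_done = 0;
  for (int t = 1; t <= T; ++t) {
    double iter_best = R_PosInf, iter_sum = 0.0;
    for (int a = 0; a < m; ++a) {
      SubStream rng((uint64_t)seed, (uint64_t)t, (uint64_t)(a + 1));
      build_path(tau, dist, alpha, beta, eps_d, rng, paths[a]);
      cut_path(paths[a], dist, k, labsets[a], cutsets[a]);
      costs[a] = partition_cost(labsets[a], dist, k);
      iter_sum += costs[a];
      if (costs[a] < iter_best) iter_best = costs[a];
      if (costs[a] < best_cost) {
        best_cost = costs[a];
        best_path = paths[a];
        best_labels = labsets[a];
        best_cuts = cutsets[a];
        best_iter = t;
      }
    }
    double mc = pheromone_step(tau, paths, cutsets, costs, rho, Q, eps_d, tau_min);
    history(t - 1, 0) = iter_best;
    history(t - 1, 1) = iter_sum / m;
    history(t - 1, 2) = mc;
    t_done = t;
    if (mc < epsilon) { converged_at = t; break; }
  }

  IntegerVector bp(best_path.size()), bl(best_labels.size()), bc(best_cuts.size());
  for (size_t i = 0; i < best_path.size(); ++i) bp[i] = best_path[i] + 1;
  for (size_t i = 0; i < best_labels.size(); ++i) bl[i] = best_labels[i];
  for (size_t i = 0; i < best_cuts.size(); ++i) bc[i] = best_cuts[i];
  NumericMatrix hist(t_done, 3);
  for (int t = 0; t < t_done; ++t)
    for (int j = 0; j < 3; ++j) hist(t, j) = history(t, j);

  return List::create(
    _["best_path"] = bp, _["best_labels"] = bl, _["best_cut_edges"] = bc,
    _["best_cost"] = best_cost, _["best_iteration"] = best_iter,
    _["history"] = hist, _["converged_at"] = converged_at,
    _["iterations_run"] = t_done, _["tau"] = tau);
}
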