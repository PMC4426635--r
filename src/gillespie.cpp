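// Event-driven (Gillespie) simulation of the constant-rate birth-death
// process, plus the backward-in-time samplers built on it. All randomness
// comes from R's RNG so that set.seed() governs every routine.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static const long long MAX_REJECTIONS = 10000000LL;

// conditions: 0 = none, 1 = survival (N(T) > 0), 2 = at_least_two_at_T
struct Traj {
  std::vector<double> times;  // event times in (0, T)
  std::vector<int> types;     // +1 birth, -1 death
  int n_final;
};

static bool sim_traj_once(double lambda, double mu, double T, Traj &out) {
  out.times.clear();
  out.types.clear();
  int n = 1;
  double t = 0.0;
  const double rate_sum = lambda + mu;
  const double pbirth = lambda / rate_sum;
  while (n > 0) {
    t += exp_rand() / (n * rate_sum);
    if (t > T) break;
    int type = (unif_rand() < pbirth) ? 1 : -1;
    n += type;
    out.times.push_back(t);
    out.types.push_back(type);
  }
  out.n_final = n;
  return n > 0;
}

static bool meets_condition(const Traj &tr, int condition) {
  if (condition == 0) return true;
  if (condition == 1) return tr.n_final >= 1;
  return tr.n_final >= 2;
}

static void sim_traj_conditioned(double lambda, double mu, double T,
                                 int condition, Traj &out,
                                 long long &attempts) {
  for (long long k = 0; k < MAX_REJECTIONS; ++k) {
    ++attempts;
    sim_traj_once(lambda, mu, T, out);
    if (meets_condition(out, condition)) return;
  }
  stop("rejection guard tripped: no trajectory met the condition in 1e7 attempts");
}

// [[Rcpp::export]]
List cpp_sim_trajectory(double lambda, double mu, double T, int condition) {
  Traj tr;
  long long attempts = 0;
  sim_traj_conditioned(lambda, mu, T, condition, tr, attempts);
  int k = tr.times.size();
  NumericVector times(k);
  IntegerVector types(k), sizes(k);
  int n = 1;
  for (int i = 0; i < k; ++i) {
    times[i] = tr.times[i];
    types[i] = tr.types[i];
    n += tr.types[i];
    sizes[i] = n;
  }
  return List::create(_["times"] = times, _["types"] = types,
                      _["sizes"] = sizes, _["n_final"] = tr.n_final,
                      _["attempts"] = (double)attempts);
}

// Sizes of n conditioned trajectories read off at the given forward times.
// [[Rcpp::export]]
List cpp_trajectory_size_matrix(double lambda, double mu, double T, int n,
                                int condition, NumericVector grid) {
  IntegerMatrix sizes(n, grid.size());
  long long attempts = 0;
  Traj tr;
  for (int i = 0; i < n; ++i) {
    sim_traj_conditioned(lambda, mu, T, condition, tr, attempts);
    // piecewise-constant scan
    for (int g = 0; g < grid.size(); ++g) {
      int m = 1;
      for (size_t e = 0; e < tr.times.size() && tr.times[e] <= grid[g]; ++e)
        m += tr.types[e];
      sizes(i, g) = m;
    }
  }
  return List::create(_["sizes"] = sizes, _["attempts"] = (double)attempts);
}

// Full genealogy. Lineages are segments: a lineage starts at its birth time
// and ends when it dies, splits (into exactly two children) or reaches T.
struct TreeSim {
  std::vector<int> parent;       // -1 for the progenitor
  std::vector<double> tstart, tend;
  std::vector<int> status;       // 0 split, 1 dead, 2 extant at T
  std::vector<int> alive;        // indices of live lineages during simulation
  int n_extant;

  bool run(double lambda, double mu, double T) {
    parent.assign(1, -1);
    tstart.assign(1, 0.0);
    tend.assign(1, T);
    status.assign(1, 2);
    alive.assign(1, 0);
    double t = 0.0;
    const double rate_sum = lambda + mu;
    const double pbirth = lambda / rate_sum;
    while (!alive.empty()) {
      int n = alive.size();
      t += exp_rand() / (n * rate_sum);
      if (t > T) break;
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      int lin = alive[i];
      if (unif_rand() < pbirth) {
        tend[lin] = t;
        status[lin] = 0;
        int c1 = parent.size();
        parent.push_back(lin); tstart.push_back(t); tend.push_back(T); status.push_back(2);
        parent.push_back(lin); tstart.push_back(t); tend.push_back(T); status.push_back(2);
        alive[i] = c1;
        alive.push_back(c1 + 1);
      } else {
        tend[lin] = t;
        status[lin] = 1;
        alive[i] = alive.back();
        alive.pop_back();
      }
    }
    n_extant = alive.size();
    return n_extant > 0;
  }
};

// [[Rcpp::export]]
List cpp_sim_tree(double lambda, double mu, double T, int condition) {
  TreeSim ts;
  long long attempts = 0;
  bool ok = false;
  while (!ok) {
    if (++attempts > MAX_REJECTIONS)
      stop("rejection guard tripped: no tree met the condition in 1e7 attempts");
    ts.run(lambda, mu, T);
    ok = (condition == 0) || (condition == 1 && ts.n_extant >= 1) ||
         (condition == 2 && ts.n_extant >= 2);
  }
  int m = ts.parent.size();
  IntegerVector parent(m), status(m);
  NumericVector tstart(m), tend(m);
  for (int i = 0; i < m; ++i) {
    parent[i] = ts.parent[i] + 1;  // 1-based, 0 for progenitor
    status[i] = ts.status[i];
    tstart[i] = ts.tstart[i];
    tend[i] = ts.tend[i];
  }
  return List::create(_["parent"] = parent, _["tstart"] = tstart,
                      _["tend"] = tend, _["status"] = status,
                      _["n_extant"] = ts.n_extant,
                      _["attempts"] = (double)attempts);
}

// Backward coalescence time (from T) of two uniformly drawn extant tips.
static double pair_depth(const TreeSim &ts, double T) {
  int n = ts.n_extant;
  int ia = (int)(unif_rand() * n); if (ia == n) ia = n - 1;
  int ib = (int)(unif_rand() * (n - 1)); if (ib == n - 1) ib = n - 2;
  if (ib >= ia) ++ib;
  int a = ts.alive[ia], b = ts.alive[ib];
  std::unordered_set<int> anc;
  for (int x = a; x != -1; x = ts.parent[x]) anc.insert(x);
  int prev = b;
  for (int x = ts.parent[b]; x != -1; x = ts.parent[x]) {
    if (anc.count(x)) return T - ts.tstart[prev];  // child's start = split time
    prev = x;
  }
  return T;  // unreachable: progenitor is a common ancestor
}

// n independent trees (conditioned on >= 2 extant tips), one random pair each.
// [[Rcpp::export]]
NumericVector cpp_pair_times(double lambda, double mu, double T, int n) {
  NumericVector out(n);
  TreeSim ts;
  long long attempts = 0;
  for (int i = 0; i < n; ++i) {
    do {
      if (++attempts > MAX_REJECTIONS)
        stop("rejection guard tripped: no tree met the condition in 1e7 attempts");
      ts.run(lambda, mu, T);
    } while (ts.n_extant < 2);
    out[i] = pair_depth(ts, T);
  }
  return out;
}

// Piecewise-constant-hazard backward draw along one trajectory.
// variant: 0 -> pair rate 1/(N rho); 1 -> 1/((N-1) rho), infinite when N = 1.
static double cs_draw(const Traj &tr, double T, double rho, int variant) {
  // segment sizes going backward: [t_k, T] has size n_final, etc.
  double E = exp_rand();
  int k = tr.times.size();
  int n = tr.n_final;
  double hi = T;
  for (int e = k - 1; e >= -1; --e) {
    double lo = (e >= 0) ? tr.times[e] : 0.0;
    double d = hi - lo;
    double haz;
    if (variant == 0) {
      haz = 1.0 / (n * rho);
    } else {
      if (n <= 1) return T - hi;  // infinite hazard: coalesce on entry
      haz = 1.0 / ((n - 1.0) * rho);
    }
    if (E <= haz * d) return (T - hi) + E / haz;
    E -= haz * d;
    if (e >= 0) n -= tr.types[e];
    hi = lo;
  }
  return NA_REAL;  // traced back past the origin without coalescing
}

// [[Rcpp::export]]
NumericMatrix cpp_cs_times(double lambda, double mu, double T, double rho,
                           int variant, int n_traj, int m, int condition) {
  NumericMatrix out(n_traj, m);
  Traj tr;
  long long attempts = 0;
  for (int i = 0; i < n_traj; ++i) {
    sim_traj_conditioned(lambda, mu, T, condition, tr, attempts);
    for (int j = 0; j < m; ++j) out(i, j) = cs_draw(tr, T, rho, variant);
  }
  out.attr("attempts") = (double)attempts;
  return out;
}

// Backward draw along a trajectory supplied from R (event times/types),
// exposed for the single-trajectory sampler and its unit tests.
// [[Rcpp::export]]
NumericVector cpp_cs_draws_for_traj(NumericVector times, IntegerVector types,
                                    int n_final, double T, double rho,
                                    int variant, int m) {
  Traj tr;
  tr.times = std::vector<double>(times.begin(), times.end());
  tr.types = std::vector<int>(types.begin(), types.end());
  tr.n_final = n_final;
  NumericVector out(m);
  for (int j = 0; j < m; ++j) out[j] = cs_draw(tr, T, rho, variant);
  return out;
}
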