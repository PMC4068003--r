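#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Simulation cores for the two spiking-network models.
//
// Both models advance in synchronous 1 ms steps (1 ms effective synaptic
// delay). All randomness comes from R's RNG so that set.seed() in R makes
// every run bit-reproducible.
//
// SOC lattice: L x L non-leaky integrate-and-fire neurons, threshold Theta = 0,
// nearest-neighbour coupling alpha. A neuron with V > 0 spikes: V -= 4, each
// existing neighbour gains alpha (open boundary: edge/corner units deliver to
// only 3/2 neighbours, the remainder is dissipated). External drive sets a
// unit just above threshold (V = EPS) so that exactly one forced spike results.
//
// Branching network: n units, each active unit draws k uniformly random
// targets (with replacement, self-targets allowed); each target independently
// becomes active next step with probability p * (1 - p_diss), and a unit
// activated by >= 1 source is active exactly once.

static const double EPS = 1e-6;

// -------------------------------------------------------------------------
// SOC lattice
// -------------------------------------------------------------------------

// One synchronous lattice step. `cur` holds candidate sites (anything whose V
// may exceed 0); stamps avoid duplicates without clearing arrays.
static inline int soc_advance(std::vector<double> &V, int L,
                              double alpha,
                              std::vector<int> &cur, std::vector<int> &nxt,
                              std::vector<int> &stamp, int tick,
                              std::vector<int> *spikers) {
  nxt.clear();
  int nspike = 0;
  if (spikers) spikers->clear();
  // collect spikers first (synchronous update: all threshold tests use the
  // state at the beginning of the step)
  std::vector<int> sp;
  sp.reserve(cur.size());
  for (size_t i = 0; i < cur.size(); ++i) {
    int s = cur[i];
    if (V[s] > 0.0) sp.push_back(s);
  }
  for (size_t i = 0; i < sp.size(); ++i) {
    int s = sp[i];
    V[s] -= 4.0;
    int r = s / L, c = s % L;
    if (r > 0)     { V[s - L] += alpha; if (stamp[s - L] != tick) { stamp[s - L] = tick; nxt.push_back(s - L); } }
    if (r < L - 1) { V[s + L] += alpha; if (stamp[s + L] != tick) { stamp[s + L] = tick; nxt.push_back(s + L); } }
    if (c > 0)     { V[s - 1] += alpha; if (stamp[s - 1] != tick) { stamp[s - 1] = tick; nxt.push_back(s - 1); } }
    if (c < L - 1) { V[s + 1] += alpha; if (stamp[s + 1] != tick) { stamp[s + 1] = tick; nxt.push_back(s + 1); } }
    if (stamp[s] != tick) { stamp[s] = tick; nxt.push_back(s); }
    ++nspike;
    if (spikers) spikers->push_back(s);
  }
  cur.swap(nxt);
  return nspike;
}

// Run one avalanche to extinction from a single forced site. Returns size
// (spike count including the forced spike); duration in steps via *dur.
static int soc_cascade(std::vector<double> &V, int L, double alpha,
                       int site, double size_cap,
                       std::vector<int> &cur, std::vector<int> &nxt,
                       std::vector<int> &stamp, int &tick,
                       int *dur, bool *capped) {
  V[site] = EPS;
  cur.clear();
  ++tick; stamp[site] = tick; cur.push_back(site);
  double size = 0.0; int steps = 0;
  *capped = false;
  while (!cur.empty()) {
    ++tick;
    int ns = soc_advance(V, L, alpha, cur, nxt, stamp, tick, NULL);
    if (ns == 0) break;
    size += ns; ++steps;
    if (size > size_cap) { *capped = true; break; }
  }
  *dur = steps;
  return (int)size;
}

// [[Rcpp::export]]
List soc_sts_cpp(int L, double alpha, int n_avalanches, int transient,
                 double size_cap) {
  int N = L * L;
  std::vector<double> V(N);
  for (int i = 0; i < N; ++i) V[i] = -4.0 * unif_rand();  // uniform on [-4, 0)
  std::vector<int> cur, nxt, stamp(N, -1);
  int tick = 0;
  IntegerVector sizes(n_avalanches), durs(n_avalanches);
  LogicalVector capped(n_avalanches);
  int total = transient + n_avalanches;
  for (int a = 0; a < total; ++a) {
    int site = (int)(unif_rand() * N); if (site == N) site = N - 1;
    int dur; bool cap;
    int s = soc_cascade(V, L, alpha, site, size_cap, cur, nxt, stamp, tick,
                        &dur, &cap);
    if (a >= transient) {
      sizes[a - transient] = s;
      durs[a - transient] = dur;
      capped[a - transient] = cap;
    }
    if (a % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sizes"] = sizes, _["durations"] = durs,
                      _["capped"] = capped);
}

// [[Rcpp::export]]
List soc_driven_cpp(int L, double alpha, double h_ms, int n_steps,
                    int transient, bool record, double max_spikes) {
  int N = L * L;
  std::vector<double> V(N);
  for (int i = 0; i < N; ++i) V[i] = -4.0 * unif_rand();
  std::vector<int> cur, nxt, stamp(N, -1), forced(N, -1);
  // cur_tick marks membership of `cur` in the stamp array; it must stay the
  // tick that built `cur`, otherwise drive insertions duplicate entries
  int cur_tick = 0;
  std::vector<int> sp_t, sp_u; std::vector<unsigned char> sp_in;
  double total_sp = 0.0, input_sp = 0.0;
  std::vector<int> spikers;
  int tot = transient + n_steps;
  for (int t = 0; t < tot; ++t) {
    // Poisson drive: each unit independently forced above threshold with
    // probability h_ms this step
    int n_in = (int)R::rbinom((double)N, h_ms);
    for (int j = 0; j < n_in; ++j) {
      int site = (int)(unif_rand() * N); if (site == N) site = N - 1;
      if (V[site] <= 0.0) V[site] = EPS;
      forced[site] = t;
      if (stamp[site] != cur_tick) { stamp[site] = cur_tick; cur.push_back(site); }
    }
    int ns = soc_advance(V, L, alpha, cur, nxt, stamp, cur_tick + 1, &spikers);
    ++cur_tick;
    if (t >= transient && ns > 0) {
      for (size_t i = 0; i < spikers.size(); ++i) {
        int s = spikers[i];
        bool is_in = (forced[s] == t);
        if (is_in) input_sp += 1.0;
        if (record) {
          sp_t.push_back(t - transient);
          sp_u.push_back(s);
          sp_in.push_back(is_in ? 1 : 0);
        }
      }
      total_sp += ns;
      if (record && total_sp > max_spikes)
        stop("runaway activity: more than %.0f spikes recorded before step %d",
             max_spikes, t - transient);
    }
    if (t % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      _["total_spikes"] = total_sp, _["input_spikes"] = input_sp,
      _["n_steps"] = n_steps);
  if (record) {
    out["times"] = IntegerVector(sp_t.begin(), sp_t.end());
    out["units"] = IntegerVector(sp_u.begin(), sp_u.end());
    out["is_input"] = LogicalVector(sp_in.begin(), sp_in.end());
  }
  return out;
}

// -------------------------------------------------------------------------
// Stochastic branching network
// -------------------------------------------------------------------------

// propagate `act` one step; newly active units appended to `nxt` (deduped via
// stamp); returns number of successful activations attempted (before dedup)
static inline void branch_propagate(const std::vector<int> &act, int n, int k,
                                    double p_eff, std::vector<int> &nxt,
                                    std::vector<int> &stamp, int tick,
                                    std::vector<unsigned char> *origin_in) {
  for (size_t i = 0; i < act.size(); ++i) {
    for (int j = 0; j < k; ++j) {
      if (unif_rand() < p_eff) {
        int tgt = (int)(unif_rand() * n); if (tgt == n) tgt = n - 1;
        if (stamp[tgt] != tick) {
          stamp[tgt] = tick;
          nxt.push_back(tgt);
          if (origin_in) origin_in->push_back(0);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List branching_sts_cpp(int n, int k, double alpha, double p_diss,
                       int n_cascades, int transient, double size_cap) {
  double p_eff = (alpha / k) * (1.0 - p_diss);
  if (p_eff < 0 || p_eff > 1) stop("activation probability outside [0, 1]");
  std::vector<int> act, nxt, stamp(n, -1);
  int tick = 0;
  IntegerVector sizes(n_cascades), durs(n_cascades);
  LogicalVector capped(n_cascades);
  int total = transient + n_cascades;
  for (int a = 0; a < total; ++a) {
    int seed_unit = (int)(unif_rand() * n); if (seed_unit == n) seed_unit = n - 1;
    act.clear(); act.push_back(seed_unit);
    double size = 1.0; int steps = 0; bool cap = false;
    while (!act.empty()) {
      ++tick;
      nxt.clear();
      branch_propagate(act, n, k, p_eff, nxt, stamp, tick, NULL);
      act.swap(nxt);
      size += act.size();
      if (!act.empty()) ++steps;
      if (size > size_cap) { cap = true; break; }
    }
    if (a >= transient) {
      sizes[a - transient] = (int)size;
      durs[a - transient] = steps;
      capped[a - transient] = cap;
    }
    if (a % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sizes"] = sizes, _["durations"] = durs,
                      _["capped"] = capped);
}

// [[Rcpp::export]]
List branching_driven_cpp(int n, int k, double alpha, double p_diss,
                          double h_ms, int n_steps, int transient,
                          bool record, double max_spikes) {
  double p_eff = (alpha / k) * (1.0 - p_diss);
  if (p_eff < 0 || p_eff > 1) stop("activation probability outside [0, 1]");
  std::vector<int> act, nxt, stamp(n, -1);
  std::vector<unsigned char> orig, orig_nxt;
  int tick = 0;
  std::vector<int> sp_t, sp_u; std::vector<unsigned char> sp_in;
  double total_sp = 0.0, input_sp = 0.0;
  int tot = transient + n_steps;
  for (int t = 0; t < tot; ++t) {
    // record current actives as spikes
    if (t >= transient && !act.empty()) {
      for (size_t i = 0; i < act.size(); ++i) {
        if (orig[i]) input_sp += 1.0;
        if (record) {
          sp_t.push_back(t - transient);
          sp_u.push_back(act[i]);
          sp_in.push_back(orig[i]);
        }
      }
      total_sp += act.size();
      if (record && total_sp > max_spikes)
        stop("runaway activity: more than %.0f spikes recorded before step %d",
             max_spikes, t - transient);
    }
    // build next step: synaptic propagation, then external drive
    ++tick;
    nxt.clear(); orig_nxt.clear();
    branch_propagate(act, n, k, p_eff, nxt, stamp, tick, &orig_nxt);
    int n_in = (int)R::rbinom((double)n, h_ms);
    for (int j = 0; j < n_in; ++j) {
      int site = (int)(unif_rand() * n); if (site == n) site = n - 1;
      if (stamp[site] != tick) {
        stamp[site] = tick;
        nxt.push_back(site);
        orig_nxt.push_back(1);
      }
    }
    act.swap(nxt); orig.swap(orig_nxt);
    if (t % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
      _["total_spikes"] = total_sp, _["input_spikes"] = input_sp,
      _["n_steps"] = n_steps);
  if (record) {
    out["times"] = IntegerVector(sp_t.begin(), sp_t.end());
    out["units"] = IntegerVector(sp_u.begin(), sp_u.end());
    out["is_input"] = LogicalVector(sp_in.begin(), sp_in.end());
  }
  return out;
}
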