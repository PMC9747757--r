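#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Cortical branching model automaton.
//
// States per node: active (fired this step), refractory counter r > 0
// (cannot activate), quiescent (r == 0, not active).  A node is active for
// exactly one step, refractory for tau_r steps, then eligible again; with
// tau_r = 1 a node that fired at t may fire again at t+2.
//
// All randomness comes from R's RNG (RNGScope), so set.seed() in R gives
// bit-for-bit reproducible dynamics.  Draw order per step is fixed:
// transmission draws for active sources in ascending node index (each
// source's out-edges in stored order, one draw per edge), then spontaneous
// draws for eligible nodes in ascending index.

namespace {

struct OutEdges {
  // CSR over sources: for source i, targets/probs in [start[i], start[i+1])
  std::vector<int> start;
  std::vector<int> tgt;
  std::vector<double> p;
};

// edge_src: k_in x N, 1-based source node of each inbound edge of column j
// edge_p:   k_in x N, transmission probability kappa * p_n for that edge
OutEdges build_out_edges(const IntegerMatrix& edge_src,
                         const NumericMatrix& edge_p) {
  const int k = edge_src.nrow(), n = edge_src.ncol();
  OutEdges oe;
  std::vector<int> deg(n, 0);
  for (int j = 0; j < n; ++j)
    for (int e = 0; e < k; ++e) deg[edge_src(e, j) - 1]++;
  oe.start.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) oe.start[i + 1] = oe.start[i] + deg[i];
  oe.tgt.resize(oe.start[n]);
  oe.p.resize(oe.start[n]);
  std::vector<int> fill(oe.start.begin(), oe.start.end() - 1);
  // column-major walk => per-source edge order is by target index, stable
  for (int j = 0; j < n; ++j) {
    for (int e = 0; e < k; ++e) {
      const int i = edge_src(e, j) - 1;
      oe.tgt[fill[i]] = j;
      oe.p[fill[i]] = edge_p(e, j);
      ++fill[i];
    }
  }
  return oe;
}

// One synchronous update. active/refr are state at time t; on return they
// hold state at t+1.  newact is caller-provided scratch (zeroed on entry and
// on exit) so the hot loop does no allocation.
inline int step_once(std::vector<char>& active, std::vector<int>& refr,
                     const OutEdges& oe, double p_s, int tau_r,
                     std::vector<char>& newact) {
  const int n = (int)active.size();
  // refractory counters set at the end of the previous step count that step;
  // decrement first so tau_r steps of blocking are enforced exactly.
  for (int j = 0; j < n; ++j)
    if (!active[j] && refr[j] > 0) --refr[j];
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    for (int e = oe.start[i]; e < oe.start[i + 1]; ++e) {
      const double u = unif_rand();  // one draw per edge of an active source
      const int j = oe.tgt[e];
      if (!active[j] && refr[j] == 0 && u <= oe.p[e]) newact[j] = 1;
    }
  }
  if (p_s > 0.0) {
    for (int j = 0; j < n; ++j) {
      if (active[j] || refr[j] > 0) continue;
      if (unif_rand() <= p_s) newact[j] = 1;
    }
  }
  int count = 0;
  for (int j = 0; j < n; ++j) {
    if (active[j]) { active[j] = 0; refr[j] = tau_r; }
    if (newact[j]) { active[j] = 1; newact[j] = 0; ++count; }
  }
  return count;
}

}  // namespace

// [[Rcpp::export(name = ".cbm_run_cpp")]]
List cbm_run_cpp(IntegerMatrix edge_src, NumericMatrix edge_p,
                 double p_s, int tau_r, int n_steps, int burn_in,
                 bool keep_raster) {
  const int n = edge_src.ncol();
  OutEdges oe = build_out_edges(edge_src, edge_p);
  std::vector<char> active(n, 0), scratch(n, 0);
  std::vector<int> refr(n, 0);
  IntegerVector counts(n_steps);
  LogicalMatrix raster = keep_raster ? LogicalMatrix(n, n_steps)
                                     : LogicalMatrix(0, 0);
  for (int t = 0; t < burn_in; ++t)
    step_once(active, refr, oe, p_s, tau_r, scratch);
  for (int t = 0; t < n_steps; ++t) {
    counts[t] = step_once(active, refr, oe, p_s, tau_r, scratch);
    if (keep_raster)
      for (int j = 0; j < n; ++j) raster(j, t) = active[j] != 0;
  }
  return List::create(_["counts"] = counts, _["raster"] = raster);
}

// Sensor model for the synthetic cohort: each channel sums a few weighted
// node traces; a model step t maps to sample t * samples_per_step (model
// time is coarser than the sampling clock); each node event registers on a
// given channel only with probability p_observe (sensor subsampling), and
// registered events are convolved with a short symmetric kernel.  One
// pass, no intermediate copies; observation draws come from R's RNG in
// fixed channel-major order.
// [[Rcpp::export(name = ".mix_smooth_cpp")]]
NumericMatrix mix_smooth_cpp(LogicalMatrix raster, IntegerMatrix mix_nodes,
                             NumericMatrix mix_w, NumericVector kern,
                             int samples_per_step, double p_observe) {
  const int n_t = raster.ncol();
  const int n_samp = n_t * samples_per_step;
  const int n_ch = mix_nodes.ncol();
  const int k_mix = mix_nodes.nrow();
  const int half = ((int)kern.size() - 1) / 2;
  NumericMatrix out(n_ch, n_samp);
  for (int c = 0; c < n_ch; ++c) {
    for (int k = 0; k < k_mix; ++k) {
      const int node = mix_nodes(k, c) - 1;
      const double w = mix_w(k, c);
      for (int t = 0; t < n_t; ++t) {
        if (!raster(node, t)) continue;
        if (p_observe < 1.0 && unif_rand() > p_observe) continue;
        // uniform timing jitter within the step window: de-aliases event
        // times from the model clock, as sensor timing spread would
        int jit = (samples_per_step > 1)
                      ? (int)(unif_rand() * samples_per_step) : 0;
        if (jit >= samples_per_step) jit = samples_per_step - 1;
        const int centre = t * samples_per_step + jit;
        for (int d = -half; d <= half; ++d) {
          const int tt = centre + d;
          if (tt >= 0 && tt < n_samp) out(c, tt) += w * kern[d + half];
        }
      }
    }
  }
  return out;
}

// Seeded avalanches: p_s = 0, one random node activated, run to extinction.
// Returns per-avalanche size/duration plus the concatenated per-step count
// series (avalanches separated by a single empty step).
// [[Rcpp::export(name = ".cbm_avalanches_cpp")]]
List cbm_avalanches_cpp(IntegerMatrix edge_src, NumericMatrix edge_p,
                        int tau_r, int n_avalanches, int max_steps) {
  const int n = edge_src.ncol();
  OutEdges oe = build_out_edges(edge_src, edge_p);
  IntegerVector sizes(n_avalanches), durations(n_avalanches);
  std::vector<int> series;
  series.reserve((size_t)n_avalanches * 4);
  std::vector<char> active(n, 0), scratch(n, 0);
  std::vector<int> refr(n, 0);
  for (int a = 0; a < n_avalanches; ++a) {
    std::fill(active.begin(), active.end(), 0);
    std::fill(refr.begin(), refr.end(), 0);
    const int seed_node = (int)(unif_rand() * n) % n;
    active[seed_node] = 1;
    int size = 1, dur = 1, cur = 1;
    series.push_back(1);
    while (cur > 0 && dur < max_steps) {
      cur = step_once(active, refr, oe, 0.0, tau_r, scratch);
      if (cur > 0) { size += cur; ++dur; series.push_back(cur); }
    }
    sizes[a] = size;
    durations[a] = dur;
    series.push_back(0);
  }
  return List::create(_["sizes"] = sizes, _["durations"] = durations,
                      _["counts"] = wrap(series));
}
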