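#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

// Self-contained RNG (splitmix64) so fits are bit-reproducible across
// platforms and independent of R's global RNG state.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
};

// Model layout: `n_states[s]` states per subunit, concatenated into one
// candidate vector; `labels` gives each state's 13C count. The last state
// of each subunit is the closure-dependent one; the rest are free.
struct Layout {
  std::vector<int> n_states;
  std::vector<int> offset;      // start index of each subunit block
  std::vector<int> labels;      // flattened
  std::vector<int> free_idx;    // global indices of free variables
  int total_states, n_mass;     // n_mass = max achievable mass + 1
};

static void project(std::vector<double>& x, const Layout& L) {
  for (size_t s = 0; s < L.n_states.size(); ++s) {
    int o = L.offset[s], n = L.n_states[s];
    double sum_free = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      double v = x[o + i];
      if (v < 0.0) v = 0.0;
      if (v > 1.0) v = 1.0;
      x[o + i] = v;
      sum_free += v;
    }
    double dep = 1.0 - sum_free;
    if (dep >= 0.0) {
      x[o + n - 1] = dep;
    } else {
      x[o + n - 1] = 0.0;
      for (int i = 0; i < n - 1; ++i) x[o + i] /= sum_free;
    }
  }
}

// forward model: convolve subunit label distributions, accumulate SSE vs obs
static double objective(const std::vector<double>& x, const Layout& L,
                        const std::vector<double>& obs,
                        std::vector<double>& buf, std::vector<double>& tmp) {
  std::fill(buf.begin(), buf.end(), 0.0);
  buf[0] = 1.0;
  int cur_max = 0;
  for (size_t s = 0; s < L.n_states.size(); ++s) {
    int o = L.offset[s], n = L.n_states[s];
    int sub_max = 0;
    for (int i = 0; i < n; ++i)
      if (L.labels[o + i] > sub_max) sub_max = L.labels[o + i];
    int new_max = cur_max + sub_max;
    if (new_max >= (int)tmp.size()) new_max = (int)tmp.size() - 1;
    std::fill(tmp.begin(), tmp.begin() + new_max + 1, 0.0);
    for (int m = 0; m <= cur_max; ++m) {
      double v = buf[m];
      if (v == 0.0) continue;
      for (int i = 0; i < n; ++i) {
        int mm = m + L.labels[o + i];
        if (mm <= new_max) tmp[mm] += v * x[o + i];
      }
    }
    std::copy(tmp.begin(), tmp.begin() + new_max + 1, buf.begin());
    cur_max = new_max;
  }
  double sse = 0.0;
  for (int m = 0; m < L.n_mass; ++m) {
    double r = obs[m] - buf[m];
    sse += r * r;
  }
  return sse;
}

// [[Rcpp::export(name = ".gaims_core")]]
Rcpp::List gaims_core(Rcpp::IntegerVector n_states, Rcpp::IntegerVector labels,
                      Rcpp::NumericVector observed, int steps, int pop_size,
                      double crossover_rate, int mutations_per_step,
                      double scale_init, double scale_final, double seed) {
  Layout L;
  L.n_states = std::vector<int>(n_states.begin(), n_states.end());
  L.labels = std::vector<int>(labels.begin(), labels.end());
  L.total_states = (int)L.labels.size();
  L.n_mass = (int)observed.size();
  L.offset.resize(L.n_states.size());
  int off = 0;
  for (size_t s = 0; s < L.n_states.size(); ++s) {
    L.offset[s] = off;
    for (int i = 0; i < L.n_states[s] - 1; ++i) L.free_idx.push_back(off + i);
    off += L.n_states[s];
  }
  int n_free = (int)L.free_idx.size();
  std::vector<double> obs(observed.begin(), observed.end());
  std::vector<double> buf(L.n_mass, 0.0), tmp(L.n_mass, 0.0);

  SplitMix64 rng((uint64_t)seed);

  // population initialized uniformly on each subunit's simplex
  // (exponential spacings normalized)
  std::vector<std::vector<double> > pop(pop_size,
      std::vector<double>(L.total_states));
  std::vector<double> fit(pop_size);
  for (int p = 0; p < pop_size; ++p) {
    for (size_t s = 0; s < L.n_states.size(); ++s) {
      int o = L.offset[s], n = L.n_states[s];
      double tot = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = -std::log(1.0 - rng.unif() + 1e-300);
        pop[p][o + i] = e;
        tot += e;
      }
      for (int i = 0; i < n; ++i) pop[p][o + i] /= tot;
    }
    fit[p] = objective(pop[p], L, obs, buf, tmp);
  }

  int best_i = 0;
  for (int p = 1; p < pop_size; ++p)
    if (fit[p] < fit[best_i]) best_i = p;
  std::vector<double> best = pop[best_i];
  double best_fit = fit[best_i];

  int trace_every = steps > 200 ? steps / 200 : 1;
  std::vector<double> trace;
  trace.reserve(steps / trace_every + 2);

  std::vector<double> child(L.total_states);
  std::vector<int> perm;
  long n_eval = pop_size;

  for (int t = 0; t < steps; ++t) {
    double scale = steps > 1
      ? scale_init + (scale_final - scale_init) * ((double)t / (steps - 1))
      : scale_final;
    bool do_cross = rng.unif() < crossover_rate && pop_size >= 2;
    double child_floor = R_PosInf;  // extra acceptance bound (crossover)
    int target;  // member the child competes against (steady-state GA:
                 // members are only displaced by better children, which
                 // keeps independent basins alive until late in the run)
    if (do_cross) {
      int a = rng.unif_int(pop_size);
      int b = rng.unif_int(pop_size - 1);
      if (b >= a) ++b;
      child = pop[a];
      for (int f = 0; f < n_free; ++f)
        if (rng.unif() < 0.5) child[L.free_idx[f]] = pop[b][L.free_idx[f]];
      // recombinant replaces the worse parent only when it beats BOTH
      // parents; otherwise crossover between a converged and an exploring
      // member steadily wipes out unrefined basins
      if (fit[a] < fit[b]) { int s = a; a = b; b = s; }  // a is now worse
      target = a;
      child_floor = fit[b];  // must also improve on the better parent
    } else {
      // binary-tournament parent selection, then annealed mutation of
      // mutations_per_step distinct free variables
      int a = rng.unif_int(pop_size);
      int b = rng.unif_int(pop_size);
      target = fit[a] <= fit[b] ? a : b;
      child = pop[target];
      int nm = mutations_per_step < n_free ? mutations_per_step : n_free;
      perm.resize(n_free);
      for (int f = 0; f < n_free; ++f) perm[f] = f;
      for (int m = 0; m < nm; ++m) {
        int j = m + rng.unif_int(n_free - m);
        std::swap(perm[m], perm[j]);
        int idx = L.free_idx[perm[m]];
        child[idx] += (2.0 * rng.unif() - 1.0) * scale;
      }
    }
    project(child, L);
    double f = objective(child, L, obs, buf, tmp);
    ++n_eval;
    if (f < fit[target] && f < child_floor) {
      pop[target] = child;
      fit[target] = f;
      if (f < best_fit) {     // strict: ties keep the earlier find
        best_fit = f;
        best = child;
      }
    }
    if (t % trace_every == 0) trace.push_back(best_fit);
  }
  trace.push_back(best_fit);

  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::NumericVector(best.begin(), best.end()),
    Rcpp::Named("objective") = best_fit,
    Rcpp::Named("trace") = Rcpp::NumericVector(trace.begin(), trace.end()),
    Rcpp::Named("evaluations") = (double)n_eval);
}
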