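// Exact SSA for the temporal logic gate CTMC over (DNA state, IntA, IntB).
//
// Induction profiles are piecewise constant, so rates are constant between
// profile breakpoints; a sampled waiting time that overshoots the active
// segment's end is discarded and the clock restarted at the breakpoint
// (valid by memorylessness of the exponential).
//
// RNG: std::mt19937_64 seeded per cell via splitmix64(splitmix64(seed) + i).
// mt19937_64 output is fully specified by the standard and uniform/exponential
// draws use explicit inverse transforms, so trajectories are reproducible
// across platforms.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// DNA codes: 0 = S_o, 1 = S_a, 2 = S_b, 3 = S_ab

struct Pars {
  double kprodA, kprodB, kleakA, kleakB, kdeg;
  double kflipA, kflipB, kflipB_exc, KdA, KdB;
};

static Pars read_pars(const List& params) {
  Pars p;
  p.kprodA = as<double>(params["kprodA"]);
  p.kprodB = as<double>(params["kprodB"]);
  p.kleakA = as<double>(params["kleakA"]);
  p.kleakB = as<double>(params["kleakB"]);
  p.kdeg = as<double>(params["kdeg"]);
  p.kflipA = as<double>(params["kflipA"]);
  p.kflipB = as<double>(params["kflipB"]);
  p.kflipB_exc = as<double>(params["kflipB_exc"]);
  p.KdA = as<double>(params["KdA"]);
  p.KdB = as<double>(params["KdB"]);
  return p;
}

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(std::uint64_t seed) : gen(seed) {}
  // uniform in (0, 1), 53-bit resolution, never exactly 0 or 1
  double unif() {
    return (static_cast<double>(gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp(double rate) { return -std::log(unif()) / rate; }
};

static inline std::uint64_t cell_seed(double seed, int index) {
  std::uint64_t s = splitmix64(static_cast<std::uint64_t>(seed));
  return splitmix64(s + static_cast<std::uint64_t>(index));
}

// Saturating tetramerization propensity: zero below 4 monomers, -> kflip as
// n -> infinity.
static inline double tetramer(double n, double kflip, double Kd) {
  if (n < 4.0 || kflip <= 0.0) return 0.0;
  double f1 = n;
  double f2 = n * (n - 1.0);
  double f3 = f2 * (n - 2.0);
  double f4 = f3 * (n - 3.0);
  double K2 = Kd * Kd, K3 = K2 * Kd, K4 = K3 * Kd;
  return kflip * f4 / (K4 + K3 * f1 + K2 * f2 + Kd * f3 + f4);
}

struct CellOut {
  int final_dna;
  int n_flips;
  double flip_t[2];
  int flip_to[2];
};

// One-cell SSA. Optionally records the full event list and/or the DNA state
// and integrase counts on a fixed time grid (state after last event <= t).
static void sim_cell(const Pars& p,
                     const std::vector<double>& seg_end,
                     const std::vector<int>& ua, const std::vector<int>& ub,
                     double t_end, Rng& rng, double max_events, CellOut& out,
                     std::vector<double>* ev_t, std::vector<int>* ev_dna,
                     std::vector<int>* ev_a, std::vector<int>* ev_b,
                     const double* grid, int n_grid,
                     int* g_dna, int* g_a, int* g_b) {
  double t = 0.0;
  int dna = 0, nA = 0, nB = 0;
  std::size_t seg = 0;
  double n_events = 0.0;
  int gj = 0;
  out.n_flips = 0;

  while (t < t_end) {
    double bA = p.kprodA * ua[seg] + p.kleakA;
    double bB = p.kprodB * ub[seg] + p.kleakB;
    double dA = p.kdeg * nA;
    double dB = p.kdeg * nB;
    double a1 = 0.0, a2 = 0.0, a3 = 0.0;
    if (dna == 0) {
      a2 = tetramer(nA, p.kflipA, p.KdA);
      a1 = tetramer(nB, p.kflipB_exc, p.KdB);
    } else if (dna == 1) {
      a3 = tetramer(nB, p.kflipB, p.KdB);
    }
    double tot = bA + bB + dA + dB + a1 + a2 + a3;
    double send = seg_end[seg];

    double t_new;
    bool is_jump;
    if (tot <= 0.0) {
      t_new = send;
      is_jump = true;
    } else {
      double tau = rng.rexp(tot);
      if (t + tau >= send) {
        t_new = send;
        is_jump = true;
      } else {
        t_new = t + tau;
        is_jump = false;
      }
    }

    // grid points strictly before the next event/breakpoint carry the
    // current state; a grid point exactly at an event time gets the
    // post-event state on a later pass
    while (gj < n_grid && grid[gj] < t_new) {
      if (g_dna) g_dna[gj] = dna;
      if (g_a) { g_a[gj] = nA; g_b[gj] = nB; }
      ++gj;
    }

    if (is_jump) {
      t = t_new;
      if (seg + 1 < seg_end.size()) ++seg;
      continue;
    }

    t = t_new;
    double u = rng.unif() * tot;
    if (u < bA) {
      ++nA;
    } else if (u < bA + bB) {
      ++nB;
    } else if (u < bA + bB + dA) {
      --nA;
    } else if (u < bA + bB + dA + dB) {
      --nB;
    } else if (u < bA + bB + dA + dB + a2) {
      dna = 1;
      out.flip_t[out.n_flips] = t; out.flip_to[out.n_flips] = dna;
      ++out.n_flips;
    } else if (u < bA + bB + dA + dB + a2 + a1) {
      dna = 2;
      out.flip_t[out.n_flips] = t; out.flip_to[out.n_flips] = dna;
      ++out.n_flips;
    } else {
      dna = 3;
      out.flip_t[out.n_flips] = t; out.flip_to[out.n_flips] = dna;
      ++out.n_flips;
    }

    if (ev_t) {
      ev_t->push_back(t);
      ev_dna->push_back(dna);
      ev_a->push_back(nA);
      ev_b->push_back(nB);
    }

    if (++n_events > max_events)
      stop("event-count guard exceeded (max_events = %.0f); "
           "rates may be runaway or t_end too large", max_events);
  }

  while (gj < n_grid) {
    if (g_dna) g_dna[gj] = dna;
    if (g_a) { g_a[gj] = nA; g_b[gj] = nB; }
    ++gj;
  }
  out.final_dna = dna;
}

// [[Rcpp::export]]
List cpp_simulate_cell(List params, NumericVector seg_end,
                       IntegerVector ua, IntegerVector ub,
                       double t_end, double seed, int cell_index,
                       double max_events) {
  Pars p = read_pars(params);
  std::vector<double> se(seg_end.begin(), seg_end.end());
  std::vector<int> va(ua.begin(), ua.end()), vb(ub.begin(), ub.end());
  Rng rng(cell_seed(seed, cell_index));
  CellOut out;
  std::vector<double> ev_t;
  std::vector<int> ev_dna, ev_a, ev_b;
  sim_cell(p, se, va, vb, t_end, rng, max_events, out,
           &ev_t, &ev_dna, &ev_a, &ev_b, nullptr, 0,
           nullptr, nullptr, nullptr);
  return List::create(
    _["time"] = wrap(ev_t), _["dna"] = wrap(ev_dna),
    _["intA"] = wrap(ev_a), _["intB"] = wrap(ev_b),
    _["final_dna"] = out.final_dna);
}

// [[Rcpp::export]]
List cpp_simulate_ensemble(List params, NumericVector seg_end,
                           IntegerVector ua, IntegerVector ub,
                           double t_end, int n_cells, double seed,
                           NumericVector grid, bool record_counts,
                           double max_events) {
  Pars p = read_pars(params);
  std::vector<double> se(seg_end.begin(), seg_end.end());
  std::vector<int> va(ua.begin(), ua.end()), vb(ub.begin(), ub.end());
  int n_grid = grid.size();

  IntegerVector final_dna(n_cells);
  NumericMatrix flip_time(n_cells, 2);
  IntegerMatrix flip_to(n_cells, 2);
  std::fill(flip_time.begin(), flip_time.end(), NA_REAL);
  std::fill(flip_to.begin(), flip_to.end(), NA_INTEGER);

  IntegerMatrix g_dna, g_a, g_b;
  if (n_grid > 0) {
    g_dna = IntegerMatrix(n_cells, n_grid);
    if (record_counts) {
      g_a = IntegerMatrix(n_cells, n_grid);
      g_b = IntegerMatrix(n_cells, n_grid);
    }
  }

  std::vector<int> row_dna(n_grid), row_a(n_grid), row_b(n_grid);
  for (int i = 0; i < n_cells; ++i) {
    if (i % 512 == 0) checkUserInterrupt();
    Rng rng(cell_seed(seed, i + 1));
    CellOut out;
    try {
      sim_cell(p, se, va, vb, t_end, rng, max_events, out,
               nullptr, nullptr, nullptr, nullptr,
               n_grid > 0 ? REAL(grid) : nullptr, n_grid,
               n_grid > 0 ? row_dna.data() : nullptr,
               (n_grid > 0 && record_counts) ? row_a.data() : nullptr,
               (n_grid > 0 && record_counts) ? row_b.data() : nullptr);
    } catch (std::exception& e) {
      stop("cell %d: %s", i + 1, e.what());
    }
    final_dna[i] = out.final_dna;
    for (int k = 0; k < out.n_flips; ++k) {
      flip_time(i, k) = out.flip_t[k];
      flip_to(i, k) = out.flip_to[k];
    }
    for (int j = 0; j < n_grid; ++j) {
      g_dna(i, j) = row_dna[j];
      if (record_counts) { g_a(i, j) = row_a[j]; g_b(i, j) = row_b[j]; }
    }
  }

  List res = List::create(
    _["final_dna"] = final_dna,
    _["flip_time"] = flip_time,
    _["flip_to"] = flip_to);
  if (n_grid > 0) {
    res["dna_grid"] = g_dna;
    if (record_counts) {
      res["intA_grid"] = g_a;
      res["intB_grid"] = g_b;
    }
  }
  return res;
}
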