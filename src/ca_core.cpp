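// Core lattice engines for the stochastic tumor-growth cellular automaton.
//
// Per-cell rule: one uniform draw rr partitions fate —
//   [0, p_signal)            proliferation-signal branch (PH++, divide if PH >= NP)
//   [p_signal, p_survive)    migration branch (second draw vs p_migrate)
//   [p_survive, 1)           death
// Candidate targets for division/migration are scanned in RNG-shuffled
// order; the first empty in-bounds site wins. Out-of-bounds sites are
// treated as permanently occupied (fixed borders).
//
// The sequential engines consume R's global RNG (set.seed-reproducible).
// The parallel engine uses one splitmix64 stream per (seed, region, step)
// so the serialized phase schedule is reproducible for fixed t.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

enum FateKind { FATE_DIE = 0, FATE_QUIESCENT = 1, FATE_PROLIFERATE = 2, FATE_MIGRATE = 3 };

struct Params {
  double p_survive, p_signal, p_migrate;
  int np, ph_init, delta;
  bool moore;
};

static Params as_params(const List& p) {
  Params pp;
  pp.p_survive = as<double>(p["p_survive"]);
  pp.p_signal  = as<double>(p["p_signal"]);
  pp.p_migrate = as<double>(p["p_migrate"]);
  pp.np        = as<int>(p["np_threshold"]);
  pp.ph_init   = as<int>(p["ph_init"]);
  pp.delta     = as<int>(p["delta"]);
  std::string nb = as<std::string>(p["neighborhood"]);
  pp.moore = (nb == "moore");
  return pp;
}

// R global stream, [0,1)
struct RRng {
  double operator()() { return unif_rand(); }
};

// splitmix64 stream; used for per-worker streams in the parallel engine
struct SMRng {
  uint64_t s;
  explicit SMRng(uint64_t seed) : s(seed) {}
  double operator()() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return (double)(z >> 11) * (1.0 / 9007199254740992.0); // 2^-53
  }
};

static uint64_t mix_seed(uint64_t master, uint64_t region, uint64_t step) {
  uint64_t x = master * 0x9E3779B97F4A7C15ULL;
  x ^= (region + 1) * 0xBF58476D1CE4E5B9ULL;
  x ^= (step + 1) * 0x94D049BB133111EBULL;
  // one splitmix round to decorrelate nearby keys
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Shuffle candidate directions, return first empty in-bounds site.
template <class RNG>
static bool find_empty_target(int r, int c, const IntegerMatrix& lat,
                              const Params& pp, RNG& rng, int& tr, int& tc) {
  const int k = pp.moore ? 8 : 4;
  const int* DR = pp.moore ? DR8 : DR4;
  const int* DC = pp.moore ? DC8 : DC4;
  int idx[8];
  for (int i = 0; i < k; ++i) idx[i] = i;
  for (int i = k - 1; i >= 1; --i) { // Fisher-Yates, one draw per swap
    int j = (int)(rng() * (i + 1));
    if (j > i) j = i;
    int tmp = idx[i]; idx[i] = idx[j]; idx[j] = tmp;
  }
  const int nr = lat.nrow(), nc = lat.ncol();
  for (int i = 0; i < k; ++i) {
    int rr2 = r + DR[idx[i]], cc2 = c + DC[idx[i]];
    if (rr2 < 0 || rr2 >= nr || cc2 < 0 || cc2 >= nc) continue; // border: blocked
    if (lat(rr2, cc2) == 0) { tr = rr2; tc = cc2; return true; }
  }
  return false;
}

// One cell, 0-based coords. May mutate ph (signal / reset on division).
// Target (tr, tc) set iff fate is PROLIFERATE or MIGRATE.
template <class RNG>
static int evaluate_core(int r, int c, int& ph, const IntegerMatrix& lat,
                         const Params& pp, RNG& rng, int& tr, int& tc) {
  double rr = rng();
  if (rr >= pp.p_survive) return FATE_DIE;
  if (rr < pp.p_signal) {
    ++ph;
    if (ph >= pp.np && find_empty_target(r, c, lat, pp, rng, tr, tc)) {
      ph = 0;
      return FATE_PROLIFERATE;
    }
    return FATE_QUIESCENT;
  }
  double rrm = rng();
  if (rrm < pp.p_migrate && find_empty_target(r, c, lat, pp, rng, tr, tc))
    return FATE_MIGRATE;
  return FATE_QUIESCENT;
}

// Apply a fate in place; push surviving records (r, c, ph triples, 0-based)
// onto `out`. Targets chosen as empty may have been taken meanwhile by an
// earlier cell this step; the cell then stays quiescent.
static void apply_core(int r, int c, int ph, int fate, int tr, int tc,
                       IntegerMatrix& lat, const Params& pp,
                       std::vector<int>& out) {
  if (fate == FATE_DIE) {
    lat(r, c) = 0;
    return;
  }
  if (fate == FATE_MIGRATE && lat(tr, tc) == 0) {
    lat(r, c) = 0;
    lat(tr, tc) = 1;
    out.push_back(tr); out.push_back(tc); out.push_back(ph);
    return;
  }
  if (fate == FATE_PROLIFERATE && lat(tr, tc) == 0) {
    lat(tr, tc) = 1;
    out.push_back(r);  out.push_back(c);  out.push_back(ph);
    out.push_back(tr); out.push_back(tc); out.push_back(pp.ph_init);
    return;
  }
  // quiescent, or a blocked migration/division target
  out.push_back(r); out.push_back(c); out.push_back(ph);
}

static IntegerMatrix triples_to_matrix(const std::vector<int>& v) {
  const int n = (int)(v.size() / 3);
  IntegerMatrix m(n, 3);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = v[3 * i] + 1; // back to 1-based
    m(i, 1) = v[3 * i + 1] + 1;
    m(i, 2) = v[3 * i + 2];
  }
  colnames(m) = CharacterVector::create("row", "col", "ph");
  return m;
}

// [[Rcpp::export]]
List cpp_evaluate_cell(int row, int col, int ph, IntegerMatrix lattice, List params) {
  Params pp = as_params(params);
  int r = row - 1, c = col - 1;
  if (r < 0 || r >= lattice.nrow() || c < 0 || c >= lattice.ncol())
    stop("cell (%d, %d) is outside the lattice", row, col);
  if (lattice(r, c) != 1)
    stop("lattice site (%d, %d) is empty; cannot evaluate a cell there", row, col);
  RRng rng;
  int tr = -1, tc = -1;
  int fate = evaluate_core(r, c, ph, lattice, pp, rng, tr, tc);
  bool has_target = (fate == FATE_PROLIFERATE || fate == FATE_MIGRATE);
  return List::create(
    _["kind"] = fate,
    _["target_row"] = has_target ? IntegerVector::create(tr + 1) : IntegerVector(0),
    _["target_col"] = has_target ? IntegerVector::create(tc + 1) : IntegerVector(0),
    _["ph"] = ph);
}

// [[Rcpp::export]]
List cpp_apply_fate(int row, int col, int ph, int kind,
                    IntegerVector target_row, IntegerVector target_col,
                    IntegerMatrix lattice, List params) {
  Params pp = as_params(params);
  IntegerMatrix lat = clone(lattice);
  int r = row - 1, c = col - 1;
  if (r < 0 || r >= lat.nrow() || c < 0 || c >= lat.ncol() || lat(r, c) != 1)
    stop("fate does not match an occupied lattice site at (%d, %d)", row, col);
  bool needs_target = (kind == FATE_PROLIFERATE || kind == FATE_MIGRATE);
  if (needs_target && (target_row.size() != 1 || target_col.size() != 1))
    stop("fate of kind %d requires a target site", kind);
  int tr = needs_target ? target_row[0] - 1 : -1;
  int tc = needs_target ? target_col[0] - 1 : -1;
  std::vector<int> out;
  apply_core(r, c, ph, kind, tr, tc, lat, pp, out);
  return List::create(_["cells"] = triples_to_matrix(out), _["lattice"] = lat);
}

// Fate tally for a lone cell with an empty neighborhood, n independent
// evaluations, fresh PH = ph_init each time. Analytic-oracle check support.
// [[Rcpp::export]]
IntegerVector cpp_tally_fates(List params, int n) {
  Params pp = as_params(params);
  IntegerMatrix lat(5, 5);
  lat(2, 2) = 1;
  RRng rng;
  IntegerVector counts(4);
  for (int i = 0; i < n; ++i) {
    int ph = pp.ph_init, tr, tc;
    int fate = evaluate_core(2, 2, ph, lat, pp, rng, tr, tc);
    counts[fate]++;
  }
  counts.names() = CharacterVector::create("DIE", "QUIESCENT", "PROLIFERATE", "MIGRATE");
  return counts;
}

// One step of the list engine (oracle = false) or the naive row-major
// full-grid-scan engine (oracle = true). `cells` is n x 3 (row, col, ph),
// 1-based. Returns the mutated lattice copy and the next list.
// [[Rcpp::export]]
List cpp_step(IntegerMatrix lattice, IntegerMatrix cells, List params, bool oracle) {
  Params pp = as_params(params);
  IntegerMatrix lat = clone(lattice);
  const int n = cells.nrow();
  std::vector<int> next;
  next.reserve((size_t)n * 3 + 64);
  RRng rng;
  if (!oracle) {
    for (int i = 0; i < n; ++i) {
      int r = cells(i, 0) - 1, c = cells(i, 1) - 1, ph = cells(i, 2);
      int tr = -1, tc = -1;
      int fate = evaluate_core(r, c, ph, lat, pp, rng, tr, tc);
      apply_core(r, c, ph, fate, tr, tc, lat, pp, next);
    }
  } else {
    // Snapshot start-of-step occupancy + PH, then scan every lattice site in
    // row-major order; evaluate (and spend RNG on) live start-of-step cells
    // only, against the live, in-place-updated lattice.
    const int nr = lat.nrow(), nc = lat.ncol();
    IntegerMatrix ph_grid(nr, nc);
    LogicalMatrix snap(nr, nc);
    for (int i = 0; i < n; ++i) {
      int r = cells(i, 0) - 1, c = cells(i, 1) - 1;
      snap(r, c) = true;
      ph_grid(r, c) = cells(i, 2);
    }
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!snap(r, c)) continue;
        int ph = ph_grid(r, c), tr = -1, tc = -1;
        int fate = evaluate_core(r, c, ph, lat, pp, rng, tr, tc);
        apply_core(r, c, ph, fate, tr, tc, lat, pp, next);
      }
    }
  }
  return List::create(
    _["lattice"] = lat,
    _["cells"] = triples_to_matrix(next),
    _["processed"] = n);
}

// n_steps of the list engine with per-step metrics, all in compiled code.
// metrics: column 1 = cells processed (list length consumed), column 2 =
// live cells after the step.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix lattice, IntegerMatrix cells, List params, int n_steps) {
  Params pp = as_params(params);
  IntegerMatrix lat = clone(lattice);
  std::vector<int> cur;
  cur.reserve((size_t)cells.nrow() * 3 + 64);
  for (int i = 0; i < cells.nrow(); ++i) {
    cur.push_back(cells(i, 0) - 1);
    cur.push_back(cells(i, 1) - 1);
    cur.push_back(cells(i, 2));
  }
  IntegerMatrix metrics(n_steps, 2);
  RRng rng;
  std::vector<int> next;
  for (int s = 0; s < n_steps; ++s) {
    const int n = (int)(cur.size() / 3);
    next.clear();
    next.reserve(cur.size() + 64);
    for (int i = 0; i < n; ++i) {
      int r = cur[3 * i], c = cur[3 * i + 1], ph = cur[3 * i + 2];
      int tr = -1, tc = -1;
      int fate = evaluate_core(r, c, ph, lat, pp, rng, tr, tc);
      apply_core(r, c, ph, fate, tr, tc, lat, pp, next);
    }
    cur.swap(next);
    metrics(s, 0) = n;
    metrics(s, 1) = (int)(cur.size() / 3);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(metrics) = CharacterVector::create("processed", "live");
  return List::create(
    _["lattice"] = lat,
    _["cells"] = triples_to_matrix(cur),
    _["metrics"] = metrics);
}

// ---------------------------------------------------------------------------
// Phase-ordered parallel step (serialized realization of the t-worker
// contract). geom is t x 6 (1-based half-open row bands): top_start, top_end,
// center_start, center_end, bottom_start, bottom_end; empty part <=> start ==
// end. region_lists is a list of t lists, each with elements top/center/
// bottom (n x 3 cell matrices, 1-based). Phases run bottom seams, then
// centers, then top seams, a barrier between; worker i owns region i's list
// of the phase's part type and a splitmix64 stream keyed on (seed, i, step).
// Outputs are routed to the next list of the subregion holding the cell's
// (possibly new) position under the CURRENT geometry — stale list membership
// is reconciled lazily. Ownership tags verify no next-list is written by two
// workers within one phase.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_parallel_step(IntegerMatrix lattice, IntegerMatrix geom, List region_lists,
                       List params, double master_seed, int step_index) {
  Params pp = as_params(params);
  IntegerMatrix lat = clone(lattice);
  const int t = geom.nrow();
  const int n_rows = lat.nrow();
  const int PART_TOP = 0, PART_CENTER = 1, PART_BOTTOM = 2;

  // row (0-based) -> subregion id = 3 * region + part, under current geometry
  std::vector<int> row_sub(n_rows, -1);
  for (int i = 0; i < t; ++i) {
    for (int p = 0; p < 3; ++p) {
      int s = geom(i, 2 * p) - 1, e = geom(i, 2 * p + 1) - 1;
      for (int r = s; r < e; ++r) {
        if (r < 0 || r >= n_rows) stop("partition geometry leaves the lattice");
        if (row_sub[r] != -1) stop("partition geometry overlaps at row %d", r + 1);
        row_sub[r] = 3 * i + p;
      }
    }
  }
  for (int r = 0; r < n_rows; ++r)
    if (row_sub[r] == -1) stop("partition geometry does not cover row %d", r + 1);

  std::vector<SMRng> streams;
  streams.reserve(t);
  for (int i = 0; i < t; ++i)
    streams.emplace_back(mix_seed((uint64_t)master_seed, (uint64_t)i, (uint64_t)step_index));

  std::vector<std::vector<int> > next(3 * t);
  std::vector<int> writer(3 * t, -1);     // ownership tag within current phase
  std::vector<int> processed(t, 0);
  int violations = 0;

  const char* part_names[3] = {"top", "center", "bottom"};
  const int phase_order[3] = {PART_BOTTOM, PART_CENTER, PART_TOP};

  for (int ph_i = 0; ph_i < 3; ++ph_i) {
    const int part = phase_order[ph_i];
    std::fill(writer.begin(), writer.end(), -1); // barrier: new phase, new tags
    for (int i = 0; i < t; ++i) {               // serialized workers
      List rl = region_lists[i];
      IntegerMatrix m = rl[part_names[part]];
      SMRng& rng = streams[i];
      for (int k = 0; k < m.nrow(); ++k) {
        int r = m(k, 0) - 1, c = m(k, 1) - 1, ph = m(k, 2);
        int tr = -1, tc = -1;
        int fate = evaluate_core(r, c, ph, lat, pp, rng, tr, tc);
        std::vector<int> out;
        apply_core(r, c, ph, fate, tr, tc, lat, pp, out);
        for (size_t j = 0; j + 2 < out.size(); j += 3) {
          int sub = row_sub[out[j]];
          if (writer[sub] != -1 && writer[sub] != i) ++violations;
          writer[sub] = i;
          next[sub].push_back(out[j]);
          next[sub].push_back(out[j + 1]);
          next[sub].push_back(out[j + 2]);
        }
      }
      processed[i] += m.nrow();
    }
  }

  List out_lists(t);
  for (int i = 0; i < t; ++i) {
    out_lists[i] = List::create(
      _["top"] = triples_to_matrix(next[3 * i + PART_TOP]),
      _["center"] = triples_to_matrix(next[3 * i + PART_CENTER]),
      _["bottom"] = triples_to_matrix(next[3 * i + PART_BOTTOM]));
  }
  return List::create(
    _["lattice"] = lat,
    _["region_lists"] = out_lists,
    _["processed"] = wrap(processed),
    _["ownership_violations"] = violations);
}
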