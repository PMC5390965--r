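// Core simulation routines for the coding-theorem machinery.
//
// Machine formalism: (n states, k symbols) Turing machines with a
// distinguished halt target.  Each transition entry, indexed by
// (state, read symbol), is either (write, move, next state) or
// (write, halt).  1-D machines move left/right on a blank (symbol 0)
// tape; 2-D machines ("turmites") move up/down/left/right on a blank
// grid.  Entry option counts are therefore 2kn + k (1-D) and
// 4kn + k (2-D), giving (2kn+k)^(nk) machines in a 1-D space —
// e.g. 22^10 for (5,2) and 10^4 for (2,2).
//
// Output convention: at halt, the tape segment (minimal bounding
// rectangle in 2-D) spanned by every position the head occupied,
// read left-to-right (row-major in 2-D).  A machine halting on its
// first step outputs the single origin cell.  Runs not halting
// within step_cap are excluded entirely.
//
// All sampling uses a self-contained mt19937 stream with rejection
// sampling for bounded draws, so results are reproducible across
// platforms for a given seed.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// bounded uniform draw in [0, n) by rejection (implementation-independent,
// unlike std::uniform_int_distribution)
inline uint32_t draw_below(std::mt19937 &rng, uint32_t n) {
  // accept u in [0, floor(2^32/n)*n)
  const uint64_t span = (uint64_t(UINT32_MAX) + 1) / n * n;
  uint32_t u;
  do {
    u = rng();
  } while (uint64_t(u) >= span);
  return u % n;
}

inline double draw_unif01(std::mt19937 &rng) {
  // 32 random bits; plenty for categorical draws here
  return (double(rng()) + 0.5) / 4294967296.0;
}

// relabel symbols of a digit string by order of first occurrence,
// skipping any '/' row separators
std::string canonicalize_key(const std::string &s) {
  int map[16];
  for (int i = 0; i < 16; ++i) map[i] = -1;
  int next = 0;
  std::string out(s);
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] == '/') continue;
    int v = s[i] - '0';
    if (map[v] < 0) map[v] = next++;
    out[i] = char('0' + map[v]);
  }
  return out;
}

struct Dist {
  std::unordered_map<std::string, double> counts;
  double total_halting = 0.0;
  double n_run = 0.0;
  int max_steps = 0; // max steps over halting runs
};

// ---------------------------------------------------------------- 1-D ----

struct Sim1D {
  int n, k, cap;
  std::vector<int> tape;
  int origin;
  Sim1D(int n_, int k_, int cap_) : n(n_), k(k_), cap(cap_) {
    tape.assign(2 * cap + 3, 0);
    origin = cap + 1;
  }

  // entries: length n*k, values in [0, 2kn + k)
  // returns true if halted; fills key and steps
  bool run(const std::vector<int> &entries, std::string &key, int &steps) {
    const int halt_base = 2 * k * n;
    int pos = origin, q = 0, lo = origin, hi = origin;
    bool halted = false;
    int st = 0;
    while (st < cap) {
      ++st;
      int sym = tape[pos];
      int e = entries[q * k + sym];
      if (e >= halt_base) {
        tape[pos] = e - halt_base;
        halted = true;
        break;
      }
      int w = e % k;
      int t = e / k;
      int dir = t % 2; // 0 = left, 1 = right
      q = t / 2;
      tape[pos] = w;
      pos += dir ? 1 : -1;
      if (pos < lo) lo = pos;
      if (pos > hi) hi = pos;
    }
    if (halted) {
      key.clear();
      key.reserve(hi - lo + 1);
      for (int i = lo; i <= hi; ++i) key.push_back(char('0' + tape[i]));
      key = canonicalize_key(key);
      steps = st;
    }
    for (int i = lo; i <= hi; ++i) tape[i] = 0;
    return halted;
  }
};

// ---------------------------------------------------------------- 2-D ----

struct Sim2D {
  int n, k, cap, side;
  std::vector<int> grid;
  int origin;
  Sim2D(int n_, int k_, int cap_) : n(n_), k(k_), cap(cap_) {
    side = 2 * cap + 3;
    grid.assign(size_t(side) * side, 0);
    origin = cap + 1;
  }

  bool run(const std::vector<int> &entries, std::string &key, int &steps) {
    const int halt_base = 4 * k * n;
    int r = origin, c = origin, q = 0;
    int rlo = r, rhi = r, clo = c, chi = c;
    bool halted = false;
    int st = 0;
    while (st < cap) {
      ++st;
      int sym = grid[size_t(r) * side + c];
      int e = entries[q * k + sym];
      if (e >= halt_base) {
        grid[size_t(r) * side + c] = e - halt_base;
        halted = true;
        break;
      }
      int w = e % k;
      int t = e / k;
      int dir = t % 4; // 0 up, 1 down, 2 left, 3 right
      q = t / 4;
      grid[size_t(r) * side + c] = w;
      switch (dir) {
      case 0: --r; break;
      case 1: ++r; break;
      case 2: --c; break;
      default: ++c;
      }
      if (r < rlo) rlo = r;
      if (r > rhi) rhi = r;
      if (c < clo) clo = c;
      if (c > chi) chi = c;
    }
    if (halted) {
      key.clear();
      key.reserve(size_t(rhi - rlo + 1) * (chi - clo + 2));
      for (int i = rlo; i <= rhi; ++i) {
        if (i > rlo) key.push_back('/');
        for (int j = clo; j <= chi; ++j)
          key.push_back(char('0' + grid[size_t(i) * side + j]));
      }
      key = canonicalize_key(key);
      steps = st;
    }
    for (int i = rlo; i <= rhi; ++i)
      for (int j = clo; j <= chi; ++j) grid[size_t(i) * side + j] = 0;
    return halted;
  }
};

List dist_to_list(const Dist &d) {
  const size_t m = d.counts.size();
  CharacterVector keys(m);
  NumericVector counts(m);
  size_t i = 0;
  for (const auto &kv : d.counts) {
    keys[i] = kv.first;
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["key"] = keys, _["count"] = counts,
                      _["total_halting"] = d.total_halting,
                      _["n_machines"] = d.n_run,
                      _["max_steps_halting"] = d.max_steps);
}

} // namespace

// [[Rcpp::export]]
List cpp_enumerate(int n_states, int n_symbols, int dimension, int step_cap) {
  const int nk = n_states * n_symbols;
  const int base = (dimension == 2 ? 4 : 2) * n_symbols * n_states + n_symbols;
  Dist d;
  std::vector<int> entries(nk, 0);
  std::string key;
  int steps = 0;
  Sim1D s1(n_states, n_symbols, step_cap);
  Sim2D s2(dimension == 2 ? n_states : 1, n_symbols,
           dimension == 2 ? step_cap : 1);
  bool more = true;
  uint32_t tick = 0;
  while (more) {
    bool halted = dimension == 2 ? s2.run(entries, key, steps)
                                 : s1.run(entries, key, steps);
    d.n_run += 1.0;
    if (halted) {
      d.counts[key] += 1.0;
      d.total_halting += 1.0;
      if (steps > d.max_steps) d.max_steps = steps;
    }
    // mixed-radix increment
    int i = 0;
    for (; i < nk; ++i) {
      if (++entries[i] < base) break;
      entries[i] = 0;
    }
    more = i < nk;
    if ((++tick & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return dist_to_list(d);
}

// [[Rcpp::export]]
List cpp_sample(int n_states, int n_symbols, int dimension, int step_cap,
                double sample_size, int seed) {
  const int nk = n_states * n_symbols;
  const uint32_t base =
      (dimension == 2 ? 4 : 2) * n_symbols * n_states + n_symbols;
  std::mt19937 rng{uint32_t(seed)};
  Dist d;
  std::vector<int> entries(nk, 0);
  std::string key;
  int steps = 0;
  Sim1D s1(n_states, n_symbols, step_cap);
  Sim2D s2(dimension == 2 ? n_states : 1, n_symbols,
           dimension == 2 ? step_cap : 1);
  uint32_t tick = 0;
  for (double m = 0; m < sample_size; m += 1.0) {
    for (int i = 0; i < nk; ++i) entries[i] = int(draw_below(rng, base));
    bool halted = dimension == 2 ? s2.run(entries, key, steps)
                                 : s1.run(entries, key, steps);
    d.n_run += 1.0;
    if (halted) {
      d.counts[key] += 1.0;
      d.total_halting += 1.0;
      if (steps > d.max_steps) d.max_steps = steps;
    }
    if ((++tick & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return dist_to_list(d);
}

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector keys) {
  const R_xlen_t m = keys.size();
  CharacterVector out(m);
  for (R_xlen_t i = 0; i < m; ++i)
    out[i] = canonicalize_key(std::string(keys[i]));
  return out;
}

namespace {
void rgs_rec(std::string &cur, int pos, int mx, int max_symbols,
             std::vector<std::string> &keys, std::vector<int> &nd) {
  if (pos == (int)cur.size()) {
    keys.push_back(cur);
    nd.push_back(mx + 1);
    return;
  }
  const int hi = std::min(mx + 1, max_symbols - 1);
  for (int v = 0; v <= hi; ++v) {
    cur[pos] = char('0' + v);
    rgs_rec(cur, pos + 1, std::max(mx, v), max_symbols, keys, nd);
  }
}
} // namespace

// Enumerate restricted growth strings of given length with at most
// max_symbols distinct values: the canonical representatives of all
// symbol-permutation classes.  Returns keys plus the number of
// distinct symbols of each class (for multiplicity weighting).
// [[Rcpp::export]]
List cpp_rgs(int length, int max_symbols) {
  std::vector<std::string> keys;
  std::vector<int> ndistinct;
  std::string cur(length, '0');
  cur[0] = '0';
  // first symbol of a canonical class is always 0
  rgs_rec(cur, 1, 0, max_symbols, keys, ndistinct);
  return List::create(_["key"] = wrap(keys), _["n_distinct"] = wrap(ndistinct));
}

// Biased sequential response generator.  Next-symbol weights start
// uniform and are reweighted by bias strength b = 1 - ability:
//   * immediate repetition damped by repetition_avoidance,
//   * the symbol two steps back boosted by alternation_excess
//     (strict alternation for binary alphabets),
//   * while unused symbols remain, already-used symbols damped by
//     cycling_strength (postponing re-use until all have appeared).
// [[Rcpp::export]]
IntegerMatrix cpp_generate_sequences(int length, int n_symbols,
                                     NumericVector ability,
                                     double repetition_avoidance,
                                     double alternation_excess,
                                     double cycling_strength, int seed) {
  const int nseq = ability.size();
  IntegerMatrix out(nseq, length);
  std::mt19937 rng{uint32_t(seed)};
  std::vector<double> w(n_symbols);
  std::vector<int> used(n_symbols);
  for (int s = 0; s < nseq; ++s) {
    double b = 1.0 - ability[s];
    if (b < 0) b = 0;
    if (b > 1) b = 1;
    std::fill(used.begin(), used.end(), 0);
    int n_used = 0, prev = -1, prev2 = -1;
    for (int t = 0; t < length; ++t) {
      double tot = 0.0;
      for (int j = 0; j < n_symbols; ++j) w[j] = 1.0;
      if (prev >= 0) w[prev] *= 1.0 - b * repetition_avoidance;
      if (prev2 >= 0) w[prev2] *= 1.0 + b * alternation_excess;
      if (n_used < n_symbols && n_used > 0)
        for (int j = 0; j < n_symbols; ++j)
          if (used[j]) w[j] *= 1.0 - b * cycling_strength;
      for (int j = 0; j < n_symbols; ++j) tot += w[j];
      int pick = 0;
      if (tot <= 0.0) {
        pick = int(draw_below(rng, uint32_t(n_symbols)));
      } else {
        double u = draw_unif01(rng) * tot, acc = 0.0;
        pick = n_symbols - 1;
        for (int j = 0; j < n_symbols; ++j) {
          acc += w[j];
          if (u <= acc) {
            pick = j;
            break;
          }
        }
      }
      out(s, t) = pick;
      if (!used[pick]) {
        used[pick] = 1;
        ++n_used;
      }
      prev2 = prev;
      prev = pick;
    }
  }
  return out;
}

// Variable-length variant (one sequence per element of lengths),
// used for grid click streams.
// [[Rcpp::export]]
List cpp_generate_sequences_varlen(IntegerVector lengths, int n_symbols,
                                   NumericVector ability,
                                   double repetition_avoidance,
                                   double alternation_excess,
                                   double cycling_strength, int seed) {
  const int nseq = lengths.size();
  List out(nseq);
  std::mt19937 rng{uint32_t(seed)};
  std::vector<double> w(n_symbols);
  std::vector<int> used(n_symbols);
  for (int s = 0; s < nseq; ++s) {
    const int length = lengths[s];
    IntegerVector seq(length);
    double b = 1.0 - ability[s];
    if (b < 0) b = 0;
    if (b > 1) b = 1;
    std::fill(used.begin(), used.end(), 0);
    int n_used = 0, prev = -1, prev2 = -1;
    for (int t = 0; t < length; ++t) {
      double tot = 0.0;
      for (int j = 0; j < n_symbols; ++j) w[j] = 1.0;
      if (prev >= 0) w[prev] *= 1.0 - b * repetition_avoidance;
      if (prev2 >= 0) w[prev2] *= 1.0 + b * alternation_excess;
      if (n_used < n_symbols && n_used > 0)
        for (int j = 0; j < n_symbols; ++j)
          if (used[j]) w[j] *= 1.0 - b * cycling_strength;
      for (int j = 0; j < n_symbols; ++j) tot += w[j];
      int pick = 0;
      if (tot <= 0.0) {
        pick = int(draw_below(rng, uint32_t(n_symbols)));
      } else {
        double u = draw_unif01(rng) * tot, acc = 0.0;
        pick = n_symbols - 1;
        for (int j = 0; j < n_symbols; ++j) {
          acc += w[j];
          if (u <= acc) {
            pick = j;
            break;
          }
        }
      }
      seq[t] = pick;
      if (!used[pick]) {
        used[pick] = 1;
        ++n_used;
      }
      prev2 = prev;
      prev = pick;
    }
    out[s] = seq;
  }
  return out;
}

// Grid click generator: clicks toggle cells of a 3x3 grid.  Weights start
// uniform; with bias strength b = 1 - ability the previous cell is
// boosted by perseveration (re-toggling, i.e. revising) and its rook
// neighbours by clustering (spatially contiguous patterns).
// [[Rcpp::export]]
List cpp_generate_clicks(IntegerVector lengths, NumericVector ability,
                         double perseveration, double clustering, int seed) {
  static const int adj[9][5] = {
      {1, 3, -1, 0, 0},  {0, 2, 4, -1, 0}, {1, 5, -1, 0, 0},
      {0, 4, 6, -1, 0},  {1, 3, 5, 7, -1}, {2, 4, 8, -1, 0},
      {3, 7, -1, 0, 0},  {4, 6, 8, -1, 0}, {5, 7, -1, 0, 0}};
  const int nseq = lengths.size();
  List out(nseq);
  std::mt19937 rng{uint32_t(seed)};
  double w[9];
  for (int s = 0; s < nseq; ++s) {
    const int length = lengths[s];
    IntegerVector seq(length);
    double b = 1.0 - ability[s];
    if (b < 0) b = 0;
    if (b > 1) b = 1;
    int prev = -1;
    for (int t = 0; t < length; ++t) {
      double tot = 0.0;
      for (int j = 0; j < 9; ++j) w[j] = 1.0;
      if (prev >= 0) {
        w[prev] *= 1.0 + perseveration * b;
        for (int a = 0; adj[prev][a] >= 0; ++a)
          w[adj[prev][a]] *= 1.0 + clustering * b;
      }
      for (int j = 0; j < 9; ++j) tot += w[j];
      double u = draw_unif01(rng) * tot, acc = 0.0;
      int pick = 8;
      for (int j = 0; j < 9; ++j) {
        acc += w[j];
        if (u <= acc) {
          pick = j;
          break;
        }
      }
      seq[t] = pick;
      prev = pick;
    }
    out[s] = seq;
  }
  return out;
}
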