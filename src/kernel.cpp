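// Monte Carlo kernel for the multi-species contact process on a periodic
// L x L lattice.  One Monte Carlo step = L*L iterations, each a death trial
// (uniform cell, dies with prob m_i) followed by a birth trial (ordered pair:
// parent cell then target cell; target becomes parent's species with prob b_i
// iff the pair is (occupied, empty)).  Local mode draws the target among the
// four von Neumann neighbours under periodic boundaries; global mode draws a
// second distinct uniform cell.
//
// Randomness comes from a self-contained xoshiro256++ stream seeded from a
// 64-bit integer, so runs are bit-reproducible for a given seed and
// independent of R's global RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed into four state words
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in [0, n) via 128-bit multiply-shift (no division);
  // the modulo bias is < n / 2^64, irrelevant at lattice sizes
  inline int below(int n) {
    return static_cast<int>(
        (static_cast<unsigned __int128>(next()) * static_cast<uint64_t>(n)) >>
        64);
  }
};

// von Neumann neighbour of (r, c) under periodic boundaries;
// dir in {0: up, 1: down, 2: left, 3: right}; returns column-major index
inline int neighbour_rc(int r, int c, int dir, int L) {
  switch (dir) {
    case 0: r = (r == 0) ? L - 1 : r - 1; break;
    case 1: r = (r == L - 1) ? 0 : r + 1; break;
    case 2: c = (c == 0) ? L - 1 : c - 1; break;
    default: c = (c == L - 1) ? 0 : c + 1; break;
  }
  return r + c * L;
}

} // namespace

// Run `steps` Monte Carlo steps in place on a copy of `grid`, recording
// per-species counts at step 0, every `record_every` steps, and the final
// step.  Returns the final grid, the record matrix (one row per record,
// columns = step, n_1..n_N, n_empty) and the step count.
// [[Rcpp::export(name = ".run_lattice_cpp")]]
List run_lattice_cpp(IntegerMatrix grid, NumericVector birth,
                     NumericVector death, bool local, int steps,
                     int record_every, double seed) {
  const int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  const int LL = L * L;
  const int N = birth.size();
  if (death.size() != N) stop("birth and death must have equal length");

  std::vector<int> g(grid.begin(), grid.end());
  std::vector<double> b(birth.begin(), birth.end());
  std::vector<double> m(death.begin(), death.end());
  std::vector<long> count(N + 1, 0); // count[0] = empty
  for (int k = 0; k < LL; ++k) {
    if (g[k] < 0 || g[k] > N) stop("cell values must lie in 0..N");
    ++count[g[k]];
  }
  long occupied = LL - count[0];

  Xoshiro256 rng(static_cast<uint64_t>(seed));

  std::vector<double> rec;
  rec.reserve((steps / std::max(record_every, 1) + 2) * (N + 2));
  auto record = [&](int step) {
    rec.push_back(step);
    for (int i = 1; i <= N; ++i) rec.push_back(static_cast<double>(count[i]));
    rec.push_back(static_cast<double>(count[0]));
  };

  record(0);
  int step = 0;
  bool frozen = false; // empty lattice: dynamics are over
  for (step = 1; step <= steps; ++step) {
    if (!frozen) {
      const double* bi = &b[0];
      const double* mi = &m[0];
      int* gp = g.data();
      for (int it = 0; it < LL; ++it) {
        // death trial
        int d = rng.below(LL);
        int sp = gp[d];
        if (sp > 0 && rng.unif() < mi[sp - 1]) {
          gp[d] = 0;
          --count[sp];
          ++count[0];
          --occupied;
        }
        // birth trial: ordered (parent, target)
        int p, t;
        if (local) {
          // draw the parent as (row, column) so the neighbour needs no
          // integer division
          int r = rng.below(L), c = rng.below(L);
          p = r + c * L;
          t = neighbour_rc(r, c, static_cast<int>(rng.next() >> 62), L);
        } else {
          p = rng.below(LL);
          do { t = rng.below(LL); } while (t == p);
        }
        int psp = gp[p];
        if (psp > 0 && gp[t] == 0 && rng.unif() < bi[psp - 1]) {
          gp[t] = psp;
          ++count[psp];
          --count[0];
          ++occupied;
        }
      }
      if (occupied == 0) frozen = true;
    }
    if (step == steps || (record_every > 0 && step % record_every == 0))
      record(step);
    if (step % 256 == 0) checkUserInterrupt();
  }

  const int ncol = N + 2;
  const int nrow = static_cast<int>(rec.size()) / ncol;
  NumericMatrix records(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) records(r, c) = rec[r * ncol + c];

  IntegerMatrix out(L, L);
  std::copy(g.begin(), g.end(), out.begin());
  return List::create(_["grid"] = out, _["records"] = records,
                      _["steps"] = steps);
}

// Counts of the four classes of von-Neumann-adjacent cell pairs (right and
// down neighbour of every cell under periodic boundaries; total 2*L*L).
// [[Rcpp::export(name = ".adjacency_cpp")]]
IntegerVector adjacency_cpp(IntegerMatrix grid) {
  const int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  long same = 0, cross = 0, mixed = 0, empty2 = 0;
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      int a = grid(r, c);
      int right = grid(r, (c + 1) % L);
      int down = grid((r + 1) % L, c);
      for (int b : {right, down}) {
        if (a == 0 && b == 0) ++empty2;
        else if (a == 0 || b == 0) ++mixed;
        else if (a == b) ++same;
        else ++cross;
      }
    }
  }
  return IntegerVector::create(
      _["same_species_pairs"] = static_cast<int>(same),
      _["cross_species_pairs"] = static_cast<int>(cross),
      _["species_empty_pairs"] = static_cast<int>(mixed),
      _["empty_empty_pairs"] = static_cast<int>(empty2));
}
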