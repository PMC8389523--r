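// Cellular Potts Model core: energy evaluation, local connectivity test,
// Metropolis copy-attempt loop, and flood-fill audits.
//
// Conventions shared with the R side:
//   * grid is an integer matrix of cell IDs; 0 is the medium.
//   * type_of has length max_id + 1 and maps ID -> type code
//     (0 = medium, 1 = blue, 2 = yellow); type_of[0] == 0 always.
//   * area_of has length max_id + 1; entry 0 is the medium site count and is
//     kept up to date like any other so that sum(area_of) == nrow * ncol.
//   * J is a 3 x 3 contact-energy table indexed by type code.
//   * row/col arguments arriving from R are 1-based; they are converted here.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Neighborhood stencils on the square lattice. Orders 1-4 collect offsets at
// the 1st-4th smallest nonzero squared distances: 1, 2, 4, 5 -> cumulative
// sizes 4, 8, 12, 20.
// ---------------------------------------------------------------------------

static void stencil_offsets(int order, std::vector<int>& dr, std::vector<int>& dc) {
  static const int d2s[4] = {1, 2, 4, 5};
  dr.clear(); dc.clear();
  for (int k = 0; k < order; ++k) {
    int target = d2s[k];
    for (int a = -2; a <= 2; ++a)
      for (int b = -2; b <= 2; ++b)
        if (a * a + b * b == target) { dr.push_back(a); dc.push_back(b); }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_build_stencil(int order) {
  if (order < 1 || order > 4) stop("stencil order must be between 1 and 4");
  std::vector<int> dr, dc;
  stencil_offsets(order, dr, dc);
  IntegerMatrix out(dr.size(), 2);
  for (size_t i = 0; i < dr.size(); ++i) { out(i, 0) = dr[i]; out(i, 1) = dc[i]; }
  return out;
}

// ---------------------------------------------------------------------------
// Hamiltonian: H = sum_<k,l> J(tau_k, tau_l) [sigma_k != sigma_l]
//                + B/(2 A0) sum_cells (A_i - A0)^2
// The boundary sum runs over unordered neighboring-site pairs of the
// hamiltonian-order stencil; the area sum excludes the medium unless
// medium_area is set.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_total_energy(const IntegerMatrix& grid, const IntegerVector& type_of,
                        const IntegerVector& area_of, const NumericMatrix& J,
                        double Bmod, double A0, int order, bool periodic,
                        bool medium_area) {
  int nr = grid.nrow(), nc = grid.ncol();
  std::vector<int> dr, dc;
  stencil_offsets(order, dr, dc);
  // half stencil -> each unordered pair once
  std::vector<int> hdr, hdc;
  for (size_t k = 0; k < dr.size(); ++k)
    if (dc[k] > 0 || (dc[k] == 0 && dr[k] > 0)) { hdr.push_back(dr[k]); hdc.push_back(dc[k]); }

  const int* g = grid.begin();
  const int* ty = type_of.begin();
  double E = 0.0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = g[r + c * nr];
      int ta = ty[a];
      for (size_t k = 0; k < hdr.size(); ++k) {
        int r2 = r + hdr[k], c2 = c + hdc[k];
        if (periodic) {
          if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
          if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
        } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
          continue;
        }
        int b = g[r2 + c2 * nr];
        if (a != b) E += J(ta, ty[b]);
      }
    }
  }
  double k2 = Bmod / (2.0 * A0);
  for (int id = medium_area ? 0 : 1; id < area_of.size(); ++id) {
    double dA = area_of[id] - A0;
    E += k2 * dA * dA;
  }
  return E;
}

// Energy change for copying new_id onto (row, col), from local terms only.
// row/col are 0-based here; the exported wrapper converts.
static double delta_energy_at(const int* g, const int* ty, const int* areas,
                              const double* Jm, double k2, double A0,
                              const std::vector<int>& dr, const std::vector<int>& dc,
                              int nr, int nc, bool periodic, bool medium_area,
                              int r, int c, int new_id) {
  int a = g[r + c * nr];
  int ta = ty[a], tb = ty[new_id];
  double dE = 0.0;
  for (size_t k = 0; k < dr.size(); ++k) {
    int r2 = r + dr[k], c2 = c + dc[k];
    if (periodic) {
      if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
      if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
    } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
      continue;
    }
    int sl = g[r2 + c2 * nr];
    int tl = ty[sl];
    if (sl != new_id) dE += Jm[tb * 3 + tl];
    if (sl != a)      dE -= Jm[ta * 3 + tl];
  }
  if (ta != 0 || medium_area) {
    double Aa = areas[a];
    dE += k2 * ((Aa - 1.0 - A0) * (Aa - 1.0 - A0) - (Aa - A0) * (Aa - A0));
  }
  if (tb != 0 || medium_area) {
    double Ab = areas[new_id];
    dE += k2 * ((Ab + 1.0 - A0) * (Ab + 1.0 - A0) - (Ab - A0) * (Ab - A0));
  }
  return dE;
}

// [[Rcpp::export]]
double cpp_delta_energy(const IntegerMatrix& grid, const IntegerVector& type_of,
                        const IntegerVector& area_of, const NumericMatrix& J,
                        double Bmod, double A0, int order, bool periodic,
                        bool medium_area, int row, int col, int new_id) {
  int nr = grid.nrow(), nc = grid.ncol();
  int r = row - 1, c = col - 1;
  if (r < 0 || r >= nr || c < 0 || c >= nc) stop("site out of bounds");
  if (new_id < 0 || new_id >= type_of.size()) stop("unknown cell ID");
  if (grid(r, c) == new_id) stop("new_id equals the current ID at site");
  std::vector<int> dr, dc;
  stencil_offsets(order, dr, dc);
  double Jm[9];
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) Jm[i * 3 + j] = J(i, j);
  return delta_energy_at(grid.begin(), type_of.begin(), area_of.begin(), Jm,
                         Bmod / (2.0 * A0), A0, dr, dc, nr, nc, periodic,
                         medium_area, r, c, new_id);
}

// ---------------------------------------------------------------------------
// Local connectivity test on the Moore ring. Ring positions in cyclic order;
// two ring sites are adjacent iff their Chebyshev distance is <= 1.
// ---------------------------------------------------------------------------

static const int RING_DR[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
static const int RING_DC[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

static int ring_adj_built = 0;
static bool RING_ADJ[8][8];

static void build_ring_adj() {
  if (ring_adj_built) return;
  for (int i = 0; i < 8; ++i)
    for (int j = 0; j < 8; ++j) {
      int dr = RING_DR[i] - RING_DR[j], dc = RING_DC[i] - RING_DC[j];
      if (dr < 0) dr = -dr;
      if (dc < 0) dc = -dc;
      RING_ADJ[i][j] = (i != j) && (dr <= 1) && (dc <= 1);
    }
  ring_adj_built = 1;
}

// number of connected components (ring 8-adjacency) of the ring sites
// holding `id`; 0 if none do
static int ring_components(const int ring[8], int id) {
  build_ring_adj();
  bool present[8];
  int n = 0;
  for (int i = 0; i < 8; ++i) { present[i] = (ring[i] == id); if (present[i]) ++n; }
  if (n == 0) return 0;
  bool seen[8] = {false, false, false, false, false, false, false, false};
  int comps = 0;
  for (int i = 0; i < 8; ++i) {
    if (!present[i] || seen[i]) continue;
    ++comps;
    int stack[8], sp = 0;
    stack[sp++] = i; seen[i] = true;
    while (sp > 0) {
      int u = stack[--sp];
      for (int v = 0; v < 8; ++v)
        if (present[v] && !seen[v] && RING_ADJ[u][v]) { seen[v] = true; stack[sp++] = v; }
    }
  }
  return comps;
}

static void gather_ring(const int* g, int nr, int nc, bool periodic,
                        int r, int c, int ring[8]) {
  for (int k = 0; k < 8; ++k) {
    int r2 = r + RING_DR[k], c2 = c + RING_DC[k];
    if (periodic) {
      if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
      if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
      ring[k] = g[r2 + c2 * nr];
    } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
      ring[k] = 0;  // off-lattice counts as medium in free mode
    } else {
      ring[k] = g[r2 + c2 * nr];
    }
  }
}

static bool local_ok(const int* g, const int* ty, int nr, int nc, bool periodic,
                     bool medium_exempt, int r, int c, int a, int new_id) {
  int ring[8];
  gather_ring(g, nr, nc, periodic, r, c, ring);
  if (!(medium_exempt && ty[a] == 0)) {
    // empty candidate set would annihilate the cell's last local presence
    if (ring_components(ring, a) != 1) return false;
  }
  if (!(medium_exempt && ty[new_id] == 0)) {
    if (ring_components(ring, new_id) != 1) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool cpp_local_connectivity_ok(const IntegerMatrix& grid, const IntegerVector& type_of,
                               bool periodic, bool medium_exempt,
                               int row, int col, int new_id) {
  int nr = grid.nrow(), nc = grid.ncol();
  int r = row - 1, c = col - 1;
  if (r < 0 || r >= nr || c < 0 || c >= nc) stop("site out of bounds");
  int a = grid(r, c);
  if (a == new_id) stop("new_id equals the current ID at site");
  return local_ok(grid.begin(), type_of.begin(), nr, nc, periodic, medium_exempt,
                  r, c, a, new_id);
}

// Component count of a set of 8 ring occupancy flags under ring 8-adjacency;
// exported so tests can drive the exhaustive 3^8 comparison from R.
// [[Rcpp::export]]
int cpp_ring_components(const IntegerVector& ring_vals, int id) {
  if (ring_vals.size() != 8) stop("ring must have 8 values");
  int ring[8];
  for (int i = 0; i < 8; ++i) ring[i] = ring_vals[i];
  return ring_components(ring, id);
}

// ---------------------------------------------------------------------------
// Flood-fill audits (8-connectivity).
// ---------------------------------------------------------------------------

// components per cell ID; index id+1 in the returned vector
// [[Rcpp::export]]
IntegerVector cpp_audit_components(const IntegerMatrix& grid, int max_id, bool periodic) {
  int nr = grid.nrow(), nc = grid.ncol();
  const int* g = grid.begin();
  std::vector<char> seen(static_cast<size_t>(nr) * nc, 0);
  IntegerVector comps(max_id + 1, 0);
  std::vector<int> stack;
  for (int start = 0; start < nr * nc; ++start) {
    if (seen[start]) continue;
    int id = g[start];
    comps[id] += 1;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int r = u % nr, c = u / nr;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + RING_DR[k], c2 = c + RING_DC[k];
        if (periodic) {
          if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
          if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
        } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
          continue;
        }
        int v = r2 + c2 * nr;
        if (!seen[v] && g[v] == id) { seen[v] = 1; stack.push_back(v); }
      }
    }
  }
  return comps;
}

// 8-connected components of the sites whose cell type equals type_code
// [[Rcpp::export]]
int cpp_count_type_clusters(const IntegerMatrix& grid, const IntegerVector& type_of,
                            int type_code, bool periodic) {
  int nr = grid.nrow(), nc = grid.ncol();
  const int* g = grid.begin();
  const int* ty = type_of.begin();
  std::vector<char> seen(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  int comps = 0;
  for (int start = 0; start < nr * nc; ++start) {
    if (seen[start] || ty[g[start]] != type_code) continue;
    ++comps;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      int r = u % nr, c = u / nr;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + RING_DR[k], c2 = c + RING_DC[k];
        if (periodic) {
          if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
          if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
        } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
          continue;
        }
        int v = r2 + c2 * nr;
        if (!seen[v] && ty[g[v]] == type_code) { seen[v] = 1; stack.push_back(v); }
      }
    }
  }
  return comps;
}

// IDs of non-medium cells with no order-1 contact to any other non-medium cell
// [[Rcpp::export]]
IntegerVector cpp_detached_cells(const IntegerMatrix& grid, int max_id, bool periodic) {
  int nr = grid.nrow(), nc = grid.ncol();
  const int* g = grid.begin();
  std::vector<char> contact(max_id + 1, 0), present(max_id + 1, 0);
  static const int DR1[2] = {1, 0}, DC1[2] = {0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = g[r + c * nr];
      present[a] = 1;
      for (int k = 0; k < 2; ++k) {
        int r2 = r + DR1[k], c2 = c + DC1[k];
        if (periodic) {
          if (r2 >= nr) r2 -= nr;
          if (c2 >= nc) c2 -= nc;
        } else if (r2 >= nr || c2 >= nc) {
          continue;
        }
        int b = g[r2 + c2 * nr];
        if (a != b && a != 0 && b != 0) { contact[a] = 1; contact[b] = 1; }
      }
    }
  }
  std::vector<int> out;
  for (int id = 1; id <= max_id; ++id)
    if (present[id] && !contact[id]) out.push_back(id);
  return wrap(out);
}

// ---------------------------------------------------------------------------
// Boundary length: order-1 heterotypic (B-Y) site contacts; optionally also
// cell-medium contacts.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_boundary_length(const IntegerMatrix& grid, const IntegerVector& type_of,
                           bool periodic, bool include_medium) {
  int nr = grid.nrow(), nc = grid.ncol();
  const int* g = grid.begin();
  const int* ty = type_of.begin();
  static const int DR1[2] = {1, 0}, DC1[2] = {0, 1};
  long long count = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int ta = ty[g[r + c * nr]];
      for (int k = 0; k < 2; ++k) {
        int r2 = r + DR1[k], c2 = c + DC1[k];
        if (periodic) {
          if (r2 >= nr) r2 -= nr;
          if (c2 >= nc) c2 -= nc;
        } else if (r2 >= nr || c2 >= nc) {
          continue;
        }
        int tb = ty[g[r2 + c2 * nr]];
        if ((ta == 1 && tb == 2) || (ta == 2 && tb == 1)) ++count;
        else if (include_medium && ta != tb && (ta == 0 || tb == 0)) ++count;
      }
    }
  }
  return static_cast<double>(count);
}

// ---------------------------------------------------------------------------
// Metropolis copy-attempt loop. A xoshiro256++ generator, seeded from R's RNG
// stream at entry, drives the loop so that set.seed() gives full
// reproducibility while keeping per-attempt cost low.
// ---------------------------------------------------------------------------

static inline uint64_t rotl64(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return static_cast<int>(unif() * n); }
};

// Component counts of every 8-bit ring occupancy pattern, so the guard in
// the hot loop is two table lookups instead of a flood fill.
static int ring_comp_table_built = 0;
static unsigned char RING_COMP_TABLE[256];

static void build_ring_comp_table() {
  if (ring_comp_table_built) return;
  build_ring_adj();
  for (int mask = 0; mask < 256; ++mask) {
    bool seen[8] = {false, false, false, false, false, false, false, false};
    int comps = 0;
    for (int i = 0; i < 8; ++i) {
      if (!((mask >> i) & 1) || seen[i]) continue;
      ++comps;
      int stack[8], sp = 0;
      stack[sp++] = i; seen[i] = true;
      while (sp > 0) {
        int u = stack[--sp];
        for (int v = 0; v < 8; ++v)
          if (((mask >> v) & 1) && !seen[v] && RING_ADJ[u][v]) {
            seen[v] = true; stack[sp++] = v;
          }
      }
    }
    RING_COMP_TABLE[mask] = static_cast<unsigned char>(comps);
  }
  ring_comp_table_built = 1;
}

// Advances the chain by n_attempts copy attempts, mutating grid and area_of
// IN PLACE (the R wrapper owns fresh copies). Candidate sites are drawn
// uniformly over mutable sites: the whole lattice when periodic, the interior
// (outermost frozen ring excluded) when free. Target values are drawn
// uniformly among the copy-order stencil neighbors. Sites at least two rows/
// columns from the lattice edge take a fast path with precomputed flat-index
// offsets; edge-adjacent sites fall back to coordinate arithmetic with
// wrapping (periodic) or clipping (free).
// [[Rcpp::export]]
List cpm_advance_cpp(IntegerMatrix grid, const IntegerVector& type_of,
                     IntegerVector area_of, const NumericMatrix& J,
                     double Bmod, double A0, double Temp,
                     int ham_order, int copy_order, bool periodic, bool guard,
                     bool medium_exempt, bool medium_area, double n_attempts) {
  int nr = grid.nrow(), nc = grid.ncol();
  int* g = grid.begin();
  int* areas = area_of.begin();
  const int* ty = type_of.begin();
  std::vector<int> hdr, hdc, pdr, pdc;
  stencil_offsets(ham_order, hdr, hdc);
  stencil_offsets(copy_order, pdr, pdc);
  int np = static_cast<int>(pdr.size());
  int ns = static_cast<int>(hdr.size());
  build_ring_comp_table();
  std::vector<int> ham_off(ns), prop_off(np);
  int ring_off[8];
  for (int k = 0; k < ns; ++k) ham_off[k] = hdr[k] + hdc[k] * nr;
  for (int k = 0; k < np; ++k) prop_off[k] = pdr[k] + pdc[k] * nr;
  for (int k = 0; k < 8; ++k) ring_off[k] = RING_DR[k] + RING_DC[k] * nr;
  double Jm[9];
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) Jm[i * 3 + j] = J(i, j);
  double k2 = Bmod / (2.0 * A0);
  double invT = 1.0 / Temp;

  // seed the fast generator from R's RNG stream (reproducible via set.seed)
  uint64_t seed;
  {
    RNGScope scope;
    uint64_t hi = static_cast<uint64_t>(unif_rand() * 4294967296.0);
    uint64_t lo = static_cast<uint64_t>(unif_rand() * 4294967296.0);
    seed = (hi << 32) ^ lo;
  }
  Xoshiro256pp rng(seed);

  int rlo = periodic ? 0 : 1, rn = periodic ? nr : nr - 2;
  int clo = periodic ? 0 : 1, cn = periodic ? nc : nc - 2;
  if (rn <= 0 || cn <= 0) stop("lattice too small for a mutable interior");

  double n_acc = 0, n_noop = 0, n_conn = 0, n_metro = 0;
  double esum = 0.0;
  long long total = static_cast<long long>(n_attempts);

  for (long long it = 0; it < total; ++it) {
    int r = rlo + rng.below(rn);
    int c = clo + rng.below(cn);
    int idx = r + c * nr;
    int a = g[idx];
    int k = rng.below(np);
    bool fast = (r >= 2 && r < nr - 2 && c >= 2 && c < nc - 2);
    int b;
    double dE;
    if (fast) {
      b = g[idx + prop_off[k]];
      if (b == a) { n_noop += 1; continue; }
      if (guard) {
        unsigned mask_a = 0, mask_b = 0;
        for (int q = 0; q < 8; ++q) {
          int v = g[idx + ring_off[q]];
          mask_a |= (v == a) << q;
          mask_b |= (v == b) << q;
        }
        if ((!(medium_exempt && a == 0) && RING_COMP_TABLE[mask_a] != 1) ||
            (!(medium_exempt && b == 0) && RING_COMP_TABLE[mask_b] != 1)) {
          n_conn += 1;
          continue;
        }
      } else if (ty[a] != 0 && areas[a] <= 1) {
        // even the standard algorithm conserves cell number: the last site
        // of a cell is never overwritten
        n_conn += 1;
        continue;
      }
      int ta = ty[a], tb = ty[b];
      const double* Ja = Jm + ta * 3;
      const double* Jb = Jm + tb * 3;
      dE = 0.0;
      for (int q = 0; q < ns; ++q) {
        int sl = g[idx + ham_off[q]];
        int tl = ty[sl];
        dE += Jb[tl] * (sl != b) - Ja[tl] * (sl != a);
      }
      if (ta != 0 || medium_area) {
        double Aa = areas[a];
        dE += k2 * (1.0 - 2.0 * (Aa - A0));
      }
      if (tb != 0 || medium_area) {
        double Ab = areas[b];
        dE += k2 * (1.0 + 2.0 * (Ab - A0));
      }
    } else {
      int r2 = r + pdr[k], c2 = c + pdc[k];
      if (periodic) {
        if (r2 < 0) r2 += nr; else if (r2 >= nr) r2 -= nr;
        if (c2 < 0) c2 += nc; else if (c2 >= nc) c2 -= nc;
        b = g[r2 + c2 * nr];
      } else if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) {
        b = 0;  // off-lattice neighbor in free mode proposes the medium value
      } else {
        b = g[r2 + c2 * nr];
      }
      if (b == a) { n_noop += 1; continue; }
      if (guard && !local_ok(g, ty, nr, nc, periodic, medium_exempt, r, c, a, b)) {
        n_conn += 1;
        continue;
      }
      if (!guard && ty[a] != 0 && areas[a] <= 1) {
        n_conn += 1;
        continue;
      }
      dE = delta_energy_at(g, ty, areas, Jm, k2, A0, hdr, hdc, nr, nc,
                           periodic, medium_area, r, c, b);
    }
    if (dE <= 0.0 || rng.unif() < std::exp(-dE * invT)) {
      g[idx] = b;
      areas[a] -= 1;
      areas[b] += 1;
      esum += dE;
      n_acc += 1;
    } else {
      n_metro += 1;
    }
  }
  return List::create(_["accepted"] = n_acc, _["rejected_noop"] = n_noop,
                      _["rejected_connectivity"] = n_conn,
                      _["rejected_metropolis"] = n_metro,
                      _["delta_energy"] = esum);
}

// Single forced copy attempt at a given site with a given target value, using
// R's RNG for the Metropolis draw. Mutates grid/area_of in place on
// acceptance. Status codes: 0 accepted, 2 rejected-connectivity,
// 3 rejected-metropolis.
// [[Rcpp::export]]
List cpp_attempt_at(IntegerMatrix grid, const IntegerVector& type_of,
                    IntegerVector area_of, const NumericMatrix& J,
                    double Bmod, double A0, double Temp,
                    int ham_order, bool periodic, bool guard,
                    bool medium_exempt, bool medium_area,
                    int row, int col, int new_id) {
  int nr = grid.nrow(), nc = grid.ncol();
  int r = row - 1, c = col - 1;
  if (r < 0 || r >= nr || c < 0 || c >= nc) stop("site out of bounds");
  if (new_id < 0 || new_id >= type_of.size()) stop("unknown cell ID");
  int a = grid(r, c);
  if (a == new_id) stop("new_id equals the current ID at site");
  std::vector<int> hdr, hdc;
  stencil_offsets(ham_order, hdr, hdc);
  double Jm[9];
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) Jm[i * 3 + j] = J(i, j);
  if (guard && !local_ok(grid.begin(), type_of.begin(), nr, nc, periodic,
                         medium_exempt, r, c, a, new_id))
    return List::create(_["status"] = 2, _["delta_energy"] = NA_REAL);
  double dE = delta_energy_at(grid.begin(), type_of.begin(), area_of.begin(), Jm,
                              Bmod / (2.0 * A0), A0, hdr, hdc, nr, nc, periodic,
                              medium_area, r, c, new_id);
  bool accept;
  {
    RNGScope scope;
    accept = (dE <= 0.0) || (unif_rand() < std::exp(-dE / Temp));
  }
  if (accept) {
    grid(r, c) = new_id;
    area_of[a] -= 1;
    area_of[new_id] += 1;
    return List::create(_["status"] = 0, _["delta_energy"] = dE);
  }
  return List::create(_["status"] = 3, _["delta_energy"] = dE);
}
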