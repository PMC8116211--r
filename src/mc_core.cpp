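#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// xoshiro256+ with splitmix64 seeding: the simulator owns its RNG stream so
// that (seed, config) -> ensemble is bit-reproducible independent of R's
// global RNG state.
namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline int randint(int n) { return (int)(unif() * n); }
};

const double BIG = 1e30;

struct System {
  int n;
  std::vector<double> x, y, z;
  // linked-cell neighbor list (confined systems): cell edge >= interaction
  // range, so all interacting partners lie in the 27 surrounding cells
  bool use_cells = false;
  double cell_x0, cell_y0, cell_z0, cell_edge;
  int ncx, ncy, ncz;
  std::vector<std::vector<int> > cell_members;  // contiguous per cell
  std::vector<int> cell_of;
  std::vector<int> chain;    // chain id per bead
  std::vector<int> type;     // type id per bead (0-based)
  // pair energies: either per-type (k x k) or per-pair (n x n)
  bool per_pair;
  std::vector<double> type_E; // k*k
  int ntype;
  std::vector<double> pair_E; // n*n (contact energy, negative = attractive)
  double surf_eps;            // depth of apical surface attraction (>= 0)
  int surf_type;              // type gaining it, -1 = none
  double bond_k, bond_r0, bond_lo2, bond_hi2; // squared window bounds
  double rep_eps, sigma2, att2;               // squared ranges
  int shape;                  // 0 none, 1 cylinder (z in [0,H]), 2 box
  double radius2, height, bx, by, bz;         // box half-... no: box [0,b*]
  double surf_z;              // z above which surface term applies

  inline double pairEnergy(int i, int j, double dx, double dy, double dz) const {
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= att2) return 0.0;
    double e = per_pair ? pair_E[(size_t)i * n + j]
                        : type_E[type[i] * ntype + type[j]];
    if (r2 < sigma2) {
      // soft core capped at rep_eps, linear in r^2
      e += rep_eps * (1.0 - r2 / sigma2);
    }
    return e;
  }

  inline double bondEnergy(double dx, double dy, double dz) const {
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < bond_lo2 || r2 > bond_hi2) return BIG;
    double r = std::sqrt(r2) - bond_r0;
    return 0.5 * bond_k * r * r;
  }

  inline bool inside(double px, double py, double pz) const {
    if (shape == 1) {
      if (pz < 0.0 || pz > height) return false;
      return px * px + py * py <= radius2;
    }
    if (shape == 2) {
      return px >= 0.0 && px <= bx && py >= 0.0 && py <= by &&
             pz >= 0.0 && pz <= bz;
    }
    return true;
  }

  inline int cellIndex(double px, double py, double pz) const {
    int cx = (int)((px - cell_x0) / cell_edge);
    int cy = (int)((py - cell_y0) / cell_edge);
    int cz = (int)((pz - cell_z0) / cell_edge);
    if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
    if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
    if (cz < 0) cz = 0; if (cz >= ncz) cz = ncz - 1;
    return (cz * ncy + cy) * ncx + cx;
  }

  void buildCells(double x0, double x1, double y0, double y1,
                  double z0, double z1, double range) {
    use_cells = true;
    cell_edge = range;
    cell_x0 = x0 - range; cell_y0 = y0 - range; cell_z0 = z0 - range;
    ncx = (int)((x1 - x0) / range) + 3;
    ncy = (int)((y1 - y0) / range) + 3;
    ncz = (int)((z1 - z0) / range) + 3;
    cell_members.assign((size_t)ncx * ncy * ncz, std::vector<int>());
    cell_of.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cellIndex(x[i], y[i], z[i]);
      cell_of[i] = c;
      cell_members[c].push_back(i);
    }
  }

  void rebuildFreeCells(double range) {
    double x0 = x[0], x1 = x[0], y0 = y[0], y1 = y[0], z0 = z[0], z1 = z[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < x0) x0 = x[i]; if (x[i] > x1) x1 = x[i];
      if (y[i] < y0) y0 = y[i]; if (y[i] > y1) y1 = y[i];
      if (z[i] < z0) z0 = z[i]; if (z[i] > z1) z1 = z[i];
    }
    buildCells(x0, x1, y0, y1, z0, z1, range);
  }

  inline void moveCell(int i, double px, double py, double pz) {
    int c = cellIndex(px, py, pz);
    int o = cell_of[i];
    if (c == o) return;
    std::vector<int>& mo = cell_members[o];
    for (size_t k = 0; k < mo.size(); ++k)
      if (mo[k] == i) { mo[k] = mo.back(); mo.pop_back(); break; }
    cell_members[c].push_back(i);
    cell_of[i] = c;
  }

  double nonbonded(int i, double px, double py, double pz) const {
    double e = 0.0;
    if (!use_cells) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if ((j == i - 1 || j == i + 1) && chain[j] == chain[i]) continue;
        e += pairEnergy(i, j, px - x[j], py - y[j], pz - z[j]);
      }
      return e;
    }
    int c = cellIndex(px, py, pz);
    int cx = c % ncx, cy = (c / ncx) % ncy, cz = c / (ncx * ncy);
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = cz + dz; if (zz < 0 || zz >= ncz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = cy + dy; if (yy < 0 || yy >= ncy) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = cx + dx; if (xx < 0 || xx >= ncx) continue;
          const std::vector<int>& mem =
            cell_members[(zz * ncy + yy) * ncx + xx];
          for (size_t k = 0; k < mem.size(); ++k) {
            int j = mem[k];
            if (j == i) continue;
            if ((j == i - 1 || j == i + 1) && chain[j] == chain[i]) continue;
            e += pairEnergy(i, j, px - x[j], py - y[j], pz - z[j]);
          }
        }
      }
    }
    return e;
  }

  // energy of bead i at position (px,py,pz), all terms involving i
  double beadEnergy(int i, double px, double py, double pz) const {
    if (!inside(px, py, pz)) return BIG;
    double e = 0.0;
    if (i > 0 && chain[i - 1] == chain[i]) {
      double eb = bondEnergy(px - x[i - 1], py - y[i - 1], pz - z[i - 1]);
      if (eb >= BIG) return BIG;
      e += eb;
    }
    if (i < n - 1 && chain[i + 1] == chain[i]) {
      double eb = bondEnergy(px - x[i + 1], py - y[i + 1], pz - z[i + 1]);
      if (eb >= BIG) return BIG;
      e += eb;
    }
    e += nonbonded(i, px, py, pz);
    if (surf_eps > 0.0 && surf_type >= 0 && type[i] == surf_type &&
        pz > surf_z) {
      e -= surf_eps;
    }
    return e;
  }
};

}  // namespace

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericMatrix init, IntegerVector chain, IntegerVector type,
            NumericMatrix typeEnergy, SEXP pairEnergy,
            double surfEps, int surfType,
            double bondK, double bondR0, double repEps, double sigma,
            double attRange,
            int shape, double radius, double height,
            double boxX, double boxY, double boxZ,
            int nSweeps, int equilSweeps, int sampleInterval,
            double step0, double seed, int useCells) {
  System S;
  S.n = init.nrow();
  const int n = S.n;
  S.x.resize(n); S.y.resize(n); S.z.resize(n);
  S.chain.assign(chain.begin(), chain.end());
  S.type.assign(type.begin(), type.end());
  for (int i = 0; i < n; ++i) {
    S.x[i] = init(i, 0); S.y[i] = init(i, 1); S.z[i] = init(i, 2);
  }
  S.ntype = typeEnergy.nrow();
  S.type_E.assign(typeEnergy.begin(), typeEnergy.end());
  S.per_pair = !Rf_isNull(pairEnergy);
  if (S.per_pair) {
    NumericMatrix pe(pairEnergy);
    if (pe.nrow() != n || pe.ncol() != n)
      stop("pair energy matrix must be n x n");
    S.pair_E.assign(pe.begin(), pe.end());
  }
  S.surf_eps = surfEps; S.surf_type = surfType;
  S.bond_k = bondK; S.bond_r0 = bondR0;
  double lo = 0.7 * bondR0, hi = 1.3 * bondR0;
  S.bond_lo2 = lo * lo; S.bond_hi2 = hi * hi;
  S.rep_eps = repEps; S.sigma2 = sigma * sigma;
  S.att2 = attRange * attRange;
  S.shape = shape; S.radius2 = radius * radius; S.height = height;
  S.bx = boxX; S.by = boxY; S.bz = boxZ;
  S.surf_z = (shape == 1 ? height : boxZ) - sigma;

  // cell list (index clamping at the grid edge can only add extra pair
  // checks, never miss one, so a stale bounding box stays correct for
  // unconfined systems; the grid is refreshed periodically)
  double range = attRange > sigma ? attRange : sigma;
  bool wantCells = useCells > 0 || (useCells < 0 && n > 48);
  bool freeCells = (shape == 0 && wantCells);
  if (shape == 1 && wantCells) {
    S.buildCells(-radius, radius, -radius, radius, 0.0, height, range);
  } else if (shape == 2 && wantCells) {
    S.buildCells(0.0, boxX, 0.0, boxY, 0.0, boxZ, range);
  } else if (freeCells) {
    S.rebuildFreeCells(range);
  }

  Rng rng((uint64_t)seed);
  double step = step0;
  long accepted = 0, attempted = 0;
  long acc_win = 0, att_win = 0;

  int nSamples = nSweeps / sampleInterval;
  NumericVector samples((R_xlen_t)nSamples * n * 3);
  int si = 0;

  int total = equilSweeps + nSweeps;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int m = 0; m < n; ++m) {
      int i = rng.randint(n);
      double px = S.x[i] + (rng.unif() - 0.5) * 2.0 * step;
      double py = S.y[i] + (rng.unif() - 0.5) * 2.0 * step;
      double pz = S.z[i] + (rng.unif() - 0.5) * 2.0 * step;
      double e_old = S.beadEnergy(i, S.x[i], S.y[i], S.z[i]);
      double e_new = S.beadEnergy(i, px, py, pz);
      ++attempted; ++att_win;
      double dE = e_new - e_old;
      if (e_new < BIG && (dE <= 0.0 || rng.unif() < std::exp(-dE))) {
        S.x[i] = px; S.y[i] = py; S.z[i] = pz;
        if (S.use_cells) S.moveCell(i, px, py, pz);
        ++accepted; ++acc_win;
      }
    }
    // step auto-tuning during equilibration only (keeps detailed balance
    // exact in the sampling phase)
    if (sweep < equilSweeps && att_win >= 50 * n) {
      double rate = (double)acc_win / att_win;
      if (rate < 0.3) step = std::max(step * 0.8, 0.01);
      else if (rate > 0.5) step = std::min(step * 1.2, 2.0);
      acc_win = 0; att_win = 0;
    }
    if (sweep >= equilSweeps) {
      int k = sweep - equilSweeps + 1;
      if (k % sampleInterval == 0 && si < nSamples) {
        for (int i = 0; i < n; ++i) {
          samples[(R_xlen_t)si * n * 3 + i] = S.x[i];
          samples[(R_xlen_t)si * n * 3 + n + i] = S.y[i];
          samples[(R_xlen_t)si * n * 3 + 2 * n + i] = S.z[i];
        }
        ++si;
      }
    }
    if (freeCells && sweep % 100 == 99) S.rebuildFreeCells(range);
    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  samples.attr("dim") = IntegerVector::create(n, 3, nSamples);
  return List::create(_["samples"] = samples,
                      _["acceptance"] = (double)accepted / attempted,
                      _["step"] = step);
}

// Contact frequency across an ensemble: fraction of configurations with
// pairwise distance < radius. coords is n x 3 x m.
// [[Rcpp::export(name = ".mc_contact_map")]]
NumericMatrix mc_contact_map(NumericVector coords, double radius) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0], m = dim[2];
  double r2 = radius * radius;
  NumericMatrix out(n, n);
  for (int s = 0; s < m; ++s) {
    const double* X = &coords[(R_xlen_t)s * n * 3];
    const double* Y = X + n;
    const double* Z = Y + n;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
        if (dx * dx + dy * dy + dz * dz < r2) {
          out(i, j) += 1.0;
        }
      }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      out(i, j) /= m;
      out(j, i) = out(i, j);
    }
    out(i, i) = 1.0;
  }
  return out;
}

// Mean pairwise Euclidean distance across an ensemble.
// [[Rcpp::export(name = ".mc_distance_map")]]
NumericMatrix mc_distance_map(NumericVector coords) {
  IntegerVector dim = coords.attr("dim");
  int n = dim[0], m = dim[2];
  NumericMatrix out(n, n);
  for (int s = 0; s < m; ++s) {
    const double* X = &coords[(R_xlen_t)s * n * 3];
    const double* Y = X + n;
    const double* Z = Y + n;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
        out(i, j) += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      out(i, j) /= m;
      out(j, i) = out(i, j);
    }
  return out;
}
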