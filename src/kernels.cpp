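// Hot loops of the crypt simulator: stochastic histone dynamics across the
// whole cell population, promoter-state division, off-lattice mechanics on
// the crypt surface, and contact counting.
//
// Stochastic kernels use an internal xoshiro256++ generator seeded from R's
// RNG at entry, so results are fully determined by R's random seed while the
// per-nucleosome draws stay cheap.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Seed the internal generator from R's RNG (two draws -> 64 bits), keeping
// every kernel call deterministic under R's seed/stream management.
Xoshiro seeded_from_R() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return Xoshiro((hi << 32) ^ lo ^ 0x6a09e667f3bcc908ULL);
}

inline double dnovo_eq(double m4, double m27, double dnovo0,
                       double e4, double e27) {
  return dnovo0 * (1.0 + std::exp(-e27 * m27)) /
         (1.0 + std::exp(e4 * m4 - e27 * m27));
}

inline double dmain_eq(double m, double dmain0, double em0, double em1) {
  return dmain0 / (1.0 + std::exp(em0 + em1 * m));
}

} // namespace

// One stochastic histone update for the listed promoter columns.
// k4/k27: n_nuc x M integer matrices of 0/1 marks (modified IN PLACE).
// cols: 0-based column indices to update (active promoters); tr, mcpg and
// cde4 are aligned with `cols` (length(cols) each, cde4 may be length 1).
// Returns the updated modified fractions m4, m27 aligned with `cols`.
// [[Rcpp::export]]
List cpp_histone_step(IntegerMatrix k4, IntegerMatrix k27, IntegerVector cols,
                      NumericVector tr, NumericVector mcpg,
                      NumericVector cde4, double cde27,
                      double q4_max, double q27_max,
                      double kt4, double kt27, double hill,
                      double coop_basal, double w4, double w27) {
  const int n = k4.nrow(), M = cols.size();
  if (k27.nrow() != n || k27.ncol() != k4.ncol() || tr.size() != M ||
      mcpg.size() != M || (cde4.size() != M && cde4.size() != 1))
    stop("cpp_histone_step: inconsistent dimensions");
  Xoshiro rng = seeded_from_R();
  std::vector<int> old4(n), old27(n);
  const double kt4h = std::pow(kt4, hill), kt27h = std::pow(kt27, hill);
  for (int jj = 0; jj < M; ++jj) {
    const int j = cols[jj];
    const double T = tr[jj];
    const double Th = std::pow(T, hill);
    const double gate4 = (Th + kt4h) > 0 ? Th / (kt4h + Th) : 0.0;
    const double gate27 = kt27h / (kt27h + Th);
    const double wm4 = std::max(0.0, 1.0 - w4 * mcpg[jj]);
    const double wm27 = std::max(0.0, 1.0 - w27 * mcpg[jj]);
    const double c4 = (cde4.size() == 1) ? cde4[0] : cde4[jj];
    int *col4 = &k4(0, j);
    int *col27 = &k27(0, j);
    for (int i = 0; i < n; ++i) { old4[i] = col4[i]; old27[i] = col27[i]; }
    int s4 = 0, s27 = 0;
    for (int i = 0; i < n; ++i) {
      // neighbour cooperativity from the pre-update configuration
      int nb = 0, l4 = 0, l27 = 0;
      if (i > 0)     { ++nb; l4 += old4[i - 1]; l27 += old27[i - 1]; }
      if (i < n - 1) { ++nb; l4 += old4[i + 1]; l27 += old27[i + 1]; }
      const double co4 = coop_basal + (1.0 - coop_basal) * (nb ? (double)l4 / nb : 0.0);
      const double co27 = coop_basal + (1.0 - coop_basal) * (nb ? (double)l27 / nb : 0.0);
      double u = rng.unif();
      if (old4[i]) { if (u < c4) col4[i] = 0; }
      else         { if (u < q4_max * gate4 * co4 * wm4) col4[i] = 1; }
      u = rng.unif();
      if (old27[i]) { if (u < cde27) col27[i] = 0; }
      else          { if (u < q27_max * gate27 * co27 * wm27) col27[i] = 1; }
      s4 += col4[i]; s27 += col27[i];
    }
    (void)s4; (void)s27;
  }
  NumericVector m4(M), m27(M);
  for (int jj = 0; jj < M; ++jj) {
    const int j = cols[jj];
    int a = 0, b = 0;
    for (int i = 0; i < n; ++i) { a += k4(i, j); b += k27(i, j); }
    m4[jj] = (double)a / n;
    m27[jj] = (double)b / n;
  }
  // k4/k27 are updated in place and deliberately not returned: returning
  // them would raise their reference count and force R to copy the large
  // mark matrices on the next in-place modification.
  return List::create(_["m4"] = m4, _["m27"] = m27);
}

// Division of the promoters of M mother cells (G genes each, held as
// consecutive column blocks). Nucleosomes carrying any mark are assigned to
// one daughter uniformly at random (both mark types of a nucleosome travel
// together) and placed at random positions; the deterministic
// DNA-methylation update is then applied per daughter with its post-dilution
// (m4, m27). dnovo0: per-promoter maximum de novo probability (elevated for
// genes under repair at this division). Returns daughter blocks in
// mother-major order: columns [2m*G, (2m+1)*G) = first daughter of mother m,
// [(2m+1)*G, (2m+2)*G) = second daughter.
// [[Rcpp::export]]
List cpp_divide_promoters(IntegerMatrix k4, IntegerMatrix k27,
                          NumericVector mcpg, NumericVector dnovo0,
                          double dmain0, double em0, double em1,
                          double e4, double e27, int n_genes) {
  const int n = k4.nrow(), M_cols = k4.ncol();
  const int G = n_genes;
  if (k27.nrow() != n || k27.ncol() != M_cols || mcpg.size() != M_cols ||
      (dnovo0.size() != M_cols && dnovo0.size() != 1) || M_cols % G != 0)
    stop("cpp_divide_promoters: inconsistent dimensions");
  const int M = M_cols / G;
  Xoshiro rng = seeded_from_R();
  IntegerMatrix dk4(n, 2 * M_cols), dk27(n, 2 * M_cols);
  NumericVector dm(2 * M_cols), dm4(2 * M_cols), dm27(2 * M_cols);
  std::vector<int> pos(n);
  std::vector<std::pair<int,int>> da, db;
  for (int m = 0; m < M; ++m) {
    for (int g = 0; g < G; ++g) {
      const int src = m * G + g;
      const int c1 = 2 * m * G + g, c2 = (2 * m + 1) * G + g;
      // collect marked nucleosomes and split them binomially
      da.clear(); db.clear();
      for (int i = 0; i < n; ++i) {
        int a = k4(i, src), b = k27(i, src);
        if (a || b) {
          if (rng.unif() < 0.5) da.push_back({a, b});
          else db.push_back({a, b});
        }
      }
      // random placement within each daughter promoter
      for (int d = 0; d < 2; ++d) {
        std::vector<std::pair<int,int>> &v = d ? db : da;
        const int dst = d ? c2 : c1;
        for (int i = 0; i < n; ++i) pos[i] = i;
        int cnt = (int)v.size();
        for (int i = 0; i < cnt; ++i) { // partial Fisher-Yates
          int j = i + (int)(rng.unif() * (n - i));
          if (j >= n) j = n - 1;
          std::swap(pos[i], pos[j]);
          dk4(pos[i], dst) = v[i].first;
          dk27(pos[i], dst) = v[i].second;
        }
      }
      const double dn0 = (dnovo0.size() == 1) ? dnovo0[0] : dnovo0[src];
      const double m0 = mcpg[src];
      const double loss = (1 - dmain_eq(m0, dmain0, em0, em1)) * m0;
      for (int d = 0; d < 2; ++d) {
        const int dst = d ? c2 : c1;
        int a4 = 0, a27 = 0;
        for (int i = 0; i < n; ++i) { a4 += dk4(i, dst); a27 += dk27(i, dst); }
        dm4[dst] = (double)a4 / n;
        dm27[dst] = (double)a27 / n;
        const double delta =
          dnovo_eq(dm4[dst], dm27[dst], dn0, e4, e27) * (1 - m0) - loss;
        dm[dst] = std::min(1.0, std::max(0.0, m0 + delta));
      }
    }
  }
  return List::create(_["k4"] = dk4, _["k27"] = dk27, _["m_cpg"] = dm,
                      _["m4"] = dm4, _["m27"] = dm27);
}

namespace {

// Project a point onto the test-tube surface: hemisphere of radius `rad`
// centred at (0,0,rad) for z below the centre plane, cylinder of radius
// `rad` above it.
inline void project_surface(double &x, double &y, double &z, double rad) {
  if (z < rad) {
    double dx = x, dy = y, dz = z - rad;
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L < 1e-12) { x = 0; y = 0; z = 0; return; }
    double f = rad / L;
    double nx = dx * f, ny = dy * f, nz = rad + dz * f;
    if (nz <= rad) { x = nx; y = ny; z = nz; return; }
    // landed on the upper hemisphere: fall through to the cylinder
    z = nz;
    x = nx; y = ny;
  }
  double rxy = std::sqrt(x * x + y * y);
  if (rxy < 1e-12) { x = rad; y = 0; }
  else { double f = rad / rxy; x *= f; y *= f; }
  if (z < rad) z = rad; // cylinder starts at the hemisphere equator
}

} // namespace

// Overdamped relaxation of pairwise repulsion/adhesion constrained to the
// crypt surface. pos: n x 3 matrix, modified IN PLACE; rows listed in
// `act` (0-based) are live cells, others are ignored. mobility: per-cell
// displacement factor (Paneth cells are anchored with low mobility).
// [[Rcpp::export]]
void cpp_mechanics_step(NumericMatrix pos, IntegerVector act,
                        NumericVector mobility,
                        double rad, double rest, double r_adh,
                        double k_rep, double k_adh, double eta,
                        int substeps) {
  const int n = act.size();
  if (pos.ncol() != 3 || mobility.size() != pos.nrow())
    stop("cpp_mechanics_step: bad dimensions");
  std::vector<double> fx(n), fy(n), fz(n);
  const double cut2 = r_adh * r_adh;
  // Verlet neighbour list with a 1-diameter skin, built once per call;
  // within-call displacements are far below the skin width
  const double skin2 = (r_adh + 1.0) * (r_adh + 1.0);
  std::vector<std::pair<int,int>> pairs;
  pairs.reserve((size_t)n * 12);
  for (int ii = 0; ii < n; ++ii) {
    const int i = act[ii];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = act[jj];
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz < skin2) pairs.push_back({ii, jj});
    }
  }
  for (int s = 0; s < substeps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (size_t q = 0; q < pairs.size(); ++q) {
      const int ii = pairs[q].first, jj = pairs[q].second;
      {
        const int i = act[ii];
        const int j = act[jj];
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double dz = pos(i, 2) - pos(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= cut2) continue;
        double d = std::sqrt(d2);
        double f;
        if (d < 1e-9) { // coincident cells: deterministic nudge apart
          dx = 1.0; dy = 0.0; dz = 0.0; d = 1.0;
          f = k_rep * rest;
        } else if (d < rest) {
          f = k_rep * (rest - d);        // repulsion (push apart)
        } else {
          f = -k_adh * (d - rest);       // adhesion (pull together)
        }
        double g = f / d;
        fx[ii] += g * dx; fy[ii] += g * dy; fz[ii] += g * dz;
        fx[jj] -= g * dx; fy[jj] -= g * dy; fz[jj] -= g * dz;
      }
    }
    for (int ii = 0; ii < n; ++ii) {
      const int i = act[ii];
      double mob = mobility[i] * eta;
      double x = pos(i, 0) + mob * fx[ii];
      double y = pos(i, 1) + mob * fy[ii];
      double z = pos(i, 2) + mob * fz[ii];
      project_surface(x, y, z, rad);
      pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
    }
  }
}

// Number of flagged (secretory) cells within `radius` of each listed cell,
// excluding the cell itself. Returns counts aligned with `act`.
// [[Rcpp::export]]
IntegerVector cpp_contact_counts(NumericMatrix pos, IntegerVector act,
                                 IntegerVector flag, double radius) {
  const int n = act.size();
  if (flag.size() != n) stop("cpp_contact_counts: bad dimensions");
  IntegerVector out(n);
  const double r2 = radius * radius;
  for (int ii = 0; ii < n; ++ii) {
    const int i = act[ii];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = act[jj];
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) {
        if (flag[jj]) ++out[ii];
        if (flag[ii]) ++out[jj];
      }
    }
  }
  return out;
}
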