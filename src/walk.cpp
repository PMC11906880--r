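// Monte Carlo random-walk engines for diffusion-weighted signal synthesis.
//
// Phase accumulation uses the integration-by-parts identity
//   phi = gamma int g.r dt = -int q.dr
// so only displacement increments are needed. Every DDE waveform of a
// protocol is a linear combination of a small number of scalar dephasing
// profiles u_j(t) (one per block timing): q(t) = a1 u_{p1}(t) n1 +
// a2 u_{p2}(t) n2. Per particle we therefore accumulate the 3-vector
// moments M_j = sum_t u_j(t) dr(t) once, and score all waveforms (all
// rotations and b-values) as phi = a1 n1.M_{p1} + a2 n2.M_{p2}.
//
// Units: um, ms, um^2/ms; exchange rates 1/ms; q in 1/um.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding and a cached Box-Muller normal:
// much faster than std::normal_distribution and fully deterministic across
// platforms for a given integer seed
struct FastRng {
  uint64_t s[4];
  bool have_cached = false;
  double cached = 0.0;

  explicit FastRng(uint64_t seed) {
    uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0, 1)
    return (next() >> 11) * 1.1102230246251565e-16 + 5.551115123125783e-17;
  }
  inline double gauss() { // Marsaglia polar method, second value cached
    if (have_cached) { have_cached = false; return cached; }
    double x, y, s;
    do {
      x = 2.0 * unif() - 1.0;
      y = 2.0 * unif() - 1.0;
      s = x * x + y * y;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = y * f;
    have_cached = true;
    return x * f;
  }
};

struct WfTable {
  std::vector<int> p1, p2, ptype;
  std::vector<double> a1, a2;
  std::vector<double> n1, n2; // 3 * n_wf, column blocks
  int n() const { return (int)p1.size(); }
};

WfTable make_wf(IntegerVector p1, NumericVector a1, NumericMatrix n1,
                IntegerVector p2, NumericVector a2, NumericMatrix n2,
                IntegerVector ptype) {
  WfTable w;
  int n = p1.size();
  w.p1.resize(n); w.p2.resize(n); w.ptype.resize(n);
  w.a1.resize(n); w.a2.resize(n);
  w.n1.resize(3 * n); w.n2.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    w.p1[i] = p1[i]; w.p2[i] = p2[i];
    w.ptype[i] = (ptype.size() == n) ? ptype[i] : 0;
    w.a1[i] = a1[i]; w.a2[i] = a2[i];
    for (int d = 0; d < 3; ++d) {
      w.n1[3 * i + d] = n1(i, d);
      w.n2[3 * i + d] = n2(i, d);
    }
  }
  return w;
}

// ptype 0: fixed-direction waveform, contributes cos(phi).
// ptype 1: analytic spherical (powder) mean over rotations for collinear
//   pairs: the rotation average of cos(n.W) over uniform n is
//   sin(|W|)/|W| with W = a1 M_{p1} + a2 M_{p2} (a2 signed for
//   antiparallel); exact Rao-Blackwellisation of the rotation scheme.
inline void score_particle(const WfTable& wf, const std::vector<double>& M,
                           std::vector<double>& sum_cos,
                           std::vector<double>& sum_cos2,
                           std::vector<double>& sum_sin) {
  for (int w = 0; w < wf.n(); ++w) {
    int p = wf.p1[w], q = wf.p2[w];
    if (wf.ptype[w] == 1) {
      double W0 = 0, W1 = 0, W2 = 0;
      if (p >= 0) {
        W0 += wf.a1[w] * M[3 * p];
        W1 += wf.a1[w] * M[3 * p + 1];
        W2 += wf.a1[w] * M[3 * p + 2];
      }
      if (q >= 0) {
        W0 += wf.a2[w] * M[3 * q];
        W1 += wf.a2[w] * M[3 * q + 1];
        W2 += wf.a2[w] * M[3 * q + 2];
      }
      double r = std::sqrt(W0 * W0 + W1 * W1 + W2 * W2);
      double c = (r < 1e-6) ? 1.0 - r * r / 6.0 : std::sin(r) / r;
      sum_cos[w] += c;
      sum_cos2[w] += c * c;
      continue;
    }
    double phi = 0.0;
    if (p >= 0) {
      phi += wf.a1[w] * (wf.n1[3 * w] * M[3 * p] +
                         wf.n1[3 * w + 1] * M[3 * p + 1] +
                         wf.n1[3 * w + 2] * M[3 * p + 2]);
    }
    if (q >= 0) {
      phi += wf.a2[w] * (wf.n2[3 * w] * M[3 * q] +
                         wf.n2[3 * w + 1] * M[3 * q + 1] +
                         wf.n2[3 * w + 2] * M[3 * q + 2]);
    }
    double c = std::cos(phi);
    sum_cos[w] += c;
    sum_cos2[w] += c * c;
    sum_sin[w] += std::sin(phi);
  }
}

} // namespace

// [[Rcpp::export]]
List mc_gaussian_cpp(NumericMatrix U, double dt, List chol_list,
                     NumericVector fractions, NumericMatrix rates,
                     IntegerVector wf_p1, NumericVector wf_a1, NumericMatrix wf_n1,
                     IntegerVector wf_p2, NumericVector wf_a2, NumericMatrix wf_n2,
                     int n_particles, int seed, IntegerVector record_steps,
                     IntegerVector wf_ptype) {
  const int n_steps = U.nrow(), n_prof = U.ncol();
  const int n_pool = fractions.size();
  WfTable wf = make_wf(wf_p1, wf_a1, wf_n1, wf_p2, wf_a2, wf_n2, wf_ptype);

  // per-pool factors of D with D = L L' (displacement = sqrt(2 dt) L z)
  std::vector<double> L(9 * n_pool);
  for (int p = 0; p < n_pool; ++p) {
    NumericMatrix Lp = chol_list[p];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) L[9 * p + 3 * c + r] = Lp(r, c);
  }
  std::vector<double> leave(n_pool, 0.0);
  for (int p = 0; p < n_pool; ++p)
    for (int q = 0; q < n_pool; ++q)
      if (q != p) leave[p] += rates(p, q);

  std::vector<double> cumf(n_pool);
  double acc = 0.0;
  for (int p = 0; p < n_pool; ++p) { acc += fractions[p]; cumf[p] = acc; }

  const int n_rec = record_steps.size();
  std::vector<double> match(n_rec, 0.0);
  std::vector<double> sum_cos(wf.n(), 0.0), sum_cos2(wf.n(), 0.0),
      sum_sin(wf.n(), 0.0);

  FastRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1);
  const double sq2dt = std::sqrt(2.0 * dt);

  std::vector<double> M(3 * n_prof);

  for (int i = 0; i < n_particles; ++i) {
    double u0 = rng.unif();
    int pool = 0;
    while (pool < n_pool - 1 && u0 > cumf[pool]) ++pool;
    const int pool0 = pool;
    std::fill(M.begin(), M.end(), 0.0);
    int rec = 0;
    for (int s = 0; s < n_steps; ++s) {
      if (leave[pool] > 0.0 && rng.unif() < leave[pool] * dt) {
        double u = rng.unif() * leave[pool];
        double a2 = 0.0;
        for (int q = 0; q < n_pool; ++q) {
          if (q == pool) continue;
          a2 += rates(pool, q);
          if (u <= a2) { pool = q; break; }
        }
      }
      double z0 = rng.gauss(), z1 = rng.gauss(), z2 = rng.gauss();
      const double* Lp = &L[9 * pool];
      double dx = sq2dt * (Lp[0] * z0 + Lp[3] * z1 + Lp[6] * z2);
      double dy = sq2dt * (Lp[1] * z0 + Lp[4] * z1 + Lp[7] * z2);
      double dz = sq2dt * (Lp[2] * z0 + Lp[5] * z1 + Lp[8] * z2);
      for (int j = 0; j < n_prof; ++j) {
        double u = U(s, j);
        if (u != 0.0) {
          M[3 * j] += u * dx;
          M[3 * j + 1] += u * dy;
          M[3 * j + 2] += u * dz;
        }
      }
      if (rec < n_rec && record_steps[rec] == s) {
        if (pool == pool0) match[rec] += 1.0;
        ++rec;
      }
    }
    score_particle(wf, M, sum_cos, sum_cos2, sum_sin);
  }

  return List::create(
    _["sum_cos"] = NumericVector(sum_cos.begin(), sum_cos.end()),
    _["sum_cos2"] = NumericVector(sum_cos2.begin(), sum_cos2.end()),
    _["sum_sin"] = NumericVector(sum_sin.begin(), sum_sin.end()),
    _["label_match"] = NumericVector(match.begin(), match.end()),
    _["n"] = n_particles);
}

namespace {

// geometry codes: 1 sphere lattice (or single sphere if L <= 0),
// 2 hexagonally packed parallel cylinders (axis z), 3 axially periodic beads
struct Geom {
  int kind;
  double R;      // sphere/cylinder radius
  double L;      // lattice constant (spheres: cubic; beads: square in xy)
  double a;      // cylinder hex spacing
  double r0, r1, period; // bead radius profile r(z) = r0 + r1 sin(2 pi z / P)
};

inline double nearest(double x, double L) { return L * std::round(x / L); }

// identity of the compartment cell a position belongs to; needed because
// near-touching packings let a step cross two walls (sphere-to-sphere
// through a contact point) without changing the inside/outside state
inline int64_t cell_id(const Geom& g, double x, double y, double z) {
  switch (g.kind) {
  case 1: {
    if (g.L <= 0) return 0;
    int64_t ix = (int64_t)std::llround(x / g.L);
    int64_t iy = (int64_t)std::llround(y / g.L);
    int64_t iz = (int64_t)std::llround(z / g.L);
    return ((ix * 73856093) ^ (iy * 19349663) ^ (iz * 83492791));
  }
  case 2: {
    double Ly = g.a * std::sqrt(3.0);
    double c0x = nearest(x, g.a), c0y = nearest(y, Ly);
    double c1x = nearest(x - 0.5 * g.a, g.a) + 0.5 * g.a;
    double c1y = nearest(y - 0.5 * Ly, Ly) + 0.5 * Ly;
    double d0 = (x - c0x) * (x - c0x) + (y - c0y) * (y - c0y);
    double d1 = (x - c1x) * (x - c1x) + (y - c1y) * (y - c1y);
    double cx = (d0 <= d1) ? c0x : c1x, cy = (d0 <= d1) ? c0y : c1y;
    int64_t ix = (int64_t)std::llround(cx * 1024.0);
    int64_t iy = (int64_t)std::llround(cy * 1024.0);
    return (ix * 73856093) ^ (iy * 19349663);
  }
  default: {
    int64_t ix = (int64_t)std::llround(x / g.L);
    int64_t iy = (int64_t)std::llround(y / g.L);
    return (ix * 73856093) ^ (iy * 19349663);
  }
  }
}

inline bool inside_geom(const Geom& g, double x, double y, double z) {
  switch (g.kind) {
  case 1: {
    double cx = 0, cy = 0, cz = 0;
    if (g.L > 0) { cx = nearest(x, g.L); cy = nearest(y, g.L); cz = nearest(z, g.L); }
    double dx = x - cx, dy = y - cy, dz = z - cz;
    return dx * dx + dy * dy + dz * dz < g.R * g.R;
  }
  case 2: {
    double Ly = g.a * std::sqrt(3.0);
    double c0x = nearest(x, g.a), c0y = nearest(y, Ly);
    double c1x = nearest(x - 0.5 * g.a, g.a) + 0.5 * g.a;
    double c1y = nearest(y - 0.5 * Ly, Ly) + 0.5 * Ly;
    double d0 = (x - c0x) * (x - c0x) + (y - c0y) * (y - c0y);
    double d1 = (x - c1x) * (x - c1x) + (y - c1y) * (y - c1y);
    return std::min(d0, d1) < g.R * g.R;
  }
  default: {
    // bead radius profile defined in r^2: r^2(z) = r0 + r1 sin(2 pi z / P)
    double cx = nearest(x, g.L), cy = nearest(y, g.L);
    double rho2 = (x - cx) * (x - cx) + (y - cy) * (y - cy);
    return rho2 < g.r0 + g.r1 * std::sin(2.0 * M_PI * z / g.period);
  }
  }
}

inline void surface_normal(const Geom& g, double x, double y, double z,
                           double& nx, double& ny, double& nz) {
  switch (g.kind) {
  case 1: {
    double cx = 0, cy = 0, cz = 0;
    if (g.L > 0) { cx = nearest(x, g.L); cy = nearest(y, g.L); cz = nearest(z, g.L); }
    nx = x - cx; ny = y - cy; nz = z - cz;
    break;
  }
  case 2: {
    double Ly = g.a * std::sqrt(3.0);
    double c0x = nearest(x, g.a), c0y = nearest(y, Ly);
    double c1x = nearest(x - 0.5 * g.a, g.a) + 0.5 * g.a;
    double c1y = nearest(y - 0.5 * Ly, Ly) + 0.5 * Ly;
    double d0 = (x - c0x) * (x - c0x) + (y - c0y) * (y - c0y);
    double d1 = (x - c1x) * (x - c1x) + (y - c1y) * (y - c1y);
    if (d0 <= d1) { nx = x - c0x; ny = y - c0y; } else { nx = x - c1x; ny = y - c1y; }
    nz = 0.0;
    break;
  }
  default: {
    // gradient of rho^2 - r0 - r1 sin(2 pi z / P)
    double cx = nearest(x, g.L), cy = nearest(y, g.L);
    nx = 2.0 * (x - cx);
    ny = 2.0 * (y - cy);
    nz = -g.r1 * (2.0 * M_PI / g.period) * std::cos(2.0 * M_PI * z / g.period);
    break;
  }
  }
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nn > 0) { nx /= nn; ny /= nn; nz /= nn; }
}

} // namespace

// [[Rcpp::export]]
List mc_restricted_cpp(NumericMatrix U, double dt, int geom_kind,
                       NumericVector geom_par, double D0, double kappa,
                       bool intra_only,
                       IntegerVector wf_p1, NumericVector wf_a1, NumericMatrix wf_n1,
                       IntegerVector wf_p2, NumericVector wf_a2, NumericMatrix wf_n2,
                       int n_particles, int seed, IntegerVector record_steps,
                       IntegerVector wf_ptype) {
  const int n_steps = U.nrow(), n_prof = U.ncol();
  WfTable wf = make_wf(wf_p1, wf_a1, wf_n1, wf_p2, wf_a2, wf_n2, wf_ptype);

  Geom g;
  g.kind = geom_kind;
  g.R = geom_par[0];
  g.L = geom_par[1];
  g.a = geom_par[2];
  g.r0 = geom_par[3];
  g.r1 = geom_par[4];
  g.period = geom_par[5];

  const double p_trans = (kappa > 0) ? kappa * std::sqrt(M_PI * dt / D0) : 0.0;
  const double sq2dt = std::sqrt(2.0 * D0 * dt);

  // extent of the periodic initialisation box
  double bx, by, bz;
  switch (g.kind) {
  case 1: bx = by = bz = (g.L > 0 ? g.L : 2 * g.R); break;
  case 2: bx = g.a; by = g.a * std::sqrt(3.0); bz = 10.0; break;
  default: bx = by = g.L; bz = g.period; break;
  }

  const int n_rec = record_steps.size();
  std::vector<double> match(n_rec, 0.0);
  std::vector<double> msd(3 * n_rec, 0.0);
  std::vector<double> sum_cos(wf.n(), 0.0), sum_cos2(wf.n(), 0.0),
      sum_sin(wf.n(), 0.0);
  double n_intra0 = 0.0;

  FastRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 7);

  std::vector<double> M(3 * n_prof);

  for (int i = 0; i < n_particles; ++i) {
    // uniform density; intra_only rejects extracellular starts
    double x, y, z;
    bool in;
    do {
      x = (rng.unif() - 0.5) * bx;
      y = (rng.unif() - 0.5) * by;
      z = (rng.unif() - 0.5) * bz;
      in = inside_geom(g, x, y, z);
    } while (intra_only && !in);
    const bool in0 = in;
    if (in0) n_intra0 += 1.0;
    int64_t cid = in ? cell_id(g, x, y, z) : 0;
    const double x0 = x, y0 = y, z0 = z;

    std::fill(M.begin(), M.end(), 0.0);
    int rec = 0;
    for (int s = 0; s < n_steps; ++s) {
      double dx = sq2dt * rng.gauss();
      double dy = sq2dt * rng.gauss();
      double dz = sq2dt * rng.gauss();
      double nx_ = x + dx, ny_ = y + dy, nz_ = z + dz;
      bool in_new = inside_geom(g, nx_, ny_, nz_);
      // a wall is crossed if the inside state flips, or if an intracellular
      // step lands in a *different* compartment (two walls crossed through a
      // near-contact region of the packing)
      int64_t cid_new = in_new ? cell_id(g, nx_, ny_, nz_) : 0;
      bool crossed = (in_new != in) || (in && in_new && cid_new != cid);
      if (crossed) {
        bool same_state;
        if (p_trans > 0.0 && (in_new != in) && rng.unif() < p_trans) {
          in = in_new; // permeation: straight crossing, label flips
          cid = cid_new;
        } else {
          // locate the first wall by bisection, then reflect specularly
          double lo = 0.0, hi = 1.0;
          for (int it = 0; it < 14; ++it) {
            double mid = 0.5 * (lo + hi);
            double mx = x + mid * dx, my = y + mid * dy, mz = z + mid * dz;
            same_state = inside_geom(g, mx, my, mz) == in &&
                         (!in || cell_id(g, mx, my, mz) == cid);
            if (same_state) lo = mid; else hi = mid;
          }
          double px = x + lo * dx, py = y + lo * dy, pz = z + lo * dz;
          double nxv, nyv, nzv;
          surface_normal(g, px, py, pz, nxv, nyv, nzv);
          double rx = (1.0 - lo) * dx, ry = (1.0 - lo) * dy, rz = (1.0 - lo) * dz;
          double dot = rx * nxv + ry * nyv + rz * nzv;
          rx -= 2.0 * dot * nxv; ry -= 2.0 * dot * nyv; rz -= 2.0 * dot * nzv;
          nx_ = px + rx; ny_ = py + ry; nz_ = pz + rz;
          bool ok = inside_geom(g, nx_, ny_, nz_) == in &&
                    (!in || cell_id(g, nx_, ny_, nz_) == cid);
          if (!ok) {
            nx_ = x; ny_ = y; nz_ = z; // rare corner case: reject the step
          }
        }
      }
      double ddx = nx_ - x, ddy = ny_ - y, ddz = nz_ - z;
      x = nx_; y = ny_; z = nz_;
      for (int j = 0; j < n_prof; ++j) {
        double u = U(s, j);
        if (u != 0.0) {
          M[3 * j] += u * ddx;
          M[3 * j + 1] += u * ddy;
          M[3 * j + 2] += u * ddz;
        }
      }
      if (rec < n_rec && record_steps[rec] == s) {
        if (in == in0) match[rec] += 1.0;
        msd[3 * rec] += (x - x0) * (x - x0);
        msd[3 * rec + 1] += (y - y0) * (y - y0);
        msd[3 * rec + 2] += (z - z0) * (z - z0);
        ++rec;
      }
    }
    score_particle(wf, M, sum_cos, sum_cos2, sum_sin);
  }

  NumericMatrix msd_out(n_rec, 3);
  for (int r = 0; r < n_rec; ++r)
    for (int d = 0; d < 3; ++d) msd_out(r, d) = msd[3 * r + d] / n_particles;

  return List::create(
    _["sum_cos"] = NumericVector(sum_cos.begin(), sum_cos.end()),
    _["sum_cos2"] = NumericVector(sum_cos2.begin(), sum_cos2.end()),
    _["sum_sin"] = NumericVector(sum_sin.begin(), sum_sin.end()),
    _["label_match"] = NumericVector(match.begin(), match.end()),
    _["msd"] = msd_out,
    _["n_intra0"] = n_intra0,
    _["n"] = n_particles);
}
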