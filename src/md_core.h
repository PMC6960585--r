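#pragma once

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Reduced units throughout: k_B T = sigma = m = 1, tau0 = 1.

struct FF {
  double fene_k;    // FENE spring constant, energy/length^2
  double fene_r0;   // FENE maximum extension
  double eps;       // WCA well depth (monomer-monomer)
  double sigma;     // monomer diameter
  double rc;        // WCA cutoff (2^{1/6} sigma in WCA mode)
  double wall_eps;  // wall repulsion strength
};

// mode: 0 = sphere with smooth radial wall, 1 = sphere with particulate wall,
//       2 = periodic cubic box (bulk reference, no wall)
struct Conf {
  int mode;
  double radius;
  double box;
  std::vector<double> wall;  // flattened 3*nw wall-particle coordinates
  int nw;
};

struct Breakdown {
  double fene = 0.0, pair = 0.0, bending = 0.0, wall = 0.0;
  double total() const { return fene + pair + bending + wall; }
};

inline FF parse_ff(const Rcpp::List& ff) {
  FF f;
  f.fene_k = Rcpp::as<double>(ff["fene_k"]);
  f.fene_r0 = Rcpp::as<double>(ff["fene_r0"]);
  f.eps = Rcpp::as<double>(ff["lj_epsilon"]);
  f.sigma = Rcpp::as<double>(ff["lj_sigma"]);
  f.rc = Rcpp::as<double>(ff["lj_cutoff"]);
  f.wall_eps = Rcpp::as<double>(ff["wall_epsilon"]);
  return f;
}

inline Conf parse_conf(const Rcpp::List& conf) {
  Conf c;
  c.mode = Rcpp::as<int>(conf["mode"]);
  c.radius = conf.containsElementNamed("radius") && !Rf_isNull(conf["radius"])
                 ? Rcpp::as<double>(conf["radius"])
                 : 0.0;
  c.box = conf.containsElementNamed("box_edge") && !Rf_isNull(conf["box_edge"])
              ? Rcpp::as<double>(conf["box_edge"])
              : 0.0;
  c.nw = 0;
  if (c.mode == 1) {
    Rcpp::NumericMatrix w = conf["wall_points"];
    c.nw = w.nrow();
    c.wall.resize(3 * c.nw);
    for (int i = 0; i < c.nw; ++i) {
      c.wall[3 * i] = w(i, 0);
      c.wall[3 * i + 1] = w(i, 1);
      c.wall[3 * i + 2] = w(i, 2);
    }
  }
  return c;
}

// WCA / shifted-truncated LJ: 4 eps [ (s/r)^12 - (s/r)^6 + 1/4 ] for r <= rc.
inline double wca_u(double r, double eps, double sigma, double rc) {
  if (r > rc) return 0.0;
  double sr2 = sigma * sigma / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6 + 0.25);
}

// -dU/dr (positive = repulsive, pushes the pair apart)
inline double wca_fmag(double r, double eps, double sigma, double rc) {
  if (r > rc) return 0.0;
  double sr2 = sigma * sigma / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
}

// Capped soft-core repulsion used during push-off: U = A (1 + cos(pi r / rc)).
inline double soft_u(double r, double a, double rc) {
  if (r > rc) return 0.0;
  return a * (1.0 + std::cos(M_PI * r / rc));
}

inline double soft_fmag(double r, double a, double rc) {
  if (r > rc) return 0.0;
  return a * M_PI / rc * std::sin(M_PI * r / rc);
}

// Deterministic RNG independent of the C++ standard library's distribution
// implementations: splitmix64-seeded xoshiro256++ with polar-method normals.
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double mul = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * mul;
    have_spare = true;
    return u * mul;
  }
};

double gauss_linking_raw(const double* a, int na, const double* b, int nb);
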