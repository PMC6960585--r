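#include "md_core.h"

using namespace Rcpp;

// Random sequential placement of rigid ring polygons / straight rods with
// monomer-level overlap rejection and, for ring pairs whose bounding spheres
// intersect, an explicit Gauss linking-number rejection (vertex distances
// alone cannot rule out concatenation).

namespace {

struct HashGrid {
  double cell;
  int nx, ny, nz;
  bool periodic;
  double box, x0;
  std::vector<std::vector<int>> bins;
  std::vector<double> pts;  // flattened accepted coordinates

  void init(double cell_size, const Conf& conf) {
    periodic = (conf.mode == 2);
    cell = cell_size;
    if (periodic) {
      box = conf.box;
      nx = ny = nz = std::max(1, (int)std::floor(box / cell));
      cell = box / nx;
      x0 = 0.0;
    } else {
      double span = 2.0 * conf.radius + 1e-6;
      nx = ny = nz = std::max(1, (int)std::ceil(span / cell));
      x0 = -conf.radius - 0.5e-6;
    }
    bins.assign((size_t)nx * ny * nz, {});
  }
  int comp(double u, int ncell) const {
    double v = u - x0;
    if (periodic) v -= box * std::floor(v / box);
    int k = (int)(v / cell);
    if (k < 0) k = 0;
    if (k >= ncell) k = ncell - 1;
    return k;
  }
  void insert(double x, double y, double z) {
    int c = (comp(z, nz) * ny + comp(y, ny)) * nx + comp(x, nx);
    bins[c].push_back((int)(pts.size() / 3));
    pts.push_back(x);
    pts.push_back(y);
    pts.push_back(z);
  }
  bool too_close(double x, double y, double z, double min_sep) const {
    int cx = comp(x, nx), cy = comp(y, ny), cz = comp(z, nz);
    double m2 = min_sep * min_sep;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ax = cx + dx, ay = cy + dy, az = cz + dz;
          if (periodic) {
            ax = (ax + nx) % nx;
            ay = (ay + ny) % ny;
            az = (az + nz) % nz;
          } else if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny ||
                     az >= nz)
            continue;
          for (int id : bins[(az * ny + ay) * nx + ax]) {
            double ddx = x - pts[3 * id], ddy = y - pts[3 * id + 1],
                   ddz = z - pts[3 * id + 2];
            if (periodic) {
              ddx -= box * std::round(ddx / box);
              ddy -= box * std::round(ddy / box);
              ddz -= box * std::round(ddz / box);
            }
            if (ddx * ddx + ddy * ddy + ddz * ddz < m2) return true;
          }
        }
    return false;
  }
};

void random_basis(Rng& rng, double* u, double* v, double* w) {
  double n2;
  do {
    w[0] = rng.norm();
    w[1] = rng.norm();
    w[2] = rng.norm();
    n2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  w[0] /= n;
  w[1] /= n;
  w[2] /= n;
  // any vector not parallel to w
  double a[3] = {1.0, 0.0, 0.0};
  if (std::fabs(w[0]) > 0.9) {
    a[0] = 0.0;
    a[1] = 1.0;
  }
  u[0] = w[1] * a[2] - w[2] * a[1];
  u[1] = w[2] * a[0] - w[0] * a[2];
  u[2] = w[0] * a[1] - w[1] * a[0];
  n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= n;
  u[1] /= n;
  u[2] /= n;
  v[0] = w[1] * u[2] - w[2] * u[1];
  v[1] = w[2] * u[0] - w[0] * u[2];
  v[2] = w[0] * u[1] - w[1] * u[0];
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix place_chains_cpp(IntegerVector n_mon, LogicalVector is_ring,
                               double bond_length, List conf_, double min_sep,
                               double wall_margin, int seed,
                               int max_attempts = 20000) {
  Conf conf = parse_conf(conf_);
  if (conf.mode != 2 && conf.radius <= 0) stop("invalid confinement radius");
  int m = n_mon.size();
  int n_total = 0;
  for (int c = 0; c < m; ++c) n_total += n_mon[c];
  NumericMatrix out(n_total, 3);
  Rng rng((uint64_t)(uint32_t)seed);

  HashGrid grid;
  grid.init(std::max(min_sep, 1.0), conf);
  grid.pts.reserve(3 * n_total);

  struct PlacedRing {
    std::vector<double> v;
    double cx, cy, cz, rad;
  };
  std::vector<PlacedRing> rings;

  int row = 0;
  for (int c = 0; c < m; ++c) {
    int n = n_mon[c];
    bool ring = is_ring[c];
    double rc_ring = ring ? bond_length / (2.0 * std::sin(M_PI / n)) : 0.0;
    bool ok = false;
    std::vector<double> cand(3 * n);
    for (int attempt = 0; attempt < max_attempts && !ok; ++attempt) {
      // candidate centre
      double cx, cy, cz;
      if (conf.mode == 2) {
        cx = rng.unif() * conf.box;
        cy = rng.unif() * conf.box;
        cz = rng.unif() * conf.box;
      } else {
        double rmax = conf.radius - wall_margin;
        do {
          cx = (2.0 * rng.unif() - 1.0) * rmax;
          cy = (2.0 * rng.unif() - 1.0) * rmax;
          cz = (2.0 * rng.unif() - 1.0) * rmax;
        } while (cx * cx + cy * cy + cz * cz > rmax * rmax);
      }
      double u[3], v[3], w[3];
      random_basis(rng, u, v, w);
      double phase = 2.0 * M_PI * rng.unif();
      for (int i = 0; i < n; ++i) {
        double lx, ly, lz;
        if (ring) {
          double ang = phase + 2.0 * M_PI * i / n;
          double a = rc_ring * std::cos(ang), b = rc_ring * std::sin(ang);
          lx = cx + a * u[0] + b * v[0];
          ly = cy + a * u[1] + b * v[1];
          lz = cz + a * u[2] + b * v[2];
        } else {
          double t = (i - 0.5 * (n - 1)) * bond_length;
          lx = cx + t * w[0];
          ly = cy + t * w[1];
          lz = cz + t * w[2];
        }
        cand[3 * i] = lx;
        cand[3 * i + 1] = ly;
        cand[3 * i + 2] = lz;
      }
      // wall feasibility
      bool fits = true;
      if (conf.mode != 2) {
        for (int i = 0; i < n && fits; ++i) {
          double r2 = cand[3 * i] * cand[3 * i] +
                      cand[3 * i + 1] * cand[3 * i + 1] +
                      cand[3 * i + 2] * cand[3 * i + 2];
          if (r2 > (conf.radius - wall_margin) * (conf.radius - wall_margin))
            fits = false;
        }
      }
      // inter-chain monomer separation
      for (int i = 0; i < n && fits; ++i)
        if (grid.too_close(cand[3 * i], cand[3 * i + 1], cand[3 * i + 2],
                           min_sep))
          fits = false;
      // non-concatenation against nearby placed rings
      if (fits && ring) {
        double crad = rc_ring;
        for (const auto& pr : rings) {
          double dx = cx - pr.cx, dy = cy - pr.cy, dz = cz - pr.cz;
          if (conf.mode == 2) {
            dx -= conf.box * std::round(dx / conf.box);
            dy -= conf.box * std::round(dy / conf.box);
            dz -= conf.box * std::round(dz / conf.box);
          }
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > crad + pr.rad) continue;
          double lk = gauss_linking_raw(cand.data(), n, pr.v.data(),
                                        (int)pr.v.size() / 3);
          if (std::fabs(lk) > 0.05) {
            fits = false;
            break;
          }
        }
      }
      if (fits) {
        for (int i = 0; i < n; ++i) {
          out(row + i, 0) = cand[3 * i];
          out(row + i, 1) = cand[3 * i + 1];
          out(row + i, 2) = cand[3 * i + 2];
          grid.insert(cand[3 * i], cand[3 * i + 1], cand[3 * i + 2]);
        }
        if (ring) {
          PlacedRing pr;
          pr.v = cand;
          pr.cx = 0;
          pr.cy = 0;
          pr.cz = 0;
          for (int i = 0; i < n; ++i) {
            pr.cx += cand[3 * i] / n;
            pr.cy += cand[3 * i + 1] / n;
            pr.cz += cand[3 * i + 2] / n;
          }
          pr.rad = rc_ring;
          rings.push_back(std::move(pr));
        }
        row += n;
        ok = true;
      }
    }
    if (!ok)
      stop("chain placement failed after %d attempts: placed %d of %d chains "
           "(%.1f%%); density too high for rejection placement",
           max_attempts, c, m, 100.0 * c / m);
  }
  return out;
}
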