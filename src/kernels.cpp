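#include "md_core.h"

#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pairwise neighbour machinery.  Cells have edge >= cutoff; the half-shell
// of 13 neighbour offsets (plus the home cell) visits every pair once.
// Wall particles (particulate sphere mode) are appended after the mobile
// monomers so they take part in the same pair loop but are never integrated.
// ---------------------------------------------------------------------------

struct CellGrid {
  int nx, ny, nz;
  double x0, y0, z0, cell;
  bool periodic;
  double box;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, int n, double cutoff,
             const Conf& conf) {
    periodic = (conf.mode == 2);
    if (periodic) {
      box = conf.box;
      nx = ny = nz = std::max(1, (int)std::floor(box / cutoff));
      cell = box / nx;
      x0 = y0 = z0 = 0.0;
    } else {
      double lo = -conf.radius - 1e-9, hi = conf.radius + 1e-9;
      nx = ny = nz = std::max(1, (int)std::floor((hi - lo) / cutoff));
      cell = (hi - lo) / nx;
      x0 = y0 = z0 = lo;
    }
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = idx(px[i] - x0, nx), cy = idx(py[i] - y0, ny),
          cz = idx(pz[i] - z0, nz);
      int c = (cz * ny + cy) * nx + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  int idx(double u, int ncell) const {
    int k;
    if (periodic) {
      u -= box * std::floor(u / box);
      k = (int)(u / cell);
      if (k >= ncell) k = ncell - 1;
    } else {
      k = (int)(u / cell);
      if (k < 0) k = 0;
      if (k >= ncell) k = ncell - 1;
    }
    return k;
  }
};

static const int HALF_SHELL[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

// Verlet pair list with skin: pairs within cutoff + skin, rebuilt (via the
// cell grid) whenever any particle has moved more than skin/2 since the last
// build, so no interacting pair is ever missed between rebuilds.
struct NeighborList {
  double skin = 0.4;
  std::vector<int> pairs;          // flattened (i, j)
  std::vector<double> ref;         // positions at last build
  bool built = false;

  bool needs_rebuild(const std::vector<double>& px,
                     const std::vector<double>& py,
                     const std::vector<double>& pz, int n_mobile) const {
    if (!built) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n_mobile; ++i) {
      double dx = px[i] - ref[3 * i], dy = py[i] - ref[3 * i + 1],
             dz = pz[i] - ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void build(const std::vector<double>& px, const std::vector<double>& py,
             const std::vector<double>& pz, int n_mobile, int n_total,
             double cutoff, const Conf& conf) {
    double rlist = cutoff + skin;
    pairs.clear();
    bool periodic = (conf.mode == 2);
    double box = conf.box;
    double rl2 = rlist * rlist;
    auto consider = [&](int i, int j) {
      if (i >= n_mobile && j >= n_mobile) return;  // wall-wall
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      if (periodic) {
        dx -= box * std::round(dx / box);
        dy -= box * std::round(dy / box);
        dz -= box * std::round(dz / box);
      }
      if (dx * dx + dy * dy + dz * dz < rl2) {
        pairs.push_back(i);
        pairs.push_back(j);
      }
    };
    if (!(periodic && std::floor(box / rlist) < 3)) {
      CellGrid g;
      g.build(px, py, pz, n_total, rlist, conf);
      for (int cz = 0; cz < g.nz; ++cz)
        for (int cy = 0; cy < g.ny; ++cy)
          for (int cx = 0; cx < g.nx; ++cx) {
            int c = (cz * g.ny + cy) * g.nx + cx;
            if (g.head[c] < 0) continue;
            for (int i = g.head[c]; i >= 0; i = g.nxt[i])
              for (int j = g.nxt[i]; j >= 0; j = g.nxt[j]) consider(i, j);
            for (int s = 0; s < 13; ++s) {
              int ax = cx + HALF_SHELL[s][0], ay = cy + HALF_SHELL[s][1],
                  az = cz + HALF_SHELL[s][2];
              if (g.periodic) {
                ax = (ax + g.nx) % g.nx;
                ay = (ay + g.ny) % g.ny;
                az = (az + g.nz) % g.nz;
              } else if (ax < 0 || ay < 0 || az < 0 || ax >= g.nx ||
                         ay >= g.ny || az >= g.nz)
                continue;
              int c2 = (az * g.ny + ay) * g.nx + ax;
              for (int i = g.head[c]; i >= 0; i = g.nxt[i])
                for (int j = g.head[c2]; j >= 0; j = g.nxt[j]) consider(i, j);
            }
          }
    } else {
      for (int i = 0; i < n_total; ++i)
        for (int j = i + 1; j < n_total; ++j) consider(i, j);
    }
    ref.resize(3 * n_mobile);
    for (int i = 0; i < n_mobile; ++i) {
      ref[3 * i] = px[i];
      ref[3 * i + 1] = py[i];
      ref[3 * i + 2] = pz[i];
    }
    built = true;
  }
};

struct PairAccum {
  // pair_style: 0 = WCA, 1 = capped soft repulsion for non-bonded pairs
  // (push-off ramp; bonded pairs keep FENE+WCA so bond lengths stay at
  // their equilibrium during the ramp)
  int pair_style;
  double soft_a;
  const std::unordered_set<uint64_t>* bonded = nullptr;
  const FF* ff;
  bool periodic;
  double box;
  int n_mobile;  // indices >= n_mobile are static wall particles
  double e_pair = 0.0, e_wall = 0.0;
  double* fx;
  double* fy;
  double* fz;

  inline void interact(int i, int j, const std::vector<double>& px,
                       const std::vector<double>& py,
                       const std::vector<double>& pz, double cutoff) {
    bool iw = i >= n_mobile, jw = j >= n_mobile;
    if (iw && jw) return;  // wall-wall: static, ignored
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    if (periodic) {
      dx -= box * std::round(dx / box);
      dy -= box * std::round(dy / box);
      dz -= box * std::round(dz / box);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cutoff * cutoff) return;
    double r = std::sqrt(r2);
    if (r <= 0.0) stop("coincident particles (r = 0) between atoms %d and %d",
                       i + 1, j + 1);
    double u, fmag;
    if (iw || jw) {  // monomer-wall: always full WCA at wall_epsilon
      u = wca_u(r, ff->wall_eps, ff->sigma, ff->rc);
      fmag = wca_fmag(r, ff->wall_eps, ff->sigma, ff->rc);
      e_wall += u;
    } else if (pair_style == 1 &&
               !(bonded && bonded->count(((uint64_t)std::min(i, j) << 32) |
                                         (uint64_t)std::max(i, j)))) {
      u = soft_u(r, soft_a, ff->rc);
      fmag = soft_fmag(r, soft_a, ff->rc);
      e_pair += u;
    } else {
      u = wca_u(r, ff->eps, ff->sigma, ff->rc);
      fmag = wca_fmag(r, ff->eps, ff->sigma, ff->rc);
      e_pair += u;
    }
    double s = fmag / r;
    if (!iw) {
      fx[i] += s * dx;
      fy[i] += s * dy;
      fz[i] += s * dz;
    }
    if (!jw) {
      fx[j] -= s * dx;
      fy[j] -= s * dy;
      fz[j] -= s * dz;
    }
  }
};

// Full force + energy evaluation.  Accumulation order is fixed (bond, pair,
// angle, wall) so repeated evaluations are bit-reproducible.
static Breakdown eval_forces(const std::vector<double>& px,
                             const std::vector<double>& py,
                             const std::vector<double>& pz, int n_mobile,
                             int n_total, const IntegerMatrix& bonds,
                             const IntegerMatrix& angles,
                             const NumericVector& angle_k, const FF& ff,
                             const Conf& conf, int pair_style, double soft_a,
                             bool use_cells, std::vector<double>& fx,
                             std::vector<double>& fy, std::vector<double>& fz,
                             NeighborList* nl = nullptr) {
  Breakdown e;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const bool periodic = (conf.mode == 2);
  const double box = conf.box;

  // 1. FENE bonds (bonded pairs additionally get the pair term below)
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    if (periodic) {
      dx -= box * std::round(dx / box);
      dy -= box * std::round(dy / box);
      dz -= box * std::round(dz / box);
    }
    double r2 = dx * dx + dy * dy + dz * dz;
    double r02 = ff.fene_r0 * ff.fene_r0;
    if (r2 >= r02)
      stop("FENE bond overstretched: bond %d (atoms %d-%d), r = %.4f >= R0 = %.4f",
           b + 1, i + 1, j + 1, std::sqrt(r2), ff.fene_r0);
    double x = r2 / r02;
    e.fene += -0.5 * ff.fene_k * r02 * std::log(1.0 - x);
    double s = -ff.fene_k / (1.0 - x);  // F = s * dr (attractive)
    fx[i] += s * dx;
    fy[i] += s * dy;
    fz[i] += s * dz;
    fx[j] -= s * dx;
    fy[j] -= s * dy;
    fz[j] -= s * dz;
  }

  // 2. non-bonded (and bonded) pair repulsion, incl. particulate wall
  std::unordered_set<uint64_t> bonded_set;
  if (pair_style == 1) {
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      bonded_set.insert(((uint64_t)std::min(i, j) << 32) |
                        (uint64_t)std::max(i, j));
    }
  }
  PairAccum acc;
  acc.pair_style = pair_style;
  acc.soft_a = soft_a;
  acc.bonded = pair_style == 1 ? &bonded_set : nullptr;
  acc.ff = &ff;
  acc.periodic = periodic;
  acc.box = box;
  acc.n_mobile = n_mobile;
  acc.fx = fx.data();
  acc.fy = fy.data();
  acc.fz = fz.data();
  double cutoff = ff.rc;

  NeighborList local;
  bool cells_ok = use_cells && n_total >= 64;
  if (cells_ok) {
    if (!nl) nl = &local;
    if (nl->needs_rebuild(px, py, pz, n_mobile)) {
      nl->build(px, py, pz, n_mobile, n_total, cutoff, conf);
    }
    const int np = (int)nl->pairs.size() / 2;
    for (int p = 0; p < np; ++p) {
      acc.interact(nl->pairs[2 * p], nl->pairs[2 * p + 1], px, py, pz, cutoff);
    }
  } else {
    for (int i = 0; i < n_total; ++i)
      for (int j = i + 1; j < n_total; ++j) acc.interact(i, j, px, py, pz, cutoff);
  }
  e.pair = acc.e_pair;
  e.wall += acc.e_wall;

  // 3. bending: U = k_b (1 + cos theta), theta the interior angle at the
  //    middle monomer (pi when the two bonds are collinear)
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double ax = px[i] - px[j], ay = py[i] - py[j], az = pz[i] - pz[j];
    double bx = px[k] - px[j], by = py[k] - py[j], bz = pz[k] - pz[j];
    if (periodic) {
      ax -= box * std::round(ax / box);
      ay -= box * std::round(ay / box);
      az -= box * std::round(az / box);
      bx -= box * std::round(bx / box);
      by -= box * std::round(by / box);
      bz -= box * std::round(bz / box);
    }
    double ra = std::sqrt(ax * ax + ay * ay + az * az);
    double rb = std::sqrt(bx * bx + by * by + bz * bz);
    double c = (ax * bx + ay * by + az * bz) / (ra * rb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double kb = angle_k[a];
    e.bending += kb * (1.0 + c);
    // F = -kb * grad(cos theta)
    double gxi = bx / (ra * rb) - c * ax / (ra * ra);
    double gyi = by / (ra * rb) - c * ay / (ra * ra);
    double gzi = bz / (ra * rb) - c * az / (ra * ra);
    double gxk = ax / (ra * rb) - c * bx / (rb * rb);
    double gyk = ay / (ra * rb) - c * by / (rb * rb);
    double gzk = az / (ra * rb) - c * bz / (rb * rb);
    fx[i] -= kb * gxi;
    fy[i] -= kb * gyi;
    fz[i] -= kb * gzi;
    fx[k] -= kb * gxk;
    fy[k] -= kb * gyk;
    fz[k] -= kb * gzk;
    fx[j] += kb * (gxi + gxk);
    fy[j] += kb * (gyi + gyk);
    fz[j] += kb * (gzi + gzk);
  }

  // 4. smooth wall: WCA on the radial gap d = R - |r|
  if (conf.mode == 0) {
    for (int i = 0; i < n_mobile; ++i) {
      double r = std::sqrt(px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i]);
      if (r >= conf.radius)
        stop("monomer %d escaped the sphere: |r| = %.4f >= R = %.4f", i + 1, r,
             conf.radius);
      double gap = conf.radius - r;
      if (gap <= ff.rc) {
        e.wall += wca_u(gap, ff.wall_eps, ff.sigma, ff.rc);
        double fmag = wca_fmag(gap, ff.wall_eps, ff.sigma, ff.rc);  // > 0
        if (r > 0) {
          double s = -fmag / r;  // push inward, along -r_hat
          fx[i] += s * px[i];
          fy[i] += s * py[i];
          fz[i] += s * pz[i];
        }
      }
    }
  } else if (conf.mode == 1) {
    for (int i = 0; i < n_mobile; ++i) {
      double r = std::sqrt(px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i]);
      if (r >= conf.radius)
        stop("monomer %d escaped the sphere: |r| = %.4f >= R = %.4f", i + 1, r,
             conf.radius);
    }
  }
  return e;
}

static void load_system(const NumericMatrix& pos, const Conf& conf,
                        std::vector<double>& px, std::vector<double>& py,
                        std::vector<double>& pz, int& n_mobile, int& n_total) {
  n_mobile = pos.nrow();
  n_total = n_mobile + conf.nw;
  px.resize(n_total);
  py.resize(n_total);
  pz.resize(n_total);
  for (int i = 0; i < n_mobile; ++i) {
    px[i] = pos(i, 0);
    py[i] = pos(i, 1);
    pz[i] = pos(i, 2);
  }
  for (int w = 0; w < conf.nw; ++w) {
    px[n_mobile + w] = conf.wall[3 * w];
    py[n_mobile + w] = conf.wall[3 * w + 1];
    pz[n_mobile + w] = conf.wall[3 * w + 2];
  }
}

// [[Rcpp::export]]
List energy_cpp(NumericMatrix pos, IntegerMatrix bonds, IntegerMatrix angles,
                NumericVector angle_k, List ff_, List conf_,
                int pair_style = 0, double soft_a = 0.0,
                bool use_cells = true) {
  FF ff = parse_ff(ff_);
  Conf conf = parse_conf(conf_);
  std::vector<double> px, py, pz;
  int n_mobile, n_total;
  load_system(pos, conf, px, py, pz, n_mobile, n_total);
  std::vector<double> fx(n_total), fy(n_total), fz(n_total);
  Breakdown e = eval_forces(px, py, pz, n_mobile, n_total, bonds, angles,
                            angle_k, ff, conf, pair_style, soft_a, use_cells,
                            fx, fy, fz);
  return List::create(_["fene"] = e.fene, _["pair"] = e.pair,
                      _["bending"] = e.bending, _["wall"] = e.wall,
                      _["total"] = e.total());
}

// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerMatrix bonds,
                         IntegerMatrix angles, NumericVector angle_k, List ff_,
                         List conf_, int pair_style = 0, double soft_a = 0.0,
                         bool use_cells = true) {
  FF ff = parse_ff(ff_);
  Conf conf = parse_conf(conf_);
  std::vector<double> px, py, pz;
  int n_mobile, n_total;
  load_system(pos, conf, px, py, pz, n_mobile, n_total);
  std::vector<double> fx(n_total), fy(n_total), fz(n_total);
  eval_forces(px, py, pz, n_mobile, n_total, bonds, angles, angle_k, ff, conf,
              pair_style, soft_a, use_cells, fx, fy, fz);
  NumericMatrix out(n_mobile, 3);
  for (int i = 0; i < n_mobile; ++i) {
    out(i, 0) = fx[i];
    out(i, 1) = fy[i];
    out(i, 2) = fz[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// NVT / NVE integration: velocity Verlet with an optional single-variable
// Nose-Hoover thermostat (friction xi, coupling mass Q).  The half-kick with
// friction is applied explicitly; the closing half-kick is semi-implicit,
//   v(t+dt) = (v_half + dt/2 F(t+dt)) / (1 + dt/2 xi(t+dt)).
// With the thermostat off this reduces to plain (symplectic) velocity Verlet.
// The optional soft-pair ramp grows the capped repulsion linearly from
// soft_a0 to soft_a1 across the run (builder push-off).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bonds,
                IntegerMatrix angles, NumericVector angle_k, List ff_,
                List conf_, double dt, int nsteps, int sample_every,
                bool thermostat, double tstar, double q, double xi0,
                int pair_style = 0, double soft_a0 = 0.0, double soft_a1 = 0.0,
                bool record_velocities = true, bool use_cells = true,
                int temp_every = 10) {
  FF ff = parse_ff(ff_);
  Conf conf = parse_conf(conf_);
  std::vector<double> px, py, pz;
  int n_mobile, n_total;
  load_system(pos, conf, px, py, pz, n_mobile, n_total);
  std::vector<double> vx(n_mobile), vy(n_mobile), vz(n_mobile);
  for (int i = 0; i < n_mobile; ++i) {
    vx[i] = vel(i, 0);
    vy[i] = vel(i, 1);
    vz[i] = vel(i, 2);
  }
  std::vector<double> fx(n_total), fy(n_total), fz(n_total);
  const double ndof = 3.0 * n_mobile - 3.0;
  double xi = xi0;

  int n_samples = (sample_every > 0) ? nsteps / sample_every : 0;
  List frames(n_samples), frame_vel(record_velocities ? n_samples : 0);
  IntegerVector frame_step(n_samples);
  NumericMatrix energy(n_samples, 5);
  int n_temp = (temp_every > 0) ? nsteps / temp_every : 0;
  NumericVector temp_trace(n_temp);

  double soft_a = soft_a0;
  NeighborList nlist;
  Breakdown e = eval_forces(px, py, pz, n_mobile, n_total, bonds, angles,
                            angle_k, ff, conf, pair_style, soft_a, use_cells,
                            fx, fy, fz, &nlist);
  int isamp = 0, itemp = 0;
  for (int step = 1; step <= nsteps; ++step) {
    double h = 0.5 * dt;
    if (thermostat) {
      for (int i = 0; i < n_mobile; ++i) {
        vx[i] += h * (fx[i] - xi * vx[i]);
        vy[i] += h * (fy[i] - xi * vy[i]);
        vz[i] += h * (fz[i] - xi * vz[i]);
      }
    } else {
      for (int i = 0; i < n_mobile; ++i) {
        vx[i] += h * fx[i];
        vy[i] += h * fy[i];
        vz[i] += h * fz[i];
      }
    }
    for (int i = 0; i < n_mobile; ++i) {
      px[i] += dt * vx[i];
      py[i] += dt * vy[i];
      pz[i] += dt * vz[i];
    }
    double ke2 = 0.0;
    if (thermostat || (temp_every > 0 && step % temp_every == 0)) {
      for (int i = 0; i < n_mobile; ++i)
        ke2 += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    if (thermostat) xi += dt * (ke2 - ndof * tstar) / q;
    if (pair_style == 1 && nsteps > 0)
      soft_a = soft_a0 + (soft_a1 - soft_a0) * ((double)step / nsteps);
    e = eval_forces(px, py, pz, n_mobile, n_total, bonds, angles, angle_k, ff,
                    conf, pair_style, soft_a, use_cells, fx, fy, fz, &nlist);
    if (thermostat) {
      double denom = 1.0 + h * xi;
      for (int i = 0; i < n_mobile; ++i) {
        vx[i] = (vx[i] + h * fx[i]) / denom;
        vy[i] = (vy[i] + h * fy[i]) / denom;
        vz[i] = (vz[i] + h * fz[i]) / denom;
      }
    } else {
      for (int i = 0; i < n_mobile; ++i) {
        vx[i] += h * fx[i];
        vy[i] += h * fy[i];
        vz[i] += h * fz[i];
      }
    }
    if (temp_every > 0 && step % temp_every == 0 && itemp < n_temp)
      temp_trace[itemp++] = ke2 / ndof;  // half-step kinetic estimate
    if (sample_every > 0 && step % sample_every == 0 && isamp < n_samples) {
      NumericMatrix fp(n_mobile, 3);
      for (int i = 0; i < n_mobile; ++i) {
        fp(i, 0) = px[i];
        fp(i, 1) = py[i];
        fp(i, 2) = pz[i];
      }
      frames[isamp] = fp;
      if (record_velocities) {
        NumericMatrix fv(n_mobile, 3);
        for (int i = 0; i < n_mobile; ++i) {
          fv(i, 0) = vx[i];
          fv(i, 1) = vy[i];
          fv(i, 2) = vz[i];
        }
        frame_vel[isamp] = fv;
      }
      frame_step[isamp] = step;
      energy(isamp, 0) = e.fene;
      energy(isamp, 1) = e.pair;
      energy(isamp, 2) = e.bending;
      energy(isamp, 3) = e.wall;
      energy(isamp, 4) = e.total();
      ++isamp;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pout(n_mobile, 3), vout(n_mobile, 3);
  for (int i = 0; i < n_mobile; ++i) {
    pout(i, 0) = px[i];
    pout(i, 1) = py[i];
    pout(i, 2) = pz[i];
    vout(i, 0) = vx[i];
    vout(i, 1) = vy[i];
    vout(i, 2) = vz[i];
  }
  colnames(energy) = CharacterVector::create("fene", "pair", "bending", "wall",
                                             "total");
  return List::create(
      _["positions"] = pout, _["velocities"] = vout, _["xi"] = xi,
      _["frames"] = frames, _["frame_velocities"] = frame_vel,
      _["frame_step"] = frame_step, _["energy"] = energy,
      _["temperature"] = temp_trace);
}

// Minimum monomer-monomer separations (overall and between different chains).
// [[Rcpp::export]]
List min_separation_cpp(NumericMatrix pos, IntegerVector chain_id, List conf_,
                        double search_cutoff = 2.0) {
  Conf conf = parse_conf(conf_);
  conf.nw = 0;  // walls irrelevant here
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i, 0);
    py[i] = pos(i, 1);
    pz[i] = pos(i, 2);
  }
  double min_all = R_PosInf, min_inter = R_PosInf;
  bool periodic = (conf.mode == 2);
  auto consider = [&](int i, int j) {
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    if (periodic) {
      dx -= conf.box * std::round(dx / conf.box);
      dy -= conf.box * std::round(dy / conf.box);
      dz -= conf.box * std::round(dz / conf.box);
    }
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < min_all) min_all = r;
    if (chain_id[i] != chain_id[j] && r < min_inter) min_inter = r;
  };
  bool cells_ok = n >= 64 && !(periodic && std::floor(conf.box / search_cutoff) < 3);
  if (cells_ok) {
    CellGrid g;
    g.build(px, py, pz, n, search_cutoff, conf);
    for (int cz = 0; cz < g.nz; ++cz)
      for (int cy = 0; cy < g.ny; ++cy)
        for (int cx = 0; cx < g.nx; ++cx) {
          int c = (cz * g.ny + cy) * g.nx + cx;
          for (int i = g.head[c]; i >= 0; i = g.nxt[i])
            for (int j = g.nxt[i]; j >= 0; j = g.nxt[j]) consider(i, j);
          for (int s = 0; s < 13; ++s) {
            int ax = cx + HALF_SHELL[s][0], ay = cy + HALF_SHELL[s][1],
                az = cz + HALF_SHELL[s][2];
            if (g.periodic) {
              ax = (ax + g.nx) % g.nx;
              ay = (ay + g.ny) % g.ny;
              az = (az + g.nz) % g.nz;
            } else if (ax < 0 || ay < 0 || az < 0 || ax >= g.nx ||
                       ay >= g.ny || az >= g.nz)
              continue;
            int c2 = (az * g.ny + ay) * g.nx + ax;
            for (int i = g.head[c]; i >= 0; i = g.nxt[i])
              for (int j = g.head[c2]; j >= 0; j = g.nxt[j]) consider(i, j);
          }
        }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  }
  return List::create(_["min_all"] = min_all, _["min_interchain"] = min_inter);
}
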