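#include "md_core.h"

using namespace Rcpp;

// Gauss linking number of two closed polylines, evaluated exactly per
// segment pair via the solid angle of the connecting tetrahedron
// (Klenin & Langowski 2000, method 1a).  For polygons the summed value is
// an integer up to floating-point rounding, so refinement invariance holds
// by construction.

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline bool unit3(double* v) {
  double n = std::sqrt(dot3(v, v));
  if (n < 1e-14) return false;
  v[0] /= n;
  v[1] /= n;
  v[2] /= n;
  return true;
}

static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// contribution of segment pair (p1->p2, p3->p4) to 4*pi*Lk
static double segment_pair_omega(const double* p1, const double* p2,
                                 const double* p3, const double* p4) {
  double r13[3], r14[3], r23[3], r24[3], s1[3], s2[3];
  for (int k = 0; k < 3; ++k) {
    r13[k] = p3[k] - p1[k];
    r14[k] = p4[k] - p1[k];
    r23[k] = p3[k] - p2[k];
    r24[k] = p4[k] - p2[k];
    s1[k] = p2[k] - p1[k];
    s2[k] = p4[k] - p3[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  // coplanar degenerate quadrilateral contributes zero solid angle
  if (!unit3(n1) || !unit3(n2) || !unit3(n3) || !unit3(n4)) return 0.0;
  double omega = std::asin(clamp1(dot3(n1, n2))) +
                 std::asin(clamp1(dot3(n2, n3))) +
                 std::asin(clamp1(dot3(n3, n4))) +
                 std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(s1, s2, cr);
  double sgn = dot3(cr, r13) >= 0.0 ? 1.0 : -1.0;
  return omega * sgn;
}

// a, b: flattened row-major n x 3 vertex arrays of the two closed curves
double gauss_linking_raw(const double* a, int na, const double* b, int nb) {
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    const double* p1 = a + 3 * i;
    const double* p2 = a + 3 * ((i + 1) % na);
    double s1 = 0.0;
    for (int k = 0; k < 3; ++k) s1 += (p2[k] - p1[k]) * (p2[k] - p1[k]);
    if (s1 < 1e-20) Rcpp::stop("degenerate (zero-length) segment in ring");
    for (int j = 0; j < nb; ++j) {
      const double* p3 = b + 3 * j;
      const double* p4 = b + 3 * ((j + 1) % nb);
      double s2 = 0.0;
      for (int k = 0; k < 3; ++k) s2 += (p4[k] - p3[k]) * (p4[k] - p3[k]);
      if (s2 < 1e-20) Rcpp::stop("degenerate (zero-length) segment in ring");
      total += segment_pair_omega(p1, p2, p3, p4);
    }
  }
  return total / (4.0 * M_PI);
}

// [[Rcpp::export]]
double linking_number_cpp(NumericMatrix ring_a, NumericMatrix ring_b) {
  int na = ring_a.nrow(), nb = ring_b.nrow();
  if (na < 3 || nb < 3) stop("rings need at least 3 vertices");
  std::vector<double> a(3 * na), b(3 * nb);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) a[3 * i + k] = ring_a(i, k);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < 3; ++k) b[3 * i + k] = ring_b(i, k);
  return gauss_linking_raw(a.data(), na, b.data(), nb);
}

// All-pairs raw linking numbers for the rings listed by (start, n) slices of
// pos.  Pairs whose bounding spheres are disjoint are reported as exactly 0
// without evaluating the double sum (disjoint hulls cannot be linked).
// [[Rcpp::export]]
NumericMatrix pairwise_linking_cpp(NumericMatrix pos, IntegerVector start,
                                   IntegerVector len) {
  int m = start.size();
  std::vector<std::vector<double>> rings(m);
  std::vector<double> cx(m), cy(m), cz(m), rad(m);
  for (int c = 0; c < m; ++c) {
    rings[c].resize(3 * len[c]);
    double sx = 0, sy = 0, sz = 0;
    for (int i = 0; i < len[c]; ++i) {
      int a = start[c] + i;
      rings[c][3 * i] = pos(a, 0);
      rings[c][3 * i + 1] = pos(a, 1);
      rings[c][3 * i + 2] = pos(a, 2);
      sx += pos(a, 0);
      sy += pos(a, 1);
      sz += pos(a, 2);
    }
    cx[c] = sx / len[c];
    cy[c] = sy / len[c];
    cz[c] = sz / len[c];
    double r2max = 0;
    for (int i = 0; i < len[c]; ++i) {
      double dx = rings[c][3 * i] - cx[c], dy = rings[c][3 * i + 1] - cy[c],
             dz = rings[c][3 * i + 2] - cz[c];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > r2max) r2max = r2;
    }
    rad[c] = std::sqrt(r2max);
  }
  NumericMatrix out(m, m);
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double lk = 0.0;
      if (d <= rad[i] + rad[j])
        lk = gauss_linking_raw(rings[i].data(), len[i], rings[j].data(),
                               len[j]);
      out(i, j) = lk;
      out(j, i) = lk;
    }
  return out;
}
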