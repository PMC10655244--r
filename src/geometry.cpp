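// Mesh / geometry kernels: minimal-surface relaxation for ring contours,
// segment-triangle intersection, radial distribution histograms, and
// nearest-monomer distances for counterion condensation diagnostics.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// Total mesh area and gradient with respect to every vertex.
// Gradient of one triangle's area wrt vertex a is 0.5 * (b - c) x n_hat.
static double mesh_area_grad(const std::vector<double> &vx,
                             const std::vector<double> &vy,
                             const std::vector<double> &vz,
                             const std::vector<int> &t0,
                             const std::vector<int> &t1,
                             const std::vector<int> &t2,
                             std::vector<double> &gx, std::vector<double> &gy,
                             std::vector<double> &gz, bool want_grad) {
  double area = 0.0;
  if (want_grad) {
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
  }
  const size_t nt = t0.size();
  for (size_t m = 0; m < nt; ++m) {
    int a = t0[m], b = t1[m], c = t2[m];
    double u[3] = {vx[b] - vx[a], vy[b] - vy[a], vz[b] - vz[a]};
    double v[3] = {vx[c] - vx[a], vy[c] - vy[a], vz[c] - vz[a]};
    double w[3];
    cross3(u, v, w);
    double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    area += 0.5 * nw;
    if (!want_grad || nw < 1e-14) continue;
    double nh[3] = {w[0] / nw, w[1] / nw, w[2] / nw};
    // vertex a: opposite edge (b, c)
    double e[3], g[3];
    e[0] = vx[b] - vx[c]; e[1] = vy[b] - vy[c]; e[2] = vz[b] - vz[c];
    cross3(e, nh, g);
    gx[a] += 0.5 * g[0]; gy[a] += 0.5 * g[1]; gz[a] += 0.5 * g[2];
    // vertex b: opposite edge (c, a)
    e[0] = vx[c] - vx[a]; e[1] = vy[c] - vy[a]; e[2] = vz[c] - vz[a];
    cross3(e, nh, g);
    gx[b] += 0.5 * g[0]; gy[b] += 0.5 * g[1]; gz[b] += 0.5 * g[2];
    // vertex c: opposite edge (a, b)
    e[0] = vx[a] - vx[b]; e[1] = vy[a] - vy[b]; e[2] = vz[a] - vz[b];
    cross3(e, nh, g);
    gx[c] += 0.5 * g[0]; gy[c] += 0.5 * g[1]; gz[c] += 0.5 * g[2];
  }
  return area;
}

// Relax a disk mesh spanned on a closed ring contour. Boundary vertices
// (the first N) stay fixed; interior ghost vertices follow a backtracking
// gradient descent of the total area. Convergence: relative area change
// over `window` consecutive steps <= tol.
// [[Rcpp::export]]
List rs_minimal_surface(NumericMatrix boundary, int n_rings, double tol,
                        int window, int max_steps) {
  const int N = boundary.nrow();
  if (N < 3) stop("ring contour needs at least 3 vertices");
  if (n_rings < 1) n_rings = 1;
  // centroid
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < N; ++i) {
    cx += boundary(i, 0); cy += boundary(i, 1); cz += boundary(i, 2);
  }
  cx /= N; cy /= N; cz /= N;

  // vertices: N boundary + n_rings * N interior (scaled copies) + centre
  const int nv = N + n_rings * N + 1;
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < N; ++i) {
    vx[i] = boundary(i, 0); vy[i] = boundary(i, 1); vz[i] = boundary(i, 2);
  }
  for (int r = 1; r <= n_rings; ++r) {
    double f = 1.0 - (double)r / (n_rings + 1);
    for (int i = 0; i < N; ++i) {
      int id = r * N + i;
      vx[id] = cx + f * (boundary(i, 0) - cx);
      vy[id] = cy + f * (boundary(i, 1) - cy);
      vz[id] = cz + f * (boundary(i, 2) - cz);
    }
  }
  vx[nv - 1] = cx; vy[nv - 1] = cy; vz[nv - 1] = cz;

  // triangles: quad strips between consecutive rings + centre fan
  std::vector<int> t0, t1, t2;
  for (int r = 0; r < n_rings; ++r) {
    for (int i = 0; i < N; ++i) {
      int i2 = (i + 1) % N;
      int a = r * N + i, b = r * N + i2;
      int a1 = (r + 1) * N + i, b1 = (r + 1) * N + i2;
      t0.push_back(a); t1.push_back(b); t2.push_back(a1);
      t0.push_back(b); t1.push_back(b1); t2.push_back(a1);
    }
  }
  for (int i = 0; i < N; ++i) {
    int i2 = (i + 1) % N;
    t0.push_back(n_rings * N + i);
    t1.push_back(n_rings * N + i2);
    t2.push_back(nv - 1);
  }

  std::vector<double> gx(nv), gy(nv), gz(nv);
  double area = mesh_area_grad(vx, vy, vz, t0, t1, t2, gx, gy, gz, true);
  const double area0 = area;
  double eta = 0.05;
  std::vector<double> hist;
  hist.reserve(max_steps + 1);
  hist.push_back(area);
  bool converged = false;
  int step = 0;
  std::vector<double> nx(nv), ny(nv), nz(nv);
  for (step = 1; step <= max_steps; ++step) {
    // try step on free vertices only
    bool ok = false;
    double newarea = area;
    for (int tries = 0; tries < 40 && !ok; ++tries) {
      nx = vx; ny = vy; nz = vz;
      for (int i = N; i < nv; ++i) {
        nx[i] -= eta * gx[i]; ny[i] -= eta * gy[i]; nz[i] -= eta * gz[i];
      }
      newarea = mesh_area_grad(nx, ny, nz, t0, t1, t2, gx, gy, gz, false);
      if (newarea <= area + 1e-14) ok = true;
      else eta *= 0.5;
    }
    if (!ok) { converged = true; break; }  // gradient step cannot decrease
    vx.swap(nx); vy.swap(ny); vz.swap(nz);
    area = newarea;
    eta *= 1.05;
    hist.push_back(area);
    area = mesh_area_grad(vx, vy, vz, t0, t1, t2, gx, gy, gz, true);
    if ((int)hist.size() > window) {
      double ref = hist[hist.size() - 1 - window];
      if (std::fabs(area - ref) <= tol * ref) { converged = true; break; }
    }
  }

  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  IntegerMatrix T(t0.size(), 3);
  for (size_t m = 0; m < t0.size(); ++m) {
    T(m, 0) = t0[m] + 1; T(m, 1) = t1[m] + 1; T(m, 2) = t2[m] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T, _["area"] = area,
                      _["initial_area"] = area0, _["steps"] = step,
                      _["converged"] = converged,
                      _["area_trace"] = NumericVector(hist.begin(), hist.end()));
}

// Moeller-Trumbore segment-triangle intersection, inclusive boundaries.
static bool seg_tri(const double *p, const double *q, const double *a,
                    const double *b, const double *c, double eps,
                    double *point) {
  double d[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double h[3];
  cross3(d, e2, h);
  double det = e1[0] * h[0] + e1[1] * h[1] + e1[2] * h[2];
  if (std::fabs(det) < 1e-14) return false;  // parallel or degenerate
  double inv = 1.0 / det;
  double s[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double u = (s[0] * h[0] + s[1] * h[1] + s[2] * h[2]) * inv;
  if (u < -eps || u > 1.0 + eps) return false;
  double qv[3];
  cross3(s, e1, qv);
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -eps || u + v > 1.0 + eps) return false;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  if (t < -eps || t > 1.0 + eps) return false;
  if (point) {
    point[0] = p[0] + t * d[0]; point[1] = p[1] + t * d[1];
    point[2] = p[2] + t * d[2];
  }
  return true;
}

// [[Rcpp::export]]
List rs_segment_triangle(NumericVector p, NumericVector q, NumericVector a,
                         NumericVector b, NumericVector c) {
  // degenerate triangle check
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3];
  cross3(e1, e2, w);
  double area2 = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (area2 < 1e-12)
    return List::create(_["hit"] = false, _["point"] = R_NilValue,
                        _["degenerate"] = true);
  double pt[3];
  bool hit = seg_tri(&p[0], &q[0], &a[0], &b[0], &c[0], 1e-10, pt);
  SEXP point = R_NilValue;
  if (hit) point = NumericVector::create(pt[0], pt[1], pt[2]);
  return List::create(_["hit"] = hit, _["point"] = point,
                      _["degenerate"] = false);
}

// For each segment (rows of s0 -> s1), does it cross any triangle of the
// mesh? One crossing counted per segment (bond-level deduplication).
// [[Rcpp::export]]
IntegerVector rs_segments_cross_mesh(NumericMatrix s0, NumericMatrix s1,
                                     NumericMatrix verts, IntegerMatrix tris) {
  const int ns = s0.nrow(), nt = tris.nrow();
  IntegerVector out(ns);
  for (int i = 0; i < ns; ++i) {
    double p[3] = {s0(i, 0), s0(i, 1), s0(i, 2)};
    double q[3] = {s1(i, 0), s1(i, 1), s1(i, 2)};
    int hit = 0;
    for (int m = 0; m < nt && !hit; ++m) {
      int ia = tris(m, 0) - 1, ib = tris(m, 1) - 1, ic = tris(m, 2) - 1;
      double a[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
      double b[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
      double c[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
      if (seg_tri(p, q, a, b, c, 1e-10, nullptr)) hit = 1;
    }
    out[i] = hit;
  }
  return out;
}

// Histogram of minimum-image pair distances. If `same` is true, posA and
// posB are the same set and each unordered pair is counted once.
// [[Rcpp::export]]
NumericVector rs_pair_histogram(NumericMatrix posA, NumericMatrix posB,
                                bool same, double L, double rmax, int nbins) {
  NumericVector h(nbins);
  const int na = posA.nrow(), nb = posB.nrow();
  const double w = rmax / nbins;
  for (int i = 0; i < na; ++i) {
    int j0 = same ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      double dx = posA(i, 0) - posB(j, 0); dx -= L * std::round(dx / L);
      double dy = posA(i, 1) - posB(j, 1); dy -= L * std::round(dy / L);
      double dz = posA(i, 2) - posB(j, 2); dz -= L * std::round(dz / L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rmax) {
        int b = (int)(r / w);
        if (b >= 0 && b < nbins) h[b] += 1.0;
      }
    }
  }
  return h;
}

// Minimum-image distance from each row of posA to its nearest row of posB.
// [[Rcpp::export]]
NumericVector rs_min_dists(NumericMatrix posA, NumericMatrix posB, double L) {
  const int na = posA.nrow(), nb = posB.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = posA(i, 0) - posB(j, 0); dx -= L * std::round(dx / L);
      double dy = posA(i, 1) - posB(j, 1); dy -= L * std::round(dy / L);
      double dz = posA(i, 2) - posB(j, 2); dz -= L * std::round(dz / L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
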