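#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 3-D convex hull volume by supporting-plane enumeration.
//
// For every triple of points we test whether its plane supports the point
// cloud (all points on one side within tolerance).  Supporting planes are
// deduplicated, the points lying on each plane are projected into 2-D and
// their polygon area is taken from a monotone-chain hull, and the volume is
// assembled from signed pyramid volumes anchored at the centroid.  O(n^4)
// worst case, which is fine at assemblage sizes (tens to a few hundred
// species per cell); coplanar faces (e.g. box-shaped clouds) are exact.

struct Plane {
  double nx, ny, nz, d; // unit outward normal, offset: n.x = d on plane
};

static void cross3(double ax, double ay, double az,
                   double bx, double by, double bz,
                   double &cx, double &cy, double &cz) {
  cx = ay * bz - az * by;
  cy = az * bx - ax * bz;
  cz = ax * by - ay * bx;
}

// 2-D convex hull (monotone chain) -> polygon area
static double hull2d_area(std::vector<std::pair<double,double> > &pts) {
  size_t n = pts.size();
  if (n < 3) return 0.0;
  std::sort(pts.begin(), pts.end());
  std::vector<std::pair<double,double> > h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2) {
      double crossv = (h[k-1].first - h[k-2].first) * (pts[i].second - h[k-2].second)
                    - (h[k-1].second - h[k-2].second) * (pts[i].first - h[k-2].first);
      if (crossv <= 0) --k; else break;
    }
    h[k++] = pts[i];
  }
  size_t lower = k + 1;
  for (size_t i = n - 1; i-- > 0; ) {
    while (k >= lower) {
      double crossv = (h[k-1].first - h[k-2].first) * (pts[i].second - h[k-2].second)
                    - (h[k-1].second - h[k-2].second) * (pts[i].first - h[k-2].first);
      if (crossv <= 0) --k; else break;
    }
    h[k++] = pts[i];
  }
  // h[0..k-2] is the hull polygon (closed); shoelace
  double area = 0.0;
  for (size_t i = 0; i + 1 < k; ++i) {
    size_t j = (i + 1 == k - 1) ? 0 : i + 1;
    area += h[i].first * h[j].second - h[j].first * h[i].second;
  }
  return 0.5 * std::fabs(area);
}

// [[Rcpp::export(name = ".hull_volume3d")]]
double hull_volume3d(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must have 3 columns");
  if (n < 4) return NA_REAL;

  std::vector<double> x(n), y(n), z(n);
  double cx = 0, cy = 0, cz = 0, scale = 0;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1); z[i] = pts(i, 2);
    cx += x[i]; cy += y[i]; cz += z[i];
  }
  cx /= n; cy /= n; cz /= n;
  for (int i = 0; i < n; ++i) {
    scale = std::max(scale, std::fabs(x[i] - cx));
    scale = std::max(scale, std::fabs(y[i] - cy));
    scale = std::max(scale, std::fabs(z[i] - cz));
  }
  if (scale <= 0) return NA_REAL; // all points identical
  const double eps = 1e-9 * scale;

  std::vector<Plane> planes;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      for (int k = j + 1; k < n; ++k) {
        double ux = x[j]-x[i], uy = y[j]-y[i], uz = z[j]-z[i];
        double vx = x[k]-x[i], vy = y[k]-y[i], vz = z[k]-z[i];
        double nxv, nyv, nzv;
        cross3(ux, uy, uz, vx, vy, vz, nxv, nyv, nzv);
        double nrm = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
        if (nrm <= eps * scale) continue; // degenerate triple
        nxv /= nrm; nyv /= nrm; nzv /= nrm;
        double d = nxv*x[i] + nyv*y[i] + nzv*z[i];
        // classify all points
        bool above = false, below = false;
        for (int m = 0; m < n; ++m) {
          double s = nxv*x[m] + nyv*y[m] + nzv*z[m] - d;
          if (s > eps) above = true;
          else if (s < -eps) below = true;
          if (above && below) break;
        }
        if (above && below) continue;
        Plane p;
        if (above) { p.nx = -nxv; p.ny = -nyv; p.nz = -nzv; p.d = -d; }
        else       { p.nx =  nxv; p.ny =  nyv; p.nz =  nzv; p.d =  d; }
        // dedupe (outward normals unique per face)
        bool dup = false;
        for (size_t q = 0; q < planes.size(); ++q) {
          if (std::fabs(planes[q].nx - p.nx) < 1e-7 &&
              std::fabs(planes[q].ny - p.ny) < 1e-7 &&
              std::fabs(planes[q].nz - p.nz) < 1e-7 &&
              std::fabs(planes[q].d  - p.d)  < 1e-7 * scale) { dup = true; break; }
        }
        if (!dup) planes.push_back(p);
      }
    }
  }
  if (planes.size() < 4) return NA_REAL; // flat or lower-dimensional cloud

  double vol = 0.0;
  for (size_t q = 0; q < planes.size(); ++q) {
    const Plane &p = planes[q];
    // orthonormal in-plane basis
    double ax, ay, az;
    if (std::fabs(p.nx) < 0.9) { ax = 1; ay = 0; az = 0; } else { ax = 0; ay = 1; az = 0; }
    double e1x, e1y, e1z, e2x, e2y, e2z;
    cross3(p.nx, p.ny, p.nz, ax, ay, az, e1x, e1y, e1z);
    double nrm = std::sqrt(e1x*e1x + e1y*e1y + e1z*e1z);
    e1x /= nrm; e1y /= nrm; e1z /= nrm;
    cross3(p.nx, p.ny, p.nz, e1x, e1y, e1z, e2x, e2y, e2z);
    std::vector<std::pair<double,double> > face;
    for (int m = 0; m < n; ++m) {
      double s = p.nx*x[m] + p.ny*y[m] + p.nz*z[m] - p.d;
      if (std::fabs(s) <= 2 * eps)
        face.push_back(std::make_pair(e1x*x[m] + e1y*y[m] + e1z*z[m],
                                      e2x*x[m] + e2y*y[m] + e2z*z[m]));
    }
    double area = hull2d_area(face);
    double h = p.d - (p.nx*cx + p.ny*cy + p.nz*cz); // centroid is interior: h > 0
    vol += area * h / 3.0;
  }
  if (vol < 1e-12 * scale * scale * scale) return NA_REAL;
  return vol;
}
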