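// Exact disc-polygon intersection areas (convex polygon, counterclockwise),
// vectorized over disc centers and radii for the density-profile edge
// correction. Same edge decomposition as the reference R implementation:
// each polygon edge contributes signed triangle parts (where it runs inside
// the disc) and circular-sector parts (where it runs outside).

#include <Rcpp.h>
using namespace Rcpp;

static double edge_disc_area(double ax, double ay, double bx, double by,
                             double r) {
  double dx = bx - ax, dy = by - ay;
  double a = dx * dx + dy * dy;
  if (a < 1e-300) return 0.0;
  double b = 2.0 * (ax * dx + ay * dy);
  double cc = ax * ax + ay * ay - r * r;
  double disc = b * b - 4.0 * a * cc;
  double ts[4] = {0.0, 1.0, 1.0, 1.0};
  int nt = 2;
  if (disc > 0) {
    double sq = std::sqrt(disc);
    double t1 = (-b - sq) / (2.0 * a), t2 = (-b + sq) / (2.0 * a);
    t1 = std::min(std::max(t1, 0.0), 1.0);
    t2 = std::min(std::max(t2, 0.0), 1.0);
    ts[0] = 0.0; ts[1] = t1; ts[2] = t2; ts[3] = 1.0;
    nt = 4;
  }
  double total = 0.0;
  for (int s = 0; s < nt - 1; ++s) {
    double t0 = ts[s], t1 = ts[s + 1];
    if (t1 - t0 < 1e-15) continue;
    double tm = 0.5 * (t0 + t1);
    double mx = ax + tm * dx, my = ay + tm * dy;
    double px0 = ax + t0 * dx, py0 = ay + t0 * dy;
    double px1 = ax + t1 * dx, py1 = ay + t1 * dy;
    if (mx * mx + my * my <= r * r) {
      total += (px0 * py1 - px1 * py0) / 2.0;
    } else {
      double th = std::atan2(py1, px1) - std::atan2(py0, px0);
      if (th > M_PI) th -= 2.0 * M_PI;
      if (th < -M_PI) th += 2.0 * M_PI;
      total += 0.5 * r * r * th;
    }
  }
  return total;
}

//' @noRd
// [[Rcpp::export(name = ".disc_poly_areas_cpp")]]
NumericMatrix disc_poly_areas_cpp(const NumericMatrix& centers,
                                  const NumericVector& radii,
                                  const NumericMatrix& poly) {
  int nc = centers.nrow(), nr = radii.size(), ne = poly.nrow();
  NumericMatrix out(nc, nr);
  for (int i = 0; i < nc; ++i) {
    double cx = centers(i, 0), cy = centers(i, 1);
    for (int j = 0; j < nr; ++j) {
      double r = radii[j];
      if (r <= 0) { out(i, j) = 0.0; continue; }
      double total = 0.0;
      for (int e = 0; e < ne; ++e) {
        int f = (e + 1 == ne) ? 0 : e + 1;
        total += edge_disc_area(poly(e, 0) - cx, poly(e, 1) - cy,
                                poly(f, 0) - cx, poly(f, 1) - cy, r);
      }
      out(i, j) = std::max(total, 0.0);
    }
  }
  return out;
}
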