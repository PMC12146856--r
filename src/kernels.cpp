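#include <Rcpp.h>
using namespace Rcpp;

// Planar geometry kernels shared by the distance, buffer and density
// operations.  All coordinates are in km in one projected plane.

static inline double seg_dist(double px, double py,
                              double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / L2;
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  }
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

static inline bool point_in_ring(double px, double py,
                                 const NumericVector &vx,
                                 const NumericVector &vy) {
  int n = vx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_to_segments(NumericVector px, NumericVector py,
                                       NumericVector x0, NumericVector y0,
                                       NumericVector x1, NumericVector y1) {
  int n = px.size(), m = x0.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int k = 0; k < m; k++) {
      double d = seg_dist(px[i], py[i], x0[k], y0[k], x1[k], y1[k]);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = point_in_ring(px[i], py[i], vx, vy);
  return out;
}

// Total road length clipped to a disc of radius r around each centre.
// [[Rcpp::export]]
NumericVector cpp_length_in_discs(NumericVector cx, NumericVector cy, double r,
                                  NumericVector x0, NumericVector y0,
                                  NumericVector x1, NumericVector y1) {
  int n = cx.size(), m = x0.size();
  double r2 = r * r;
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double tot = 0.0;
    for (int k = 0; k < m; k++) {
      double dx = x1[k] - x0[k], dy = y1[k] - y0[k];
      double A = dx * dx + dy * dy;
      if (A == 0.0) continue;
      double fx = x0[k] - cx[i], fy = y0[k] - cy[i];
      double B = 2.0 * (fx * dx + fy * dy);
      double C = fx * fx + fy * fy - r2;
      double disc = B * B - 4.0 * A * C;
      if (disc <= 0.0) continue;
      double s = std::sqrt(disc);
      double t1 = (-B - s) / (2.0 * A), t2 = (-B + s) / (2.0 * A);
      double lo = t1 > 0.0 ? t1 : 0.0;
      double hi = t2 < 1.0 ? t2 : 1.0;
      if (hi > lo) tot += (hi - lo) * std::sqrt(A);
    }
    out[i] = tot;
  }
  return out;
}

// Grid census used for buffer areas and area fractions: counts the grid cells
// (cell centres given by the outer product xs x ys) falling inside the ring
// (when supplied) and, of those, the ones within distance d of any segment.
// Returns c(n_in_ring, n_in_both).  Segment bounding boxes give an early
// reject; a hit gives an early accept.
// [[Rcpp::export]]
NumericVector cpp_grid_buffer_count(NumericVector xs, NumericVector ys,
                                    NumericVector x0, NumericVector y0,
                                    NumericVector x1, NumericVector y1,
                                    double d,
                                    NumericVector vx, NumericVector vy) {
  int nx = xs.size(), ny = ys.size(), m = x0.size();
  bool use_ring = vx.size() >= 3;
  std::vector<double> bxmin(m), bxmax(m), bymin(m), bymax(m);
  for (int k = 0; k < m; k++) {
    bxmin[k] = std::min(x0[k], x1[k]) - d;
    bxmax[k] = std::max(x0[k], x1[k]) + d;
    bymin[k] = std::min(y0[k], y1[k]) - d;
    bymax[k] = std::max(y0[k], y1[k]) + d;
  }
  double n_ring = 0.0, n_both = 0.0;
  for (int i = 0; i < nx; i++) {
    double px = xs[i];
    for (int j = 0; j < ny; j++) {
      double py = ys[j];
      if (use_ring && !point_in_ring(px, py, vx, vy)) continue;
      n_ring += 1.0;
      for (int k = 0; k < m; k++) {
        if (px < bxmin[k] || px > bxmax[k] || py < bymin[k] || py > bymax[k])
          continue;
        if (seg_dist(px, py, x0[k], y0[k], x1[k], y1[k]) <= d) {
          n_both += 1.0;
          break;
        }
      }
    }
  }
  return NumericVector::create(n_ring, n_both);
}

// Area of disc(centre, r) clipped to a polygon ring.  Discs wholly inside the
// ring short-circuit to pi r^2; boundary-crossing discs are integrated by
// vertical strips (exact interval arithmetic in y, midpoint rule in x).
// [[Rcpp::export]]
NumericVector cpp_disc_region_area(NumericVector cx, NumericVector cy, double r,
                                   NumericVector vx, NumericVector vy,
                                   int ncols) {
  int n = cx.size(), ne = vx.size();
  NumericVector out(n);
  const double PI = 3.14159265358979323846;
  for (int i = 0; i < n; i++) {
    bool centre_in = point_in_ring(cx[i], cy[i], vx, vy);
    double dmin = R_PosInf;
    for (int e = 0, f = ne - 1; e < ne; f = e++) {
      double d = seg_dist(cx[i], cy[i], vx[f], vy[f], vx[e], vy[e]);
      if (d < dmin) dmin = d;
    }
    if (centre_in && dmin >= r) { out[i] = PI * r * r; continue; }
    if (!centre_in && dmin >= r) { out[i] = 0.0; continue; }
    double h = 2.0 * r / ncols, area = 0.0;
    std::vector<double> cross;
    for (int c = 0; c < ncols; c++) {
      double x = cx[i] - r + (c + 0.5) * h;
      double dx = x - cx[i];
      double s = r * r - dx * dx;
      if (s <= 0.0) continue;
      s = std::sqrt(s);
      double ylo = cy[i] - s, yhi = cy[i] + s;
      // polygon crossings of the vertical line at x
      cross.clear();
      for (int e = 0, f = ne - 1; e < ne; f = e++) {
        double xa = vx[f], xb = vx[e];
        if ((xa > x) == (xb > x)) continue;
        double t = (x - xa) / (xb - xa);
        cross.push_back(vy[f] + t * (vy[e] - vy[f]));
      }
      std::sort(cross.begin(), cross.end());
      for (size_t p = 0; p + 1 < cross.size(); p += 2) {
        double lo = std::max(ylo, cross[p]);
        double hi = std::min(yhi, cross[p + 1]);
        if (hi > lo) area += (hi - lo) * h;
      }
    }
    out[i] = area;
  }
  return out;
}
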