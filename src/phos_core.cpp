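#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 8-connected labeling of a binary mask by iterative flood fill.
// Labels are assigned in raster-scan order of each region's first pixel,
// which makes the labeling deterministic.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int dc = -1; dc <= 1; ++dc) {
            for (int dr = -1; dr <= 1; ++dr) {
              if (dr == 0 && dc == 0) continue;
              int r2 = rr + dr, c2 = cc + dc;
              if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
              if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
                lab(r2, c2) = next;
                stack.push_back(r2 + c2 * nr);
              }
            }
          }
        }
      }
    }
  }
  return lab;
}

// Axon-map intensity kernel: for each query point, the maximum over bundle
// sample points k of w[k] * exp(-d(p, a_k)^2 * inv2rho2), where w[k] is the
// precomputed axonal decay weight of sample k.
// [[Rcpp::export(name = ".cpp_axon_intensity")]]
NumericVector cpp_axon_intensity(const NumericVector& px,
                                 const NumericVector& py,
                                 const NumericVector& vx,
                                 const NumericVector& vy,
                                 const NumericVector& w,
                                 const double inv2rho2) {
  const int n = px.size();
  const int K = vx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = 0.0;
    for (int k = 0; k < K; ++k) {
      double dx = px[i] - vx[k], dy = py[i] - vy[k];
      double v = w[k] * std::exp(-(dx * dx + dy * dy) * inv2rho2);
      if (v > best) best = v;
    }
    out[i] = best;
  }
  return out;
}

// Minimum distance from each query point to a polyline, plus the arc-length
// position (along the polyline) of the foot point achieving the minimum.
// Vertices are (vx[k], vy[k]), k = 0..K-1, in order.
// [[Rcpp::export(name = ".cpp_polyline_dist")]]
List cpp_polyline_dist(const NumericVector& px, const NumericVector& py,
                       const NumericVector& vx, const NumericVector& vy) {
  const int n = px.size();
  const int K = vx.size();
  if (K < 1) stop("polyline must have at least one vertex");
  NumericVector dmin(n), sfoot(n);
  // cumulative arc length at each vertex
  std::vector<double> s(K, 0.0);
  for (int k = 1; k < K; ++k) {
    double dx = vx[k] - vx[k - 1], dy = vy[k] - vy[k - 1];
    s[k] = s[k - 1] + std::sqrt(dx * dx + dy * dy);
  }
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf, bests = 0.0;
    if (K == 1) {
      double dx = px[i] - vx[0], dy = py[i] - vy[0];
      best = std::sqrt(dx * dx + dy * dy);
      bests = 0.0;
    }
    for (int k = 0; k + 1 < K; ++k) {
      double ax = vx[k], ay = vy[k];
      double bx = vx[k + 1], by = vy[k + 1];
      double abx = bx - ax, aby = by - ay;
      double len2 = abx * abx + aby * aby;
      double t = 0.0;
      if (len2 > 0.0) {
        t = ((px[i] - ax) * abx + (py[i] - ay) * aby) / len2;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
      }
      double fx = ax + t * abx, fy = ay + t * aby;
      double dx = px[i] - fx, dy = py[i] - fy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best) {
        best = d;
        bests = s[k] + t * std::sqrt(len2);
      }
    }
    dmin[i] = best;
    sfoot[i] = bests;
  }
  return List::create(_["dmin"] = dmin, _["sfoot"] = sfoot);
}
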