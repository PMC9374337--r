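#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation of planar points.
// Circumcentres are cached per triangle so the in-circle test is one
// squared-distance comparison.

struct Tri {
  int a, b, c;
  double ccx, ccy, r2;
  bool dead;
};

static bool circumcircle(const std::vector<double> &X,
                         const std::vector<double> &Y,
                         int a, int b, int c,
                         double &ccx, double &ccy, double &r2) {
  double ax = X[a], ay = Y[a], bx = X[b], by = Y[b], cx = X[c], cy = Y[c];
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ccx = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  ccy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  double dx = ax - ccx, dy = ay - ccy;
  r2 = dx * dx + dy * dy;
  return true;
}

// Returns an m x 3 matrix of 1-based point indices, one row per Delaunay
// triangle. Input must be free of exact duplicates (handled by the R wrapper).
// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points for a triangulation");
  std::vector<double> X(x.begin(), x.end()), Y(y.begin(), y.end());
  double xmin = *std::min_element(X.begin(), X.end());
  double xmax = *std::max_element(X.begin(), X.end());
  double ymin = *std::min_element(Y.begin(), Y.end());
  double ymax = *std::max_element(Y.begin(), Y.end());
  double dmax = std::max(xmax - xmin, ymax - ymin);
  if (dmax <= 0) stop("degenerate input: all points coincide on an axis");
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);
  // super-triangle vertices get indices n, n+1, n+2
  X.push_back(midx - 30.0 * dmax); Y.push_back(midy - 10.0 * dmax);
  X.push_back(midx + 30.0 * dmax); Y.push_back(midy - 10.0 * dmax);
  X.push_back(midx);               Y.push_back(midy + 30.0 * dmax);

  std::vector<Tri> tris;
  {
    Tri t0; t0.a = n; t0.b = n + 1; t0.c = n + 2; t0.dead = false;
    if (!circumcircle(X, Y, t0.a, t0.b, t0.c, t0.ccx, t0.ccy, t0.r2))
      stop("internal error: degenerate super-triangle");
    tris.push_back(t0);
  }

  std::vector<int> bad;
  size_t n_dead = 0;
  for (int p = 0; p < n; ++p) {
    const double pxx = X[p], pyy = Y[p];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (tris[t].dead) continue;
      double dx = pxx - tris[t].ccx, dy = pyy - tris[t].ccy;
      if (dx * dx + dy * dy <= tris[t].r2) bad.push_back((int)t);
    }
    std::map<std::pair<int, int>, int> ecount;
    for (int bi : bad) {
      int v[3] = {tris[bi].a, tris[bi].b, tris[bi].c};
      for (int e = 0; e < 3; ++e) {
        int u = v[e], w = v[(e + 1) % 3];
        std::pair<int, int> key(std::min(u, w), std::max(u, w));
        ++ecount[key];
      }
      tris[bi].dead = true;
      ++n_dead;
    }
    for (std::map<std::pair<int, int>, int>::const_iterator it = ecount.begin();
         it != ecount.end(); ++it) {
      if (it->second != 1) continue;  // interior edge of the cavity
      Tri nt; nt.a = it->first.first; nt.b = it->first.second; nt.c = p;
      nt.dead = false;
      if (!circumcircle(X, Y, nt.a, nt.b, nt.c, nt.ccx, nt.ccy, nt.r2))
        continue;  // collinear sliver; skip
      tris.push_back(nt);
    }
    if (n_dead > tris.size() / 2 && tris.size() > 1024) {
      std::vector<Tri> keep;
      keep.reserve(tris.size() - n_dead);
      for (size_t t = 0; t < tris.size(); ++t)
        if (!tris[t].dead) keep.push_back(tris[t]);
      tris.swap(keep);
      n_dead = 0;
    }
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> ta, tb, tc;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri &tr = tris[t];
    if (tr.dead || tr.a >= n || tr.b >= n || tr.c >= n) continue;
    ta.push_back(tr.a + 1); tb.push_back(tr.b + 1); tc.push_back(tr.c + 1);
  }
  if (ta.empty())
    stop("degenerate (collinear) input: no valid triangulation");
  IntegerMatrix M(ta.size(), 3);
  for (size_t i = 0; i < ta.size(); ++i) {
    M(i, 0) = ta[i]; M(i, 1) = tb[i]; M(i, 2) = tc[i];
  }
  return M;
}
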