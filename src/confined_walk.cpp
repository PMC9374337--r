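#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squared distance from (x, y, z) to the axis segment {(t, 0, 0): |t| <= h};
// cx receives the clamped axial coordinate (nearest point on the segment).
static inline double axis_dist2(double x, double y, double z, double h,
                                double &cx) {
  cx = x;
  if (cx > h) cx = h; else if (cx < -h) cx = -h;
  double dx = x - cx;
  return dx * dx + y * y + z * z;
}

// Brownian steps inside a reflective spherocylinder (axis along x, centred at
// the origin). A proposed position outside the compartment is specularly
// reflected across the tangent plane at the nearest surface point, iterating
// until interior. pole_d_factor rescales the step size for particles whose
// current position lies in a hemispherical cap (|x| > half_cyl); 1 = uniform.
// Returns an n_steps x (3 * n_particles) matrix of positions AFTER each step
// (no t = 0 row). Uses R's RNG, so results are seed-reproducible.
// [[Rcpp::export]]
NumericMatrix confined_walk_cpp(NumericMatrix init, int n_steps,
                                double step_sd, double radius, double half_cyl,
                                double pole_d_factor) {
  const int np = init.nrow();
  const double r2 = radius * radius;
  NumericMatrix out(n_steps, 3 * np);
  std::vector<double> px(np), py(np), pz(np);
  for (int i = 0; i < np; ++i) {
    px[i] = init(i, 0); py[i] = init(i, 1); pz[i] = init(i, 2);
  }
  const double pole_sd = step_sd * std::sqrt(pole_d_factor);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < np; ++i) {
      const double sd = (std::fabs(px[i]) > half_cyl) ? pole_sd : step_sd;
      double nx = px[i] + R::rnorm(0.0, sd);
      double ny = py[i] + R::rnorm(0.0, sd);
      double nz = pz[i] + R::rnorm(0.0, sd);
      double cx;
      int iter = 0;
      while (axis_dist2(nx, ny, nz, half_cyl, cx) > r2 && iter < 200) {
        double dx = nx - cx, dy = ny, dz = nz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double ux = dx / d, uy = dy / d, uz = dz / d;
        // nearest surface point and outward normal
        double sx = cx + radius * ux, sy = radius * uy, sz = radius * uz;
        double dot = (nx - sx) * ux + (ny - sy) * uy + (nz - sz) * uz;
        nx -= 2.0 * dot * ux;
        ny -= 2.0 * dot * uy;
        nz -= 2.0 * dot * uz;
        ++iter;
      }
      if (iter >= 200) {
        // pathological step (step_sd >> compartment): project just inside
        double dx = nx - cx, dy = ny, dz = nz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        double f = (radius * 0.999999) / d;
        nx = cx + dx * f; ny = dy * f; nz = dz * f;
      }
      px[i] = nx; py[i] = ny; pz[i] = nz;
      out(s, 3 * i) = nx; out(s, 3 * i + 1) = ny; out(s, 3 * i + 2) = nz;
    }
  }
  return out;
}
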