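#include <Rcpp.h>
using namespace Rcpp;

// Boundary codes: 0 = periodic, 1 = no-flux, 2 = wound strip
// (Dirichlet a = a_w on the x = Lx edge, no-flux on the other edges).
// Field matrix a is nx x ny; a(ix, iy) sits at ((ix+0.5)dx, (iy+0.5)dx).

static inline int wrapi(int i, int n) { return (i % n + n) % n; }
static inline int refli(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

static inline double node(const NumericMatrix& a, int ix, int iy, int boundary) {
  const int nx = a.nrow(), ny = a.ncol();
  if (boundary == 0) return a(wrapi(ix, nx), wrapi(iy, ny));
  return a(refli(ix, nx), refli(iy, ny));
}

// One explicit Euler step of da/dt = p - h a - b sum_i delta(r_i) + d_a Lap(a).
// Each cell depletes the field by b (concentration per minute) deposited
// entirely in the grid cell containing it; the field is clamped at zero so
// the fixed per-cell uptake cannot drive concentrations negative.
// [[Rcpp::export(name = ".cpp_atp_step")]]
void cpp_atp_step(NumericMatrix a, double dx, NumericMatrix pos,
                  double p_atp, double h, double b, double d_a,
                  double dt, int boundary, double a_w) {
  const int nx = a.nrow(), ny = a.ncol();
  const double inv_dx2 = 1.0 / (dx * dx);
  NumericMatrix lap(nx, ny);
  const double* A = a.begin();
  double* L = lap.begin();
  for (int iy = 1; iy < ny - 1; ++iy) {       // interior: no boundary lookups
    const int off = iy * nx;
    for (int ix = 1; ix < nx - 1; ++ix) {
      const int q = off + ix;
      L[q] = (A[q - 1] + A[q + 1] + A[q - nx] + A[q + nx] - 4.0 * A[q]) * inv_dx2;
    }
  }
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      if (ix > 0 && ix < nx - 1 && iy > 0 && iy < ny - 1) continue;
      lap(ix, iy) = (node(a, ix + 1, iy, boundary) + node(a, ix - 1, iy, boundary) +
                     node(a, ix, iy + 1, boundary) + node(a, ix, iy - 1, boundary) -
                     4.0 * a(ix, iy)) * inv_dx2;
    }
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      a(ix, iy) += dt * (p_atp - h * a(ix, iy) + d_a * lap(ix, iy));
  const int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pos(i, 0) / dx);
    int iy = (int)std::floor(pos(i, 1) / dx);
    if (boundary == 0) { ix = wrapi(ix, nx); iy = wrapi(iy, ny); }
    else { ix = refli(ix, nx); iy = refli(iy, ny); }
    a(ix, iy) -= b * dt;
  }
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      if (a(ix, iy) < 0.0) a(ix, iy) = 0.0;
  if (boundary == 2)
    for (int iy = 0; iy < ny; ++iy) a(nx - 1, iy) = a_w;
}

// Central-difference gradient at the four surrounding nodes, bilinearly
// interpolated to each query position. Returns n x 2 (da/dx, da/dy).
// [[Rcpp::export(name = ".cpp_gradient_at")]]
NumericMatrix cpp_gradient_at(const NumericMatrix& a, double dx,
                              const NumericMatrix& pts, int boundary) {
  const int nx = a.nrow(), ny = a.ncol(), n = pts.nrow();
  NumericMatrix g(n, 2);
  for (int i = 0; i < n; ++i) {
    double u = pts(i, 0) / dx - 0.5, w = pts(i, 1) / dx - 0.5;
    int i0 = (int)std::floor(u), j0 = (int)std::floor(w);
    double fu = u - i0, fw = w - j0;
    double gx = 0.0, gy = 0.0;
    for (int du = 0; du <= 1; ++du)
      for (int dw = 0; dw <= 1; ++dw) {
        double wt = (du ? fu : 1.0 - fu) * (dw ? fw : 1.0 - fw);
        int ix = i0 + du, iy = j0 + dw;
        double gxx = (node(a, ix + 1, iy, boundary) - node(a, ix - 1, iy, boundary)) / (2.0 * dx);
        double gyy = (node(a, ix, iy + 1, boundary) - node(a, ix, iy - 1, boundary)) / (2.0 * dx);
        gx += wt * gxx; gy += wt * gyy;
      }
    g(i, 0) = gx; g(i, 1) = gy;
  }
  return g;
}

// One forward-Euler step of dr_i/dt = c grad a + sum_j f(|r_j - r_i|) u_ij + v e_i,
// with run-and-tumble headings: resampled uniformly on the circle at Poisson
// rate 2/tau so that the long-time diffusivity is v^2 tau (the estimator
// convention d_u = MSD/time, tau = d_u/v^2).
// [[Rcpp::export(name = ".cpp_cell_step")]]
void cpp_cell_step(NumericMatrix pos, NumericMatrix headings, NumericVector next_tumble,
                   double t_now, const NumericMatrix& a, double dx,
                   double c, double v, double tau, double sigma, double k,
                   double dt, int boundary, double Lx, double Ly) {
  const int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    if (next_tumble[i] <= t_now) {
      double th = unif_rand() * 2.0 * M_PI;
      headings(i, 0) = std::cos(th);
      headings(i, 1) = std::sin(th);
      next_tumble[i] = t_now + exp_rand() * tau / 2.0;  // mean run = tau/2
    }
  }
  NumericMatrix grad = cpp_gradient_at(a, dx, pos, boundary);
  NumericMatrix newpos(n, 2);
  for (int i = 0; i < n; ++i) {
    double fx = 0.0, fy = 0.0;
    if (k > 0.0) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double ddx = pos(i, 0) - pos(j, 0), ddy = pos(i, 1) - pos(j, 1);
        if (boundary == 0) {  // minimum image
          if (ddx > Lx / 2) ddx -= Lx; else if (ddx < -Lx / 2) ddx += Lx;
          if (ddy > Ly / 2) ddy -= Ly; else if (ddy < -Ly / 2) ddy += Ly;
        }
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        if (d < sigma && d > 0.0) {
          double mag = k * (sigma - d);
          fx += mag * ddx / d; fy += mag * ddy / d;
        }
      }
    }
    double ux = c * grad(i, 0) + fx + v * headings(i, 0);
    double uy = c * grad(i, 1) + fy + v * headings(i, 1);
    double x = pos(i, 0) + dt * ux, y = pos(i, 1) + dt * uy;
    if (!R_finite(x) || !R_finite(y))
      stop("non-finite cell position at t = %f (cell %d)", t_now, i + 1);
    if (boundary == 0) {
      x -= Lx * std::floor(x / Lx);
      y -= Ly * std::floor(y / Ly);
    } else {  // reflect
      if (x < 0) x = -x; if (x > Lx) x = 2 * Lx - x;
      if (y < 0) y = -y; if (y > Ly) y = 2 * Ly - y;
      if (x < 0) x = 0; if (x > Lx) x = Lx;
      if (y < 0) y = 0; if (y > Ly) y = Ly;
    }
    newpos(i, 0) = x; newpos(i, 1) = y;
  }
  for (int i = 0; i < n; ++i) { pos(i, 0) = newpos(i, 0); pos(i, 1) = newpos(i, 1); }
}

// Advance the coupled system nsteps operator-split steps (field, then cells).
// Modifies a, pos, headings, next_tumble in place; returns the new time.
// [[Rcpp::export(name = ".cpp_advance")]]
double cpp_advance(NumericMatrix a, NumericMatrix pos, NumericMatrix headings,
                   NumericVector next_tumble, double t0, int nsteps, double dt,
                   double dx, double c, double v, double tau, double sigma, double k,
                   double p_atp, double h, double b, double d_a,
                   int boundary, double a_w, double Lx, double Ly) {
  double t = t0;
  for (int s = 0; s < nsteps; ++s) {
    cpp_atp_step(a, dx, pos, p_atp, h, b, d_a, dt, boundary, a_w);
    cpp_cell_step(pos, headings, next_tumble, t, a, dx, c, v, tau, sigma, k,
                  dt, boundary, Lx, Ly);
    t += dt;
  }
  return t;
}
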