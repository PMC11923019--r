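#include "hh.h"
using namespace Rcpp;

// Backward-in-time solver for the stochastic HJB equation
//   dV/dt + min_{|u|<=umax} H(z, grad V, u) + (D/K^2) V_xx = 0,
//   V(z, T_end) = gamma q(z),
// marched in reverse time s = T_end - t as V_s = H*(z, grad V) + (D/K^2) V_xx
// with per-step Lie splitting: explicit local Lax-Friedrichs WENO5 update of
// the Hamiltonian, then an implicit (tridiagonal) solve of the x-diffusion.

// Fifth-order WENO reconstruction from five consecutive one-sided
// differences (Jiang-Peng smoothness indicators).
static inline double weno5pick(double v1, double v2, double v3, double v4,
                               double v5) {
  double s1 = 13.0 / 12.0 * (v1 - 2 * v2 + v3) * (v1 - 2 * v2 + v3)
            + 0.25 * (v1 - 4 * v2 + 3 * v3) * (v1 - 4 * v2 + 3 * v3);
  double s2 = 13.0 / 12.0 * (v2 - 2 * v3 + v4) * (v2 - 2 * v3 + v4)
            + 0.25 * (v2 - v4) * (v2 - v4);
  double s3 = 13.0 / 12.0 * (v3 - 2 * v4 + v5) * (v3 - 2 * v4 + v5)
            + 0.25 * (3 * v3 - 4 * v4 + v5) * (3 * v3 - 4 * v4 + v5);
  double m = v1 * v1;
  if (v2 * v2 > m) m = v2 * v2;
  if (v3 * v3 > m) m = v3 * v3;
  if (v4 * v4 > m) m = v4 * v4;
  if (v5 * v5 > m) m = v5 * v5;
  double eps = 1e-6 * m + 1e-40;  // floor keeps the q-products away from underflow
  // division-free weights: a_k = c_k / (s_k + eps)^2 up to a common factor
  double q1 = (s1 + eps) * (s1 + eps);
  double q2 = (s2 + eps) * (s2 + eps);
  double q3 = (s3 + eps) * (s3 + eps);
  double a1 = 0.1 * q2 * q3;
  double a2 = 0.6 * q1 * q3;
  double a3 = 0.3 * q1 * q2;
  double num = a1 * (v1 * (1.0 / 3.0) - v2 * (7.0 / 6.0) + v3 * (11.0 / 6.0))
             + a2 * (-v2 * (1.0 / 6.0) + v3 * (5.0 / 6.0) + v4 * (1.0 / 3.0))
             + a3 * (v3 * (1.0 / 3.0) + v4 * (5.0 / 6.0) - v5 * (1.0 / 6.0));
  return num / (a1 + a2 + a3);
}

// One-sided WENO5 first derivatives along a line of n nodes with spacing h.
// Ghost nodes by linear extrapolation (constant one-sided differences).
// buf must have room for n + 6 values; d for n + 5 differences.
static void weno_line(const double* f, int n, double h,
                      double* dm, double* dp, double* buf, double* d) {
  for (int i = 0; i < n; ++i) buf[i + 3] = f[i];
  buf[2] = 2 * f[0] - f[1];
  buf[1] = 3 * f[0] - 2 * f[1];
  buf[0] = 4 * f[0] - 3 * f[1];
  buf[n + 3] = 2 * f[n - 1] - f[n - 2];
  buf[n + 4] = 3 * f[n - 1] - 2 * f[n - 2];
  buf[n + 5] = 4 * f[n - 1] - 3 * f[n - 2];
  double ih = 1.0 / h;
  for (int i = 0; i < n + 5; ++i) d[i] = (buf[i + 1] - buf[i]) * ih;
  for (int i = 0; i < n; ++i) {
    dm[i] = weno5pick(d[i], d[i + 1], d[i + 2], d[i + 3], d[i + 4]);
    dp[i] = weno5pick(d[i + 5], d[i + 4], d[i + 3], d[i + 2], d[i + 1]);
  }
}

// [[Rcpp::export]]
List cpp_weno5_line(NumericVector f, double h) {
  int n = f.size();
  if (n < 7) stop("WENO5 needs at least 7 nodes");
  NumericVector dm(n), dp(n);
  std::vector<double> buf(n + 6), d(n + 5);
  weno_line(f.begin(), n, h, dm.begin(), dp.begin(), buf.data(), d.data());
  return List::create(_["left"] = dm, _["right"] = dp);
}

// Hamiltonian minimized over |u| <= umax (Pontryagin saturation):
//   H = p.F - px^2/(4K^2)                          if |px| <= 2 K umax
//   H = p.F + umax^2 - |px| umax / K               otherwise
static inline double ham_opt(double fx, double fy, double px, double py,
                             double umax, double K) {
  double h = px * fx + py * fy;
  double apx = std::fabs(px);
  if (apx <= 2.0 * K * umax) return h - px * px / (4.0 * K * K);
  return h + umax * umax - apx * umax / K;
}

// [[Rcpp::export]]
double cpp_hamiltonian_optimal(double fx, double fy, double px, double py,
                               double umax, double K) {
  return ham_opt(fx, fy, px, py, umax, K);
}

// Tridiagonal solve of (I - c d^2/dx^2) x = r with homogeneous-Neumann rows
// (mirror ghost), c = dt D / (K dx)^2. In-place Thomas algorithm.
static void thomas_neumann(double* x, int n, double c,
                           double* cw, double* dw) {
  // rows: [1+2c, -2c | -c, 1+2c, -c | ... | -2c, 1+2c]
  double b0 = 1.0 + 2.0 * c;
  cw[0] = -2.0 * c / b0;
  dw[0] = x[0] / b0;
  for (int i = 1; i < n - 1; ++i) {
    double m = 1.0 + 2.0 * c + c * cw[i - 1];
    cw[i] = -c / m;
    dw[i] = (x[i] + c * dw[i - 1]) / m;
  }
  double m = 1.0 + 2.0 * c + 2.0 * c * cw[n - 2];
  dw[n - 1] = (x[n - 1] + 2.0 * c * dw[n - 2]) / m;
  x[n - 1] = dw[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dw[i] - cw[i] * x[i + 1];
}

// [[Rcpp::export]]
NumericMatrix cpp_diffusion_x(NumericMatrix slice, double nu_dt, double dx) {
  int nx = slice.nrow(), ny = slice.ncol();
  NumericMatrix out = clone(slice);
  if (nu_dt == 0.0) return out;
  double c = nu_dt / (dx * dx);
  std::vector<double> cw(nx), dw(nx);
  for (int j = 0; j < ny; ++j)
    thomas_neumann(&out(0, j), nx, c, cw.data(), dw.data());
  return out;
}

// [[Rcpp::export]]
List cpp_solve_hjb(NumericMatrix Fx, NumericMatrix Fy, NumericMatrix Vterm,
                   double dx, double dy, double umax, double K,
                   double D, double T_end, double cfl, double store_dt) {
  int nx = Fx.nrow(), ny = Fx.ncol();
  if (nx < 16 || ny < 16) stop("grid too small for the WENO5 stencil");

  // Local Lax-Friedrichs dissipation bounds: |dH/dpx| <= |f_x| + umax/K,
  // |dH/dpy| = |f_y|, maximized over the grid line through each node.
  std::vector<double> axv(nx, 0.0), ayv(ny, 0.0);
  double maxAx = 0.0, maxAy = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double ax = std::fabs(Fx(i, j)) + umax / K;
      double ay = std::fabs(Fy(i, j));
      if (ax > axv[i]) axv[i] = ax;
      if (ay > ayv[j]) ayv[j] = ay;
      if (ax > maxAx) maxAx = ax;
      if (ay > maxAy) maxAy = ay;
    }
  double dt = cfl * std::min(dx / maxAx, dy / maxAy);
  long nsteps = (long)std::ceil(T_end / dt - 1e-12);
  dt = T_end / nsteps;

  long store_every = std::max(1L, (long)std::llround(store_dt / dt));
  std::vector<long> stored;
  for (long m = 0; m <= nsteps; m += store_every) stored.push_back(m);
  if (stored.back() != nsteps) stored.push_back(nsteps);
  int nstored = (int)stored.size();

  std::size_t npix = (std::size_t)nx * ny;
  NumericVector slices((R_xlen_t)(npix * nstored));
  NumericVector times(nstored);

  std::vector<double> cur(Vterm.begin(), Vterm.end()), nxt(npix);
  std::vector<double> pxm(npix), pxp(npix), pym(npix), pyp(npix);
  int nbuf = std::max(nx, ny);
  std::vector<double> buf(nbuf + 6), dbuf(nbuf + 5), ybuf(nbuf),
      ym(nbuf), yp(nbuf), cw(nx), dw(nx);

  int ks = 0;  // next entry of `stored` to emit
  auto emit = [&](long m) {
    int pos = nstored - 1 - ks;  // ascending physical time in the output
    std::copy(cur.begin(), cur.end(), slices.begin() + (std::size_t)pos * npix);
    times[pos] = T_end - m * dt;
    ++ks;
  };
  emit(0);

  double diff_c = dt * D / (K * K * dx * dx);
  for (long m = 1; m <= nsteps; ++m) {
    // one-sided WENO5 costates in x (contiguous columns) and y (gathered)
    for (int j = 0; j < ny; ++j)
      weno_line(&cur[(std::size_t)nx * j], nx, dx,
                &pxm[(std::size_t)nx * j], &pxp[(std::size_t)nx * j],
                buf.data(), dbuf.data());
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) ybuf[j] = cur[i + (std::size_t)nx * j];
      weno_line(ybuf.data(), ny, dy, ym.data(), yp.data(),
                buf.data(), dbuf.data());
      for (int j = 0; j < ny; ++j) {
        pym[i + (std::size_t)nx * j] = ym[j];
        pyp[i + (std::size_t)nx * j] = yp[j];
      }
    }
    // reverse-time explicit update; in s = T_end - t the dissipation enters
    // with a + sign: V += dt (H(pbar) + ax/2 (px+ - px-) + ay/2 (py+ - py-))
    for (int j = 0; j < ny; ++j) {
      double ay = 0.5 * ayv[j];
      const double* fxc = &Fx(0, j);
      const double* fyc = &Fy(0, j);
      std::size_t off = (std::size_t)nx * j;
      for (int i = 0; i < nx; ++i) {
        double a = pxm[off + i], b = pxp[off + i];
        double cmy = pym[off + i], cpy = pyp[off + i];
        double H = ham_opt(fxc[i], fyc[i], 0.5 * (a + b), 0.5 * (cmy + cpy),
                           umax, K);
        nxt[off + i] = cur[off + i]
          + dt * (H + 0.5 * axv[i] * (b - a) + ay * (cpy - cmy));
      }
    }
    if (D > 0.0)
      for (int j = 0; j < ny; ++j)
        thomas_neumann(&nxt[(std::size_t)nx * j], nx, diff_c,
                       cw.data(), dw.data());
    cur.swap(nxt);
    if (m % 2000 == 0 || m == nsteps) {
      for (std::size_t q = 0; q < npix; ++q)
        if (!std::isfinite(cur[q]))
          stop("value function diverged at step %ld", m);
    }
    if (ks < nstored && stored[ks] == m) emit(m);
  }

  slices.attr("dim") = IntegerVector::create(nx, ny, nstored);
  return List::create(_["slices"] = slices, _["times"] = times,
                      _["dt_pde"] = dt, _["n_steps"] = (double)nsteps,
                      _["alpha_x_max"] = maxAx, _["alpha_y_max"] = maxAy);
}
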