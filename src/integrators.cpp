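#include "hh.h"
using namespace Rcpp;

// Honeycutt second-order stochastic Runge-Kutta (SRK2) for additive noise:
//   g  = sqrt(2 D dt) xi          (voltage component only)
//   F1 = drift(z); F2 = drift(z + dt F1 + g)
//   z' = z + (dt/2)(F1 + F2) + g
// The same Gaussian draw enters predictor and corrector. With D = 0 this is
// exactly the deterministic Heun (RK2) scheme, sharing the code path.

// Open-loop single neuron in physical (V, n) coordinates.
// u_ctrl: length 0 -> u = 0; length 1 -> constant; length nsteps -> per-step
// zero-order-hold control. Noise stream is (master_seed, stream 0), matching
// neuron 0 of the population integrator.
// [[Rcpp::export]]
List cpp_run_neuron(double V0, double n0, NumericVector par,
                    double T, double dt, double D, double master_seed,
                    NumericVector u_ctrl, int record_every) {
  HHParams p = as_hh_params(par);
  long nsteps = (long)std::llround(T / dt);
  if (nsteps < 1) stop("horizon shorter than one step");
  int nu = u_ctrl.size();
  if (nu > 1 && nu < nsteps)
    stop("control vector shorter than the number of steps");
  NormalStream rng((std::uint64_t)master_seed, 0);

  long nrec = nsteps / record_every + 1;
  NumericVector rt(nrec), rV(nrec), rn(nrec), ru(nrec), re(nrec);
  double V = V0, n = n0, energy = 0.0;
  rt[0] = 0.0; rV[0] = V; rn[0] = n; ru[0] = NA_REAL; re[0] = 0.0;
  long ir = 1;
  const double namp = std::sqrt(2.0 * D * dt);

  for (long k = 0; k < nsteps; ++k) {
    double u = (nu == 0) ? 0.0 : (nu == 1 ? u_ctrl[0] : u_ctrl[k]);
    double g = (D > 0.0) ? namp * rng.normal() : 0.0;
    double cpl = 0.0;
    double F1V = hh_fV_fast(V, n, p) + cpl + u;
    double F1n = hh_fn_fast(V, n);
    double Vp = V + dt * F1V + g;
    double np = n + dt * F1n;
    double F2V = hh_fV_fast(Vp, np, p) + cpl + u;
    double F2n = hh_fn_fast(Vp, np);
    V = V + 0.5 * dt * (F1V + F2V) + g;
    n = n + 0.5 * dt * (F1n + F2n);
    energy += u * u * dt;
    if (!std::isfinite(V) || !std::isfinite(n))
      stop("trajectory blew up at t = %f ms", (k + 1) * dt);
    if ((k + 1) % record_every == 0) {
      rt[ir] = (k + 1) * dt; rV[ir] = V; rn[ir] = n; ru[ir] = u; re[ir] = energy;
      ++ir;
    }
  }
  return List::create(_["t"] = rt, _["V"] = rV, _["n"] = rn,
                      _["u"] = ru, _["cum_energy"] = re,
                      _["energy"] = energy);
}

// Value-gradient lookup shared by the closed-loop integrators: V_x stored on
// grid nodes for each stored time slice; bilinear in space (queries clamped
// to the grid) and linear in time between adjacent slices.
struct PolicyTable {
  const double* vx;      // [i + nx*(j + ny*k)]
  const double* tg;      // ascending time grid, length nt
  int nx, ny, nt;
  double x0, dxg, y0, dyg, umax, K;

  inline double bilin(int k, double x, double y) const {
    double fx = (x - x0) / dxg, fy = (y - y0) / dyg;
    if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
    if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
    int i = (int)fx; if (i > nx - 2) i = nx - 2;
    int j = (int)fy; if (j > ny - 2) j = ny - 2;
    double ax = fx - i, ay = fy - j;
    const double* b = vx + (std::size_t)nx * ny * k;
    double f00 = b[i + nx * j],     f10 = b[i + 1 + nx * j];
    double f01 = b[i + nx * (j+1)], f11 = b[i + 1 + nx * (j+1)];
    return (1 - ax) * (1 - ay) * f00 + ax * (1 - ay) * f10
         + (1 - ax) * ay * f01 + ax * ay * f11;
  }
  inline double control(double V, double n, double t) const {
    double x = V / K, y = n;
    int k1 = 1;
    while (k1 < nt - 1 && tg[k1] < t) ++k1;   // nt is small; linear scan cached by locality
    int k0 = k1 - 1;
    double w = (t - tg[k0]) / (tg[k1] - tg[k0]);
    if (w < 0) w = 0; if (w > 1) w = 1;
    double vxv = (1 - w) * bilin(k0, x, y) + w * bilin(k1, x, y);
    double u = -vxv / (2.0 * K);
    if (u > umax) u = umax;
    if (u < -umax) u = -umax;
    return u;
  }
};

// Closed-loop single neuron under the saturated feedback law
// u = -V_x/(2K), |u| <= u_max, with zero-order hold over each SDE step.
// [[Rcpp::export]]
List cpp_run_neuron_policy(double V0, double n0, NumericVector par,
                           double dt, double D, double master_seed,
                           NumericVector vx, NumericVector tgrid,
                           double x0, double dxg, int nx,
                           double y0, double dyg, int ny,
                           double umax, int record_every) {
  HHParams p = as_hh_params(par);
  PolicyTable pol;
  pol.vx = vx.begin(); pol.tg = tgrid.begin();
  pol.nx = nx; pol.ny = ny; pol.nt = tgrid.size();
  pol.x0 = x0; pol.dxg = dxg; pol.y0 = y0; pol.dyg = dyg;
  pol.umax = umax; pol.K = p.K;
  double T_end = tgrid[pol.nt - 1];
  long nsteps = (long)std::llround(T_end / dt);
  NormalStream rng((std::uint64_t)master_seed, 0);

  long nrec = nsteps / record_every + 1;
  NumericVector rt(nrec), rV(nrec), rn(nrec), ru(nrec), re(nrec);
  double V = V0, n = n0, energy = 0.0;
  rt[0] = 0.0; rV[0] = V; rn[0] = n; ru[0] = NA_REAL; re[0] = 0.0;
  long ir = 1;
  const double namp = std::sqrt(2.0 * D * dt);

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double u = pol.control(V, n, t);   // queried at the pre-step state
    double g = (D > 0.0) ? namp * rng.normal() : 0.0;
    double F1V = hh_fV_fast(V, n, p) + u;
    double F1n = hh_fn_fast(V, n);
    double Vp = V + dt * F1V + g;
    double np = n + dt * F1n;
    double F2V = hh_fV_fast(Vp, np, p) + u;
    double F2n = hh_fn_fast(Vp, np);
    V = V + 0.5 * dt * (F1V + F2V) + g;
    n = n + 0.5 * dt * (F1n + F2n);
    energy += u * u * dt;
    if (!std::isfinite(V) || !std::isfinite(n))
      stop("controlled trajectory blew up at t = %f ms", t + dt);
    if ((k + 1) % record_every == 0) {
      rt[ir] = (k + 1) * dt; rV[ir] = V; rn[ir] = n; ru[ir] = u; re[ir] = energy;
      ++ir;
    }
  }
  return List::create(_["t"] = rt, _["V"] = rV, _["n"] = rn,
                      _["u"] = ru, _["cum_energy"] = re,
                      _["energy"] = energy,
                      _["V_end"] = V, _["n_end"] = n);
}
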