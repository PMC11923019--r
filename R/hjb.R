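#' Uniform solver grid in scaled coordinates
#'
#' The default domain x in \[-1.0, 0.55\], y in \[0, 0.9\] covers the
#' periodic orbit (V in about \[-75, 45\] mV, n in \[0.39, 0.72\]) and the
#' phaseless point with wide margins for noise excursions (noisy
#' trajectories at D = 15 stay within V in about \[-82, 48\] mV). Keeping
#' the corners out of the far hyperpolarized/high-n region, where the drift
#' is an order of magnitude faster than anywhere trajectories go, also
#' keeps the CFL-limited time step reasonable.
#'
#' @param x_min,x_max,y_min,y_max domain bounds in scaled coordinates
#'   (x = V/K, y = n).
#' @param nx,ny node counts (at least 16 each for the WENO5 stencil).
#' @return an object of class `hh_grid`.
#' @export
grid_spec <- function(x_min = -1.0, x_max = 0.55, y_min = 0.0, y_max = 0.9,
                      nx = 320, ny = 320) {
  stopifnot(nx >= 16, ny >= 16, x_max > x_min, y_max > y_min)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 nx = as.integer(nx), ny = as.integer(ny),
                 dx = (x_max - x_min) / (nx - 1),
                 dy = (y_max - y_min) / (ny - 1),
                 x = seq(x_min, x_max, length.out = nx),
                 y = seq(y_min, y_max, length.out = ny)),
            class = "hh_grid")
}

#' Cost specification for the phase-resetting problem
#'
#' Total cost \eqn{J = \int_0^{T_{end}} u^2\,dt + \gamma q(z(T_{end}))} with
#' the Gaussian end-point cost
#' \deqn{\gamma q(z) = \gamma\left(1 - e^{-\left[(x - x_{pl})^2/\sigma_x^2 +
#'   (y - y_{pl})^2/\sigma_y^2\right]}\right),}
#' which is zero at the phaseless target and saturates at \eqn{\gamma} far
#' from it.
#'
#' @param gamma end-point penalty weight.
#' @param sigma_x2,sigma_y2 squared Gaussian widths in scaled coordinates.
#' @param T_end control horizon, ms.
#' @param target scaled target `c(x_pl, y_pl)`; by default the phaseless
#'   point of `params` found by [find_fixed_point()].
#' @param params used only to locate the default target.
#' @return an object of class `hh_cost`.
#' @export
cost_spec <- function(gamma = 1000, sigma_x2 = 0.001, sigma_y2 = 0.001,
                      T_end = 7, target = NULL, params = neuron_params()) {
  stopifnot(gamma > 0, sigma_x2 > 0, sigma_y2 > 0, T_end > 0)
  if (is.null(target)) {
    fp <- find_fixed_point(params)
    target <- c(fp$V / params$K, fp$n)
  }
  structure(list(gamma = gamma, sigma_x2 = sigma_x2, sigma_y2 = sigma_y2,
                 T_end = T_end, target = target),
            class = "hh_cost")
}

#' Gaussian end-point cost
#'
#' @param x,y scaled state (vectorized; `outer`-compatible).
#' @param cost an `hh_cost` object.
#' @return \eqn{\gamma q(x, y)}.
#' @export
terminal_cost <- function(x, y, cost) {
  cost$gamma * (1 - exp(-((x - cost$target[1])^2 / cost$sigma_x2 +
                          (y - cost$target[2])^2 / cost$sigma_y2)))
}

#' One-sided WENO5 derivatives along a line
#'
#' Fifth-order weighted essentially non-oscillatory Hamilton-Jacobi
#' reconstructions of the left- and right-biased first derivative at every
#' node. Ghost nodes extend the line by linear extrapolation.
#'
#' @param f values on a uniform line (length at least 7).
#' @param h node spacing.
#' @return list with components `left` and `right`.
#' @export
weno5_derivatives <- function(f, h) {
  if (length(f) < 7) stop("WENO5 needs at least 7 nodes")
  cpp_weno5_line(as.numeric(f), h)
}

#' Hamiltonian minimized over the bounded control
#'
#' The running cost \eqn{u^2} plus costate-weighted drift, minimized over
#' \eqn{|u| \le u_{max}} (Pontryagin saturation):
#' \deqn{H = p^T F - p_x^2/(4K^2)} when \eqn{|p_x| \le 2 K u_{max}}, and
#' \deqn{H = p^T F + u_{max}^2 - |p_x| u_{max}/K} beyond the switch. The
#' two branches agree at \eqn{|p_x| = 2 K u_{max}}.
#'
#' @param fx,fy scaled drift components at the evaluation point.
#' @param p_x,p_y costate (value-gradient) components.
#' @param u_max control bound, uA/uF.
#' @param K voltage scaling factor.
#' @return the Hamiltonian value (vectorized).
#' @export
hamiltonian_optimal <- function(fx, fy, p_x, p_y, u_max, K) {
  h <- p_x * fx + p_y * fy
  ifelse(abs(p_x) <= 2 * K * u_max,
         h - p_x^2 / (4 * K^2),
         h + u_max^2 - abs(p_x) * u_max / K)
}

#' Local Lax-Friedrichs numerical Hamiltonian
#'
#' Monotone flux for the level-set update: the Hamiltonian evaluated at the
#' averaged one-sided costates minus directional dissipation,
#' \deqn{\hat H = H(\bar p_x, \bar p_y) - \tfrac{\alpha_x}{2}(p_x^+ - p_x^-)
#'   - \tfrac{\alpha_y}{2}(p_y^+ - p_y^-),}
#' with \eqn{\alpha_x \ge |f_x| + u_{max}/K} and \eqn{\alpha_y \ge |f_y|}
#' bounding the costate-derivatives of H.
#'
#' @param p_x_minus,p_x_plus,p_y_minus,p_y_plus one-sided costates.
#' @param fx,fy scaled drift at the node.
#' @param alpha_x,alpha_y dissipation coefficients.
#' @inheritParams hamiltonian_optimal
#' @return the numerical Hamiltonian (vectorized).
#' @export
llf_numerical_hamiltonian <- function(p_x_minus, p_x_plus,
                                      p_y_minus, p_y_plus,
                                      fx, fy, alpha_x, alpha_y, u_max, K) {
  hamiltonian_optimal(fx, fy, (p_x_minus + p_x_plus) / 2,
                      (p_y_minus + p_y_plus) / 2, u_max, K) -
    (alpha_x / 2) * (p_x_plus - p_x_minus) -
    (alpha_y / 2) * (p_y_plus - p_y_minus)
}

#' Implicit diffusion step along x
#'
#' Solves \eqn{(I - dt\,(D/K^2)\,\partial^2/\partial x^2)\,V^{new} = V}
#' along each constant-y line with a second-order centered Laplacian,
#' homogeneous-Neumann boundary rows, and a tridiagonal (Thomas) solve. The
#' y direction carries no diffusion: noise enters the voltage equation only.
#'
#' @param slice value-function slice, nx x ny matrix (x indexes rows).
#' @param D noise intensity.
#' @param K voltage scaling factor.
#' @param dt time step.
#' @param dx x spacing.
#' @return the updated slice. `D = 0` returns the input unchanged.
#' @export
implicit_diffusion_step <- function(slice, D, K, dt, dx) {
  stopifnot(dt > 0, D >= 0)
  if (D == 0) return(slice)
  cpp_diffusion_x(slice, dt * D / K^2, dx)
}

#' Solve an HJB equation on a grid for a custom drift
#'
#' Engine behind [solve_hjb()], exposed so that analytically solvable
#' problems (linear-quadratic control, pure advection) can be run through
#' the identical numerical path. Marches
#' \eqn{V_t + \min_u H + (D/K^2) V_{xx} = 0}
#' backward from `terminal` with per-step Lie splitting: explicit local
#' Lax-Friedrichs WENO5 Hamiltonian update, then the implicit tridiagonal
#' x-diffusion solve. The time step is set from the CFL condition
#' `dt = cfl * min(dx/max alpha_x, dy/max alpha_y)`.
#'
#' @param Fx,Fy drift components on the grid (nx x ny matrices).
#' @param terminal terminal value on the grid.
#' @param grid an `hh_grid`.
#' @param T_end horizon.
#' @param u_max control bound.
#' @param K voltage scaling factor (control gain is 1/K).
#' @param D noise intensity.
#' @param cfl CFL number (explicit part).
#' @param store_dt approximate spacing of stored time slices.
#' @return a list with `slices` (nx x ny x n_times array, ascending time),
#'   `times`, `dt_pde`, `n_steps`.
#' @export
solve_hjb_grid <- function(Fx, Fy, terminal, grid, T_end, u_max, K,
                           D = 0, cfl = 0.5, store_dt = 0.01) {
  stopifnot(inherits(grid, "hh_grid"),
            nrow(Fx) == grid$nx, ncol(Fx) == grid$ny,
            all(dim(Fy) == dim(Fx)), all(dim(terminal) == dim(Fx)),
            T_end > 0, u_max >= 0, K > 0, D >= 0, cfl > 0)
  cpp_solve_hjb(Fx, Fy, terminal, grid$dx, grid$dy, u_max, K, D,
                T_end, cfl, store_dt)
}

#' Solve the stochastic HJB equation for the neuron model
#'
#' Computes the stochastic cost-to-go function \eqn{V(z, t)}: the minimum
#' expected cost (input energy plus Gaussian end-point penalty) to steer the
#' noisy neuron to the phaseless set by `T_end`, under \eqn{|u| \le u_{max}}.
#' The terminal slice is exactly \eqn{\gamma q}; the equation is marched
#' backward in time on the grid. With `D = 0` the same code path (diffusion
#' step skipped) produces the deterministic cost-to-go function.
#'
#' @param params an `hh_params` object.
#' @param grid an `hh_grid` (the target must lie strictly inside).
#' @param cost an `hh_cost`.
#' @param D noise intensity used in the PDE.
#' @param u_max control bound, uA/uF.
#' @param cfl CFL number for the explicit Hamiltonian update.
#' @param store_dt approximate spacing of stored slices, ms; policy lookup
#'   interpolates linearly in time between slices.
#' @return an object of class `hh_value_function`: list with `slices`
#'   (nx x ny x n_times), `times` (ascending, `times[1] = 0`,
#'   last = `T_end`), `grid`, `cost`, `params`, `D`, `u_max`, `dt_pde`,
#'   `n_steps`.
#' @examples
#' \donttest{
#' vf <- solve_hjb(grid = grid_spec(nx = 48, ny = 48), D = 1)
#' print(vf)
#' }
#' @export
solve_hjb <- function(params = neuron_params(), grid = grid_spec(),
                      cost = cost_spec(params = params), D = 0,
                      u_max = 10, cfl = 0.5, store_dt = 0.01) {
  stopifnot(D >= 0, u_max > 0)
  tg <- cost$target
  if (tg[1] <= grid$x_min || tg[1] >= grid$x_max ||
      tg[2] <= grid$y_min || tg[2] >= grid$y_max)
    stop("target point must lie strictly inside the grid")
  r <- rhs_scaled(rep(grid$x, times = grid$ny),
                  rep(grid$y, each = grid$nx), params)
  Fx <- matrix(r$dx, grid$nx, grid$ny)
  Fy <- matrix(r$dy, grid$nx, grid$ny)
  term <- outer(grid$x, grid$y, terminal_cost, cost = cost)
  sol <- solve_hjb_grid(Fx, Fy, term, grid, cost$T_end, u_max, params$K,
                        D = D, cfl = cfl, store_dt = store_dt)
  structure(list(slices = sol$slices, times = sol$times, grid = grid,
                 cost = cost, params = params, D = D, u_max = u_max,
                 dt_pde = sol$dt_pde, n_steps = sol$n_steps),
            class = "hh_value_function")
}

#' @export
print.hh_value_function <- function(x, ...) {
  cat(sprintf("Stochastic HJB value function (D = %g, u_max = %g)\n",
              x$D, x$u_max))
  cat(sprintf("  grid %d x %d on [%g, %g] x [%g, %g], T_end = %g ms\n",
              x$grid$nx, x$grid$ny, x$grid$x_min, x$grid$x_max,
              x$grid$y_min, x$grid$y_max, x$cost$T_end))
  cat(sprintf("  %d backward steps (dt_pde = %.3g ms), %d stored slices\n",
              as.integer(x$n_steps), x$dt_pde, length(x$times)))
  cat(sprintf("  value range at t = 0: [%.4g, %.4g]\n",
              min(x$slices[, , 1]), max(x$slices[, , 1])))
  invisible(x)
}

#' @export
plot.hh_value_function <- function(x, t = 0, ...) {
  k <- which.min(abs(x$times - t))
  image(x$grid$x, x$grid$y, x$slices[, , k],
        xlab = "x = V/K", ylab = "y = n",
        main = sprintf("V(z, t = %.2f ms), D = %g", x$times[k], x$D), ...)
  points(x$cost$target[1], x$cost$target[2], pch = 1, cex = 1.5)
  invisible(x)
}

#' Value function at an arbitrary state and time
#'
#' Bilinear interpolation in space, linear in time between stored slices.
#'
#' @param vf an `hh_value_function`.
#' @param x,y scaled state (vectorized).
#' @param t time in `[0, T_end]`.
#' @return interpolated values.
#' @export
value_at <- function(vf, x, y, t = 0) {
  if (t < min(vf$times) - 1e-9 || t > max(vf$times) + 1e-9)
    stop("t outside [0, T_end]")
  k1 <- max(2, min(length(vf$times), findInterval(t, vf$times) + 1))
  k0 <- k1 - 1
  w <- (t - vf$times[k0]) / (vf$times[k1] - vf$times[k0])
  w <- min(1, max(0, w))
  (1 - w) * bilinear_interpolate(vf$slices[, , k0], vf$grid, x, y) +
    w * bilinear_interpolate(vf$slices[, , k1], vf$grid, x, y)
}
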