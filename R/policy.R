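#' Saturated optimal control from the value gradient
#'
#' The minimizer of the Hamiltonian under \eqn{|u| \le u_{max}}:
#' \eqn{u = -V_x/(2K)} while \eqn{|V_x| \le 2 K u_{max}}, clipped to
#' \eqn{-\mathrm{sign}(V_x)\, u_{max}} beyond the switch (both branches
#' agree at the switch).
#'
#' @param V_x x-component of the value gradient (vectorized).
#' @param u_max control bound.
#' @param K voltage scaling factor.
#' @return the control, uA/uF.
#' @export
optimal_control_from_gradient <- function(V_x, u_max, K) {
  ifelse(abs(V_x) <= 2 * K * u_max, -V_x / (2 * K), -sign(V_x) * u_max)
}

#' Bilinear interpolation of a grid field
#'
#' Standard four-node blend; queries outside the grid are clamped to the
#' boundary node (rare noise excursions must not abort a run).
#'
#' @param field nx x ny matrix on `grid`.
#' @param grid an `hh_grid`.
#' @param x,y query coordinates (vectorized).
#' @return interpolated values.
#' @export
bilinear_interpolate <- function(field, grid, x, y) {
  fx <- pmin(pmax((x - grid$x_min) / grid$dx, 0), grid$nx - 1)
  fy <- pmin(pmax((y - grid$y_min) / grid$dy, 0), grid$ny - 1)
  i <- pmin(floor(fx), grid$nx - 2) + 1
  j <- pmin(floor(fy), grid$ny - 2) + 1
  ax <- fx - (i - 1); ay <- fy - (j - 1)
  nx <- grid$nx
  f00 <- field[cbind(i, j)];     f10 <- field[cbind(i + 1, j)]
  f01 <- field[cbind(i, j + 1)]; f11 <- field[cbind(i + 1, j + 1)]
  (1 - ax) * (1 - ay) * f00 + ax * (1 - ay) * f10 +
    (1 - ax) * ay * f01 + ax * ay * f11
}

#' Feedback policy from a value function
#'
#' Precomputes the value gradient \eqn{V_x} on the grid nodes of every
#' stored slice (central differences, one-sided at the edges); feedback
#' queries then interpolate the gradient (bilinear in space, linear in time)
#' and map it through [optimal_control_from_gradient()].
#'
#' The strategy label records how the policy is meant to be evaluated:
#' `"stochastic-on-stochastic"` (u*), `"stochastic-on-deterministic"`
#' (u-tilde*), `"deterministic-on-stochastic"` (u0*),
#' `"deterministic-on-deterministic"` (u_d*). The caller supplies the value
#' function solved at the matching noise level (stochastic strategies: the
#' simulation D; deterministic strategies: D = 0 in the PDE).
#'
#' @param value an `hh_value_function`.
#' @param strategy one of the four labels above.
#' @return an object of class `hh_policy`.
#' @export
hh_policy <- function(value,
                      strategy = c("stochastic-on-stochastic",
                                   "stochastic-on-deterministic",
                                   "deterministic-on-stochastic",
                                   "deterministic-on-deterministic")) {
  strategy <- match.arg(strategy)
  sl <- value$slices
  nx <- dim(sl)[1]
  dx <- value$grid$dx
  Vx <- array(0, dim(sl))
  Vx[2:(nx - 1), , ] <- (sl[3:nx, , , drop = FALSE] -
                           sl[1:(nx - 2), , , drop = FALSE]) / (2 * dx)
  Vx[1, , ] <- (sl[2, , ] - sl[1, , ]) / dx
  Vx[nx, , ] <- (sl[nx, , ] - sl[nx - 1, , ]) / dx
  structure(list(Vx = Vx, times = value$times, grid = value$grid,
                 u_max = value$u_max, K = value$params$K,
                 D = value$D, params = value$params, cost = value$cost,
                 strategy = strategy),
            class = "hh_policy")
}

#' @export
print.hh_policy <- function(x, ...) {
  cat(sprintf("Feedback policy (%s): value function D = %g, u_max = %g\n",
              x$strategy, x$D, x$u_max))
  invisible(x)
}

#' Evaluate the feedback control law
#'
#' @param policy an `hh_policy`.
#' @param x,y scaled state (vectorized).
#' @param t time in `[0, T_end]`, ms.
#' @return control value(s), clipped to `u_max`.
#' @export
feedback_control <- function(policy, x, y, t) {
  tms <- policy$times
  if (t < tms[1] - 1e-9 || t > tms[length(tms)] + 1e-9)
    stop("t outside [0, T_end]")
  k1 <- max(2, min(length(tms), findInterval(t, tms) + 1))
  k0 <- k1 - 1
  w <- min(1, max(0, (t - tms[k0]) / (tms[k1] - tms[k0])))
  vx <- (1 - w) * bilinear_interpolate(policy$Vx[, , k0], policy$grid, x, y) +
    w * bilinear_interpolate(policy$Vx[, , k1], policy$grid, x, y)
  optimal_control_from_gradient(vx, policy$u_max, policy$K)
}

policy_is_deterministic_trajectory <- function(policy) {
  policy$strategy %in% c("stochastic-on-deterministic",
                         "deterministic-on-deterministic")
}

#' Closed-loop control of a single neuron
#'
#' Integrates the neuron from `z0` over the control horizon with the
#' feedback law queried once per SDE step (zero-order hold), and reports the
#' three cost components: input energy \eqn{\int u^2 dt}, end-point cost
#' \eqn{\gamma q(z(T_{end}))}, and total cost J. For the
#' "on-deterministic" strategies the trajectory carries no noise and the
#' result is seed-independent.
#'
#' @param policy an `hh_policy`.
#' @param D_sim noise intensity of the simulated trajectory (must be 0 for
#'   on-deterministic strategies).
#' @param z0 initial state `c(V, n)` in physical coordinates; default the
#'   spike point (maximum voltage on the deterministic orbit).
#' @param dt SDE step, ms.
#' @param seed integer seed.
#' @param record_every thin the stored trajectory.
#' @return list with `trajectory` (`hh_trajectory`), `energy`,
#'   `endpoint_cost`, `total_cost`, `z_end`.
#' @export
run_single_neuron <- function(policy, D_sim = 0, z0 = NULL, dt = 0.005,
                              seed = 1, record_every = 1L) {
  stopifnot(inherits(policy, "hh_policy"), D_sim >= 0)
  if (policy_is_deterministic_trajectory(policy) && D_sim != 0)
    stop("strategy '", policy$strategy,
         "' evaluates the policy on the deterministic trajectory; D_sim must be 0")
  if (is.null(z0)) z0 <- find_period(policy$params)$spike_point
  g <- policy$grid
  rec <- cpp_run_neuron_policy(z0[1], z0[2], par_vec(policy$params), dt,
                               D_sim, seed, policy$Vx,
                               policy$times, g$x_min, g$dx, g$nx,
                               g$y_min, g$dy, g$ny, policy$u_max,
                               as.integer(record_every))
  endpoint <- terminal_cost(rec$V_end / policy$K, rec$n_end, policy$cost)
  traj <- structure(data.frame(t = rec$t, V = rec$V, n = rec$n, u = rec$u,
                               cum_energy = rec$cum_energy),
                    energy = rec$energy, dt = dt, D = D_sim, seed = seed,
                    class = c("hh_trajectory", "data.frame"))
  list(trajectory = traj, energy = rec$energy, endpoint_cost = endpoint,
       total_cost = rec$energy + endpoint,
       z_end = c(V = rec$V_end, n = rec$n_end))
}

#' Precompute a control waveform on the deterministic trajectory
#'
#' Runs the closed loop without noise and returns the 7 ms control signal
#' sampled on the SDE grid. This is the waveform replayed by the event-based
#' population controller: u-tilde* when `policy` wraps a stochastic value
#' function, u_d* when it wraps the deterministic (D = 0) one.
#'
#' @inheritParams run_single_neuron
#' @return an object of class `hh_waveform`: data.frame `(t, u)` with
#'   attributes `dt`, `D` (of the value function), `energy`.
#' @export
control_waveform <- function(policy, z0 = NULL, dt = 0.005) {
  run <- run_single_neuron(policy, D_sim = 0, z0 = z0, dt = dt, seed = 1)
  tr <- run$trajectory
  u <- tr$u[-1]                      # u over [t, t + dt), zero-order hold
  structure(data.frame(t = tr$t[-length(tr$t)], u = u),
            dt = dt, D = policy$D, energy = run$energy,
            class = c("hh_waveform", "data.frame"))
}

#' @export
print.hh_waveform <- function(x, ...) {
  cat(sprintf("Control waveform: %.3f ms at dt = %g ms (value function D = %g)\n",
              nrow(x) * attr(x, "dt"), attr(x, "dt"), attr(x, "D")))
  cat(sprintf("  energy %.4f (uA/uF)^2 ms, max |u| = %.3f\n",
              attr(x, "energy"), max(abs(x$u))))
  invisible(x)
}

#' Export / import a control waveform as CSV
#'
#' Columns `t`, `u`; the population module can replay a waveform without a
#' value function in memory.
#' @param wave an `hh_waveform`.
#' @param path file path.
#' @export
write_waveform_csv <- function(wave, path) {
  write.csv(data.frame(t = wave$t, u = wave$u), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param dt the SDE step the waveform was sampled on (validated).
#' @export
read_waveform_csv <- function(path, dt = 0.005) {
  df <- read.csv(path)
  stopifnot(all(c("t", "u") %in% names(df)))
  if (nrow(df) > 1 && abs(diff(df$t)[1] - dt) > 1e-9)
    stop("waveform cadence does not match dt = ", dt)
  structure(df[c("t", "u")], dt = dt, D = NA_real_,
            energy = sum(df$u^2) * dt,
            class = c("hh_waveform", "data.frame"))
}
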