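#' One Honeycutt SRK2 step
#'
#' Second-order stochastic Runge-Kutta update for additive, state-independent
#' noise:
#' \deqn{g = a \sqrt{2 D\, dt}\, \xi,\quad F_1 = f(z),\quad
#'       F_2 = f(z + dt\,F_1 + g),\quad
#'       z' = z + \tfrac{dt}{2}(F_1 + F_2) + g,}
#' with the same Gaussian draw \eqn{\xi} in predictor and corrector. With
#' `D = 0` the update is exactly a deterministic Heun (RK2) step.
#'
#' `z` may be a vector (one state) or a matrix (one row per independent
#' path); `drift` must return an object of the same shape.
#'
#' @param z current state (numeric vector or matrix of paths).
#' @param drift function of `z` returning the deterministic drift.
#' @param dt time step.
#' @param xi standard-normal draw(s), same shape as `z`.
#' @param noise_amp per-component noise amplitude `a` (recycled).
#' @param D noise intensity.
#' @return the updated state.
#' @export
srk2_step <- function(z, drift, dt, xi = 0, noise_amp = 0, D = 0) {
  stopifnot(dt > 0, D >= 0)
  g <- if (D > 0) {
    gg <- noise_amp * sqrt(2 * D * dt) * xi
    if (is.matrix(z) && !is.matrix(gg)) matrix(gg, nrow(z), ncol(z), byrow = TRUE) else gg
  } else 0
  F1 <- drift(z)
  F2 <- drift(z + dt * F1 + g)
  z + (dt / 2) * (F1 + F2) + g
}

#' Integrate a single neuron SDE
#'
#' Advances the reduced Hodgkin-Huxley neuron
#' \eqn{dV = (f_V + u)\,dt + \sqrt{2D}\,dW}, \eqn{dn = f_n\,dt}
#' with the Honeycutt SRK2 scheme in physical coordinates. The control is
#' sampled zero-order-hold once per step at the pre-step state and time, and
#' the running energy is the left-Riemann sum of \eqn{u^2 dt}.
#'
#' With a `NULL` or numeric `control` the loop runs in compiled code; a
#' function `control(V, n, t)` falls back to an R loop (intended for short
#' diagnostic runs).
#'
#' @param params an `hh_params` object.
#' @param z0 initial state `c(V, n)`.
#' @param T horizon, ms.
#' @param dt SDE step, ms (default 0.005, about 2400 steps per spike
#'   period).
#' @param D noise intensity; `D = 0` gives the deterministic trajectory.
#' @param seed integer seed; identical seeds give bit-identical records.
#' @param control `NULL` (u = 0), a scalar, a per-step vector, or a
#'   function `(V, n, t) -> u`.
#' @param record_every thin the stored record to every so-many steps.
#' @return an object of class `hh_trajectory`: a data.frame with columns
#'   `t`, `V`, `n`, `u`, `cum_energy` and attributes `energy`, `dt`, `D`,
#'   `seed`.
#' @examples
#' tr <- integrate_neuron(neuron_params(), c(-59, 0.45), T = 25, D = 0)
#' max(tr$V)   # spike amplitude
#' @export
integrate_neuron <- function(params, z0, T, dt = 0.005, D = 0, seed = 1,
                             control = NULL, record_every = 1L) {
  stopifnot(T > 0, dt > 0, D >= 0)
  if (is.function(control)) {
    nsteps <- round(T / dt)
    set.seed(seed)
    xi <- if (D > 0) rnorm(nsteps) else numeric(nsteps)
    V <- z0[1]; n <- z0[2]; energy <- 0
    out <- matrix(NA_real_, nsteps + 1, 5)
    out[1, ] <- c(0, V, n, NA, 0)
    namp <- sqrt(2 * D * dt)
    for (k in seq_len(nsteps)) {
      t <- (k - 1) * dt
      u <- control(V, n, t)
      g <- namp * xi[k]
      r1 <- rhs_physical(V, n, params, u)
      Vp <- V + dt * r1$dV + g; np <- n + dt * r1$dn
      r2 <- rhs_physical(Vp, np, params, u)
      V <- V + dt / 2 * (r1$dV + r2$dV) + g
      n <- n + dt / 2 * (r1$dn + r2$dn)
      energy <- energy + u^2 * dt
      if (!is.finite(V) || !is.finite(n))
        stop("trajectory blew up at t = ", signif(t + dt, 6), " ms")
      out[k + 1, ] <- c(k * dt, V, n, u, energy)
    }
    keep <- c(1, which((seq_len(nsteps)) %% record_every == 0) + 1)
    df <- as.data.frame(out[keep, , drop = FALSE])
    names(df) <- c("t", "V", "n", "u", "cum_energy")
  } else {
    uvec <- if (is.null(control)) numeric(0) else as.numeric(control)
    rec <- cpp_run_neuron(z0[1], z0[2], par_vec(params), T, dt, D,
                          seed, uvec, as.integer(record_every))
    df <- data.frame(t = rec$t, V = rec$V, n = rec$n, u = rec$u,
                     cum_energy = rec$cum_energy)
    energy <- rec$energy
  }
  structure(df, energy = energy, dt = dt, D = D, seed = seed,
            class = c("hh_trajectory", "data.frame"))
}

#' @export
print.hh_trajectory <- function(x, ...) {
  cat(sprintf("Neuron trajectory: %.3f ms at dt = %g ms, D = %g, seed %s\n",
              max(x$t), attr(x, "dt"), attr(x, "D"),
              format(attr(x, "seed"))))
  cat(sprintf("  energy int u^2 dt = %.4f (uA/uF)^2 ms\n", attr(x, "energy")))
  invisible(x)
}

#' @export
plot.hh_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t, x$V, type = "l", xlab = "t (ms)", ylab = "V (mV)", ...)
  plot(x$t, x$u, type = "l", xlab = "t (ms)", ylab = "u (uA/uF)", ...)
  invisible(x)
}

#' Export a trajectory record to CSV
#'
#' Columns `t`, `V`, `n`, `u`, `cum_energy`.
#' @param traj an `hh_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
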