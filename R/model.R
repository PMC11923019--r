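#' Parameters of the reduced Hodgkin-Huxley neuron
#'
#' The classical squid-axon conductances with instantaneous sodium activation
#' (\eqn{m = m_\infty(V)}) and sodium inactivation slaved to the potassium
#' gate (\eqn{h = 0.8 - n}), which reduces the four-dimensional
#' Hodgkin-Huxley equations to a planar oscillator in \eqn{(V, n)}.
#'
#' With the default baseline current \eqn{I_b = 10\,\mu A/cm^2} the model
#' spikes periodically (period about 11.85 ms). Below
#' \eqn{I_b \approx 6.36} it is excitable (no periodic orbit); between about
#' 6.36 and 8.82 a stable fixed point and a stable periodic orbit coexist.
#'
#' @param I_b baseline current, uA/cm^2.
#' @param gNa,gK,gL maximal conductances, mS/cm^2.
#' @param V_Na,V_K,V_L reversal potentials, mV.
#' @param c membrane capacitance, uF/cm^2.
#' @param K voltage scaling factor used in the solver coordinates
#'   \eqn{x = V/K}; dimensionless.
#' @return an object of class `hh_params`.
#' @examples
#' p <- neuron_params()
#' rhs_physical(-59.6, 0.403, p)
#' @export
neuron_params <- function(I_b = 10, gNa = 120, gK = 36, gL = 0.3,
                          V_Na = 50, V_K = -77, V_L = -54.4,
                          c = 1, K = 100) {
  stopifnot(gNa > 0, gK > 0, gL > 0, c > 0, K > 0, is.finite(I_b))
  structure(list(I_b = I_b, gNa = gNa, gK = gK, gL = gL,
                 V_Na = V_Na, V_K = V_K, V_L = V_L, c = c, K = K),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Reduced Hodgkin-Huxley parameters\n")
  cat(sprintf("  I_b = %g uA/cm^2, c = %g uF/cm^2, K = %g\n", x$I_b, x$c, x$K))
  cat(sprintf("  gNa = %g, gK = %g, gL = %g mS/cm^2\n", x$gNa, x$gK, x$gL))
  cat(sprintf("  V_Na = %g, V_K = %g, V_L = %g mV\n", x$V_Na, x$V_K, x$V_L))
  invisible(x)
}

# named vector in the layout the compiled code expects
par_vec <- function(p) {
  c(gNa = p$gNa, gK = p$gK, gL = p$gL, VNa = p$V_Na, VK = p$V_K,
    VL = p$V_L, c = p$c, Ib = p$I_b, K = p$K)
}

#' Gating rate functions of the membrane model
#'
#' Voltage-dependent opening/closing rates for the sodium activation gate
#' (`a_m`, `b_m`) and the potassium gate (`a_n`, `b_n`), plus the
#' instantaneous sodium activation `m_inf = a_m/(a_m + b_m)`. The removable
#' singularities of `a_m` at V = -40 mV and `a_n` at V = -55 mV are
#' evaluated by their analytic limits (1.0 and 0.1) on a small
#' `|V - V0| < 1e-7` branch to avoid catastrophic cancellation.
#'
#' @param V membrane voltage, mV (vectorized).
#' @return a list with components `a_m`, `b_m`, `a_n`, `b_n`, `m_inf`
#'   (rates in 1/ms).
#' @export
gating_rates <- function(V) {
  if (any(!is.finite(V))) stop("non-finite voltage")
  dm <- V + 40
  a_m <- ifelse(abs(dm) < 1e-7, 1.0, 0.1 * dm / (1 - exp(-dm / 10)))
  b_m <- 4 * exp(-(V + 65) / 18)
  dn <- V + 55
  a_n <- ifelse(abs(dn) < 1e-7, 0.1, 0.01 * dn / (1 - exp(-dn / 10)))
  b_n <- 0.125 * exp(-(V + 65) / 80)
  list(a_m = a_m, b_m = b_m, a_n = a_n, b_n = b_n,
       m_inf = a_m / (a_m + b_m))
}

#' Deterministic vector field in physical coordinates
#'
#' Right-hand sides \eqn{\dot V = f_V(V,n) + u}, \eqn{\dot n = f_n(V,n)}.
#' The additive control acts on the voltage equation only.
#'
#' @param V,n state (vectorized).
#' @param params an `hh_params` object.
#' @param u control input, uA/uF.
#' @return list with components `dV`, `dn` (units mV/ms and 1/ms).
#' @export
rhs_physical <- function(V, n, params = neuron_params(), u = 0) {
  if (any(!is.finite(V)) || any(!is.finite(n))) stop("non-finite state")
  g <- gating_rates(V)
  fV <- (params$I_b -
           params$gNa * g$m_inf^3 * (0.8 - n) * (V - params$V_Na) -
           params$gK * n^4 * (V - params$V_K) -
           params$gL * (V - params$V_L)) / params$c
  fn <- g$a_n * (1 - n) - g$b_n * n
  list(dV = fV + u, dn = fn)
}

#' Vector field in solver (scaled) coordinates
#'
#' The solver works in \eqn{z = (x, y) = (V/K, n)} so both states are of
#' order one. The drift is \eqn{F(z) = (f_V(Kx, y)/K,\; f_n(Kx, y))} and the
#' control enters through \eqn{B = (1/K, 0)}.
#'
#' @param x,y scaled state (vectorized).
#' @inheritParams rhs_physical
#' @return list with components `dx`, `dy`.
#' @export
rhs_scaled <- function(x, y, params = neuron_params(), u = 0) {
  r <- rhs_physical(params$K * x, y, params, u = 0)
  list(dx = r$dV / params$K + u / params$K, dy = r$dn)
}

#' Locate the unstable fixed point (phaseless set)
#'
#' Damped Newton iteration on \eqn{(f_V, f_n)} with a finite-difference
#' Jacobian. In the oscillatory regime this root is the phaseless set of the
#' oscillator: the one state where asymptotic phase is undefined, so noise
#' acting there randomizes the subsequent spike time.
#'
#' @param params an `hh_params` object.
#' @param guess starting state `c(V, n)` inside V in \[-100, 50\],
#'   n in \[0, 1\].
#' @param tol residual norm required for convergence.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `hh_fixed_point`: a list with `V`, `n`,
#'   `residual`, `jacobian` (2x2), `eigenvalues`, `unstable`.
#' @examples
#' fp <- find_fixed_point(neuron_params())
#' round(c(fp$V, fp$n), 3)   # close to (-59.6, 0.403)
#' @export
find_fixed_point <- function(params = neuron_params(), guess = c(-59, 0.40),
                             tol = 1e-12, max_iter = 100) {
  stopifnot(length(guess) == 2, guess[1] >= -100, guess[1] <= 50,
            guess[2] >= 0, guess[2] <= 1)
  z <- as.numeric(guess)
  fval <- function(z) {
    r <- rhs_physical(z[1], z[2], params)
    c(r$dV, r$dn)
  }
  jac <- function(z, h = 1e-6) {
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      e <- c(0, 0); e[k] <- h
      J[, k] <- (fval(z + e) - fval(z - e)) / (2 * h)
    }
    J
  }
  Fz <- fval(z)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(Fz^2)) < tol) break
    J <- jac(z)
    step <- tryCatch(solve(J, Fz), error = function(e)
      stop("singular Jacobian during root find at (",
           paste(signif(z, 6), collapse = ", "), ")"))
    lambda <- 1
    repeat {   # damping: accept the first step that reduces the residual
      znew <- z - lambda * step
      Fnew <- fval(znew)
      if (sqrt(sum(Fnew^2)) < sqrt(sum(Fz^2)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    z <- znew; Fz <- Fnew
  }
  if (sqrt(sum(Fz^2)) >= tol)
    stop("fixed-point iteration did not converge; last iterate (",
         paste(signif(z, 8), collapse = ", "), "), residual ",
         signif(sqrt(sum(Fz^2)), 3))
  J <- jac(z)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(V = z[1], n = z[2], residual = sqrt(sum(Fz^2)),
                 jacobian = J, eigenvalues = ev,
                 unstable = max(Re(ev)) > 0),
            class = "hh_fixed_point")
}

#' @export
print.hh_fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point (V, n) = (%.4f, %.6f), residual %.2e\n",
              x$V, x$n, x$residual))
  cat(sprintf("  eigenvalues %s (%s)\n",
              paste(format(x$eigenvalues, digits = 4), collapse = ", "),
              if (x$unstable) "unstable" else "stable"))
  invisible(x)
}

#' Spiking period and spike point of the deterministic orbit
#'
#' Integrates the deterministic model, discards a transient, and estimates
#' the period from successive upward crossings of the Poincare section
#' V = `section` mV, with linear interpolation of the crossing times. The
#' spike point is the state of maximal voltage over the final period.
#'
#' @param params an `hh_params` object (must be in the oscillatory regime).
#' @param dt integration step, ms.
#' @param transient initial interval discarded before measuring, ms.
#' @param horizon total integration time, ms.
#' @param section Poincare section voltage, mV. Arbitrary, but it must cut
#'   the orbit transversally; V = 0 cuts the spike upstroke.
#' @param z0 initial state.
#' @return an object of class `hh_orbit`: list with `period` (ms),
#'   `spike_point` (c(V, n) at maximal V), `phaseless_point`,
#'   `n_crossings`.
#' @examples
#' \donttest{
#' orb <- find_period(neuron_params())
#' orb$period   # about 11.85 ms
#' }
#' @export
find_period <- function(params = neuron_params(), dt = 0.001,
                        transient = 200, horizon = transient + 150,
                        section = 0, z0 = c(-59, 0.45)) {
  rec <- cpp_run_neuron(z0[1], z0[2], par_vec(params), horizon, dt,
                        0, 0, numeric(0), 1L)
  V <- rec$V; tt <- rec$t
  i <- which(V[-length(V)] < section & V[-1] >= section & tt[-1] > transient)
  if (length(i) < 2)
    stop("no sustained oscillation detected: no Poincare-section crossings ",
         "after the transient (is the model in the oscillatory regime?)")
  tc <- tt[i] + dt * (section - V[i]) / (V[i + 1] - V[i])
  period <- mean(diff(tc))
  # spike point: max V over the final full period
  j <- which(tt >= tc[length(tc)] - period & tt <= tc[length(tc)])
  jmax <- j[which.max(V[j])]
  structure(list(period = period,
                 spike_point = c(V = V[jmax], n = rec$n[jmax]),
                 phaseless_point = {
                   fp <- find_fixed_point(params)
                   c(V = fp$V, n = fp$n)
                 },
                 n_crossings = length(tc)),
            class = "hh_orbit")
}

#' @export
print.hh_orbit <- function(x, ...) {
  cat(sprintf("Periodic orbit: T_s = %.4f ms (%d section crossings)\n",
              x$period, x$n_crossings))
  cat(sprintf("  spike point (V, n) = (%.3f, %.4f)\n",
              x$spike_point[1], x$spike_point[2]))
  cat(sprintf("  phaseless point (V, n) = (%.3f, %.4f)\n",
              x$phaseless_point[1], x$phaseless_point[2]))
  invisible(x)
}

# TRUE when a simulation started on the I_b = 10 orbit still oscillates at
# the end of `horizon` ms: late peak-to-peak voltage amplitude exceeding
# half the initial amplitude. Robust to slow decay near the saddle-node of
# periodic orbits.
sustained_oscillation <- function(params, z0, horizon = 500, dt = 0.005,
                                  window = 50) {
  rec <- cpp_run_neuron(z0[1], z0[2], par_vec(params), horizon, dt,
                        0, 0, numeric(0), 1L)
  early <- rec$V[rec$t <= window]
  late <- rec$V[rec$t >= horizon - window]
  (max(late) - min(late)) > 0.5 * (max(early) - min(early))
}

#' Locate the bifurcation currents of the reduced model
#'
#' Two thresholds in the baseline current \eqn{I_b}: the value where the
#' fixed point loses stability (largest real part of the Jacobian
#' eigenvalues crosses zero, located by bisection) and the onset of the
#' stable periodic orbit (bisection on sustained versus decaying oscillation
#' when started from the \eqn{I_b = 10} orbit).
#'
#' @param params template `hh_params`; `I_b` is overridden during the scan.
#' @param I_fp_range bracket for the fixed-point stability threshold.
#' @param I_orbit_range bracket for the periodic-orbit onset.
#' @param tol_fp,tol_orbit bisection tolerances, uA/cm^2.
#' @return list with `I_fp_instability` (about 8.82) and `I_orbit_onset`
#'   (about 6.36).
#' @export
scan_bifurcations <- function(params = neuron_params(),
                              I_fp_range = c(7, 10),
                              I_orbit_range = c(5.5, 7.5),
                              tol_fp = 0.01, tol_orbit = 0.02) {
  max_re <- function(I) {
    p <- params; p$I_b <- I
    max(Re(find_fixed_point(p, guess = c(-59, 0.4))$eigenvalues))
  }
  lo <- I_fp_range[1]; hi <- I_fp_range[2]
  if (max_re(lo) >= 0 || max_re(hi) <= 0)
    stop("I_fp_range does not bracket the stability change")
  while (hi - lo > tol_fp) {
    mid <- (lo + hi) / 2
    if (max_re(mid) > 0) hi <- mid else lo <- mid
  }
  I_fp <- (lo + hi) / 2

  orb <- find_period(params)
  z0 <- orb$spike_point
  lo <- I_orbit_range[1]; hi <- I_orbit_range[2]
  osc <- function(I) {
    p <- params; p$I_b <- I
    sustained_oscillation(p, z0)
  }
  if (osc(lo) || !osc(hi))
    stop("I_orbit_range does not bracket the orbit onset")
  while (hi - lo > tol_orbit) {
    mid <- (lo + hi) / 2
    if (osc(mid)) hi <- mid else lo <- mid
  }
  list(I_fp_instability = I_fp, I_orbit_onset = (lo + hi) / 2)
}
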