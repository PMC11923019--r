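#' Build a symmetric coupling matrix
#'
#' Electrotonic (gap-junction-like) coupling strengths \eqn{\alpha_{ij}} with
#' zero diagonal. Kinds:
#' \describe{
#'   \item{homogeneous}{all off-diagonals equal `alpha_bar`.}
#'   \item{heterogeneous}{upper-triangle entries drawn from
#'     Normal(`alpha_bar`, sd = 0.2 `alpha_bar`), mirrored; negative draws
#'     truncated to zero (electrotonic coupling is non-negative; the 5-sigma
#'     margin makes truncation rare).}
#'   \item{sparse-heterogeneous}{heterogeneous, then exactly 20% of the
#'     unordered pairs set to zero uniformly at random.}
#' }
#'
#' @param kind network kind.
#' @param N number of neurons.
#' @param alpha_bar mean coupling strength.
#' @param seed integer seed (R RNG, restored on exit).
#' @return an object of class `hh_network`: list with `alpha` (N x N),
#'   `N`, `alpha_bar`, `kind`, `seed`.
#' @examples
#' net <- build_coupling("sparse-heterogeneous", N = 10, alpha_bar = 0.2, seed = 1)
#' sum(net$alpha[upper.tri(net$alpha)] == 0)   # 0.2 * choose(10, 2) = 9
#' @export
build_coupling <- function(kind = c("homogeneous", "heterogeneous",
                                    "sparse-heterogeneous"),
                           N = 100, alpha_bar, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(N >= 2, alpha_bar >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  a <- matrix(0, N, N)
  up <- upper.tri(a)
  npairs <- N * (N - 1) / 2
  if (kind == "homogeneous") {
    a[up] <- alpha_bar
  } else {
    w <- pmax(rnorm(npairs, mean = alpha_bar, sd = 0.2 * alpha_bar), 0)
    if (kind == "sparse-heterogeneous")
      w[sample.int(npairs, round(0.2 * npairs))] <- 0
    a[up] <- w
  }
  a <- a + t(a)
  structure(list(alpha = a, N = N, alpha_bar = alpha_bar, kind = kind,
                 seed = seed),
            class = "hh_network")
}

#' @export
print.hh_network <- function(x, ...) {
  off <- x$alpha[upper.tri(x$alpha)]
  cat(sprintf("%s network: N = %d, alpha_bar = %g (seed %d)\n",
              x$kind, x$N, x$alpha_bar, x$seed))
  cat(sprintf("  off-diagonal mean %.4f, sd %.4f, %d of %d pairs zero\n",
              mean(off), sd(off), sum(off == 0), length(off)))
  invisible(x)
}

#' Coupling drift term
#'
#' \eqn{(1/N) \sum_j \alpha_{ij} (V_j - V_i)} for every neuron i. Vanishes
#' in perfect synchrony, so synchrony is invariant under the coupled
#' deterministic dynamics.
#'
#' @param V voltages of all neurons.
#' @param net an `hh_network`.
#' @return per-neuron coupling term, mV/ms.
#' @export
coupling_drift <- function(V, net) {
  as.numeric(net$alpha %*% V - V * rowSums(net$alpha)) / net$N
}

#' Event-based controller specification
#'
#' A fixed control waveform replayed whenever the population mean voltage
#' crosses `threshold` upward. While a cycle is active further crossings are
#' ignored; the controller re-arms as soon as the cycle ends.
#'
#' @param waveform an `hh_waveform` (or data.frame with columns t, u)
#'   sampled on the SDE grid.
#' @param threshold mean-voltage trigger, mV.
#' @param dt SDE step the waveform is sampled on, ms.
#' @return an object of class `hh_event_controller` with fields
#'   `threshold`, `u` (per-step control values), `dt`, `cycle_ms`.
#' @export
event_controller <- function(waveform, threshold = -20, dt = attr(waveform, "dt")) {
  if (is.null(dt)) dt <- 0.005
  u <- waveform$u
  stopifnot(length(u) > 0, all(is.finite(u)))
  structure(list(threshold = threshold, u = u, dt = dt,
                 cycle_ms = length(u) * dt),
            class = "hh_event_controller")
}

#' One controller update (reference state machine)
#'
#' Pure-R mirror of the compiled controller, exposed for testing the event
#' semantics: idle -> active on an upward crossing
#' (`V_bar_prev < threshold <= V_bar_now`); while active the stored waveform
#' is emitted step by step and crossings are ignored; after exactly one
#' cycle the controller returns to idle.
#'
#' @param ctrl an `hh_event_controller`.
#' @param state list(active, k, events) or `NULL` to initialize.
#' @param V_bar_now,V_bar_prev mean voltage at this and the previous step.
#' @param t current time, ms.
#' @return list(u, state).
#' @export
event_controller_step <- function(ctrl, state, V_bar_now, V_bar_prev, t) {
  if (is.null(state)) state <- list(active = FALSE, k = 0L, events = numeric(0))
  u <- 0
  if (!state$active && V_bar_prev < ctrl$threshold &&
      V_bar_now >= ctrl$threshold) {
    state$active <- TRUE
    state$k <- 0L
    state$events <- c(state$events, t)
  }
  if (state$active) {
    u <- ctrl$u[state$k + 1L]
    state$k <- state$k + 1L
    if (state$k >= length(ctrl$u)) {
      state$active <- FALSE
      state$k <- 0L
    }
  }
  list(u = u, state = state)
}

#' Simulate a coupled noisy population
#'
#' Honeycutt SRK2 integration of N electrotonically coupled neurons
#' (per-neuron i.i.d. noise streams split deterministically from
#' `seed`), with the shared event-based control input applied identically to
#' every voltage equation. Spikes are recorded as upward crossings of 0 mV
#' with a 1 ms refractory. All neurons start synchronized at the spike
#' point unless `z0` is given.
#'
#' @param net an `hh_network`.
#' @param controller an `hh_event_controller`, or `NULL` for no control.
#' @param T horizon, ms.
#' @param dt SDE step, ms (must match the controller waveform cadence).
#' @param D per-neuron noise intensity.
#' @param seed master integer seed.
#' @param params an `hh_params`.
#' @param z0 `c(V, n)` applied to every neuron, or an N x 2 matrix;
#'   default the spike point of the deterministic orbit.
#' @param z0_policy `"spike-point"` (synchronized) or `"phase-spread"`
#'   (states spread along one period of the orbit; diagnostics only).
#' @param record_every thin the stored mean-voltage/control record.
#' @param record_traces keep per-neuron V and n traces (memory!).
#' @return an object of class `hh_population_record`: list with `t`,
#'   `V_bar`, `u`, `cum_energy`, `energy`, `event_times`, `raster`
#'   (data.frame neuron, time), `V_end`, `n_end` and optionally `V_traces`,
#'   `n_traces`.
#' @export
simulate_population <- function(net, controller = NULL, T = 425, dt = 0.005,
                                D = 0, seed = 1, params = neuron_params(),
                                z0 = NULL,
                                z0_policy = c("spike-point", "phase-spread"),
                                record_every = 10L, record_traces = FALSE) {
  stopifnot(inherits(net, "hh_network"), T > 0, dt > 0, D >= 0)
  z0_policy <- match.arg(z0_policy)
  if (is.null(z0)) {
    orb <- find_period(params)
    if (z0_policy == "spike-point") {
      z0 <- matrix(orb$spike_point, net$N, 2, byrow = TRUE)
    } else {
      one <- integrate_neuron(params, orb$spike_point, T = orb$period,
                              dt = 0.001, D = 0)
      idx <- round(seq(1, nrow(one), length.out = net$N + 1))[seq_len(net$N)]
      z0 <- cbind(one$V[idx], one$n[idx])
    }
  } else if (!is.matrix(z0)) {
    z0 <- matrix(z0, net$N, 2, byrow = TRUE)
  }
  wave <- numeric(0); thr <- 0
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "hh_event_controller"))
    if (abs(controller$dt - dt) > 1e-9)
      stop("waveform cadence (dt = ", controller$dt,
           ") does not match the SDE step (", dt, ")")
    wave <- controller$u; thr <- controller$threshold
  }
  rec <- cpp_simulate_population(z0[, 1], z0[, 2], par_vec(params),
                                 net$alpha, T, dt, D, seed, wave, thr,
                                 as.integer(record_every), record_traces,
                                 0, 1)
  out <- list(t = rec$t, V_bar = rec$V_bar, u = rec$u,
              cum_energy = rec$cum_energy, energy = rec$energy,
              event_times = rec$event_times,
              raster = data.frame(neuron = rec$spike_neuron,
                                  time = rec$spike_time),
              V_end = rec$V_end, n_end = rec$n_end,
              N = net$N, D = D, dt = dt, seed = seed,
              cycle_ms = if (length(wave)) length(wave) * dt else NA_real_)
  if (record_traces) {
    out$V_traces <- rec$V_traces
    out$n_traces <- rec$n_traces
  }
  structure(out, class = "hh_population_record")
}

#' @export
print.hh_population_record <- function(x, ...) {
  cat(sprintf("Population record: N = %d, %.0f ms, D = %g (seed %s)\n",
              x$N, max(x$t), x$D, format(x$seed)))
  cat(sprintf("  %d control events, energy %.2f (uA/uF)^2 ms, %d spikes\n",
              length(x$event_times), x$energy, nrow(x$raster)))
  invisible(x)
}

#' @export
plot.hh_population_record <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t, x$V_bar, type = "l", xlab = "t (ms)", ylab = "mean V (mV)", ...)
  abline(h = -20, lty = 3)
  if (length(x$event_times))
    points(x$event_times, rep(-20, length(x$event_times)), pch = 4)
  plot(x$raster$time, x$raster$neuron, pch = ".", xlab = "t (ms)",
       ylab = "neuron", ...)
  invisible(x)
}

#' Export a spike raster to CSV
#'
#' Columns `neuron_id`, `spike_time_ms`.
#' @param record an `hh_population_record`.
#' @param path output file.
#' @export
write_raster_csv <- function(record, path) {
  write.csv(data.frame(neuron_id = record$raster$neuron,
                       spike_time_ms = record$raster$time),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a coupling matrix to CSV
#' @param net an `hh_network`.
#' @param path output file.
#' @export
write_network_csv <- function(net, path) {
  write.csv(net$alpha, path, row.names = FALSE)
  invisible(path)
}
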