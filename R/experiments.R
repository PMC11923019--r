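#' Default experiment plan
#'
#' The five paired noise/coupling conditions used throughout the population
#' study, with the event-based horizon.
#'
#' @param n_realizations noise realizations per condition.
#' @param T horizon, ms.
#' @param master_seed every run's seed is derived from this plus indices.
#' @return list with `pairs` (data.frame D, alpha_bar), `T`,
#'   `n_realizations`, `master_seed`.
#' @export
experiment_plan <- function(n_realizations = 100, T = 425, master_seed = 1) {
  list(pairs = data.frame(D = c(0.5, 1, 5, 10, 15),
                          alpha_bar = c(0.05, 0.1, 0.15, 0.2, 0.25)),
       T = T, n_realizations = n_realizations, master_seed = master_seed)
}

# realization seeds: decorrelated downstream by counter-based splitting,
# so a simple affine map is enough (kept below 2^31)
realization_seed <- function(master, index) {
  (as.numeric(master) * 1000 + index) %% 2147483647
}

#' Compare single-neuron control strategies under noise
#'
#' Monte Carlo comparison of the three evaluation strategies at one noise
#' level: u* (stochastic value function on the stochastic trajectory),
#' u0* (deterministic value function on the stochastic trajectory), and
#' u-tilde* (stochastic value function on the deterministic trajectory,
#' noise-independent). Reports per-realization energies, end-point costs and
#' total costs, ensemble-mean control input over time, and mean
#' cumulative energy \eqn{\langle\int u^2 dt\rangle} (which differs from
#' \eqn{\int \langle u\rangle^2 dt} by Jensen's inequality).
#'
#' @param vf_stoch value function solved at `D_sim`.
#' @param vf_det value function solved at D = 0.
#' @param D_sim noise intensity of the simulated trajectories.
#' @param n number of realizations.
#' @param dt SDE step, ms.
#' @param z0 initial state (default: spike point, computed once).
#' @param master_seed seed; realization r uses a seed derived from it.
#' @return list with components `u_star`, `u0_star` (each holding `energy`,
#'   `endpoint`, `total`, `mean_u`, `mean_cum_energy`), `u_tilde`
#'   (waveform energy and trace), `t` (step times), `D`, `n`.
#' @export
single_neuron_comparison <- function(vf_stoch, vf_det, D_sim, n = 500,
                                     dt = 0.005, z0 = NULL, master_seed = 1) {
  if (is.null(z0)) z0 <- find_period(vf_stoch$params)$spike_point
  pol_s <- hh_policy(vf_stoch, "stochastic-on-stochastic")
  pol_0 <- hh_policy(vf_det, "deterministic-on-stochastic")
  pol_t <- hh_policy(vf_stoch, "stochastic-on-deterministic")

  run_ensemble <- function(pol, tag) {
    energy <- endpoint <- total <- numeric(n)
    usum <- esum <- NULL
    for (r in seq_len(n)) {
      run <- run_single_neuron(pol, D_sim = D_sim, z0 = z0, dt = dt,
                               seed = realization_seed(master_seed, r))
      energy[r] <- run$energy
      endpoint[r] <- run$endpoint_cost
      total[r] <- run$total_cost
      u <- run$trajectory$u[-1]
      ce <- run$trajectory$cum_energy[-1]
      if (is.null(usum)) { usum <- u; esum <- ce }
      else { usum <- usum + u; esum <- esum + ce }
    }
    list(energy = energy, endpoint = endpoint, total = total,
         mean_u = usum / n, mean_cum_energy = esum / n, strategy = tag)
  }
  us <- run_ensemble(pol_s, "u*")
  u0 <- run_ensemble(pol_0, "u0*")
  det <- run_single_neuron(pol_t, D_sim = 0, z0 = z0, dt = dt)
  list(u_star = us, u0_star = u0,
       u_tilde = list(energy = det$energy,
                      u = det$trajectory$u[-1],
                      cum_energy = det$trajectory$cum_energy[-1],
                      endpoint = det$endpoint_cost,
                      total = det$total_cost),
       t = det$trajectory$t[-1], D = D_sim, n = n)
}

#' Population energy comparison for two control waveforms
#'
#' Event-based runs of the homogeneous (or other) network at one
#' (D, alpha_bar) condition, repeated over noise realizations for each
#' waveform. Returns the time-resolved ensemble mean and variance of
#' cumulative energy and the per-realization final energies.
#'
#' @param wave_stoch,wave_det `hh_waveform`s (stochastic and deterministic
#'   policies).
#' @param D noise intensity.
#' @param alpha_bar mean coupling strength.
#' @param n_realizations realizations per waveform.
#' @param T horizon, ms.
#' @param kind network kind.
#' @param N network size.
#' @param dt SDE step, ms.
#' @param master_seed seed; the network uses it directly, realization r a
#'   derived seed.
#' @param threshold event trigger on the mean voltage, mV.
#' @return list with `stochastic` and `deterministic` components, each
#'   holding `final_energy` (vector), `t`, `mean_cum_energy`,
#'   `var_cum_energy`, `n_events`.
#' @export
population_energy_comparison <- function(wave_stoch, wave_det, D, alpha_bar,
                                         n_realizations = 20, T = 425,
                                         kind = "homogeneous", N = 100,
                                         dt = 0.005, master_seed = 1,
                                         threshold = -20) {
  net <- build_coupling(kind, N = N, alpha_bar = alpha_bar,
                        seed = master_seed)
  z0 <- find_period(neuron_params())$spike_point
  one <- function(wave, tag) {
    ctrl <- event_controller(wave, threshold = threshold, dt = dt)
    fe <- nev <- numeric(n_realizations)
    msum <- vsum <- NULL; tt <- NULL
    for (r in seq_len(n_realizations)) {
      rec <- simulate_population(net, ctrl, T = T, dt = dt, D = D,
                                 seed = realization_seed(master_seed, r),
                                 z0 = z0, record_every = 100L)
      fe[r] <- rec$energy
      nev[r] <- length(rec$event_times)
      if (is.null(msum)) { msum <- rec$cum_energy; vsum <- rec$cum_energy^2
                           tt <- rec$t }
      else { msum <- msum + rec$cum_energy; vsum <- vsum + rec$cum_energy^2 }
    }
    m <- msum / n_realizations
    list(final_energy = fe, t = tt, mean_cum_energy = m,
         var_cum_energy = pmax(vsum / n_realizations - m^2, 0),
         n_events = nev, strategy = tag)
  }
  list(stochastic = one(wave_stoch, "u_tilde*"),
       deterministic = one(wave_det, "u_d*"),
       D = D, alpha_bar = alpha_bar, kind = kind, n = n_realizations)
}

#' Energy robustness across network types
#'
#' Mean and standard deviation of the 425 ms cumulative control energy for
#' homogeneous, heterogeneous and sparse-heterogeneous networks at each
#' (D, alpha_bar) condition, under event-based control with the matching
#' stochastic-policy waveform.
#'
#' @param waveforms named list of `hh_waveform`s, one per noise level; names
#'   are the D values as strings (e.g. `"15"`).
#' @param pairs data.frame with columns `D`, `alpha_bar`.
#' @param kinds network kinds to include.
#' @param n_realizations realizations per cell.
#' @param T horizon, ms.
#' @param N network size.
#' @param dt SDE step, ms.
#' @param master_seed seed.
#' @return data.frame with columns `D`, `alpha_bar`, `kind`, `mean`, `sd`,
#'   `n`, plus attribute `energies` (list of per-realization vectors).
#' @export
robustness_table <- function(waveforms, pairs = experiment_plan()$pairs,
                             kinds = c("homogeneous", "heterogeneous",
                                       "sparse-heterogeneous"),
                             n_realizations = 20, T = 425, N = 100,
                             dt = 0.005, master_seed = 1) {
  rows <- list(); energies <- list()
  for (i in seq_len(nrow(pairs))) {
    D <- pairs$D[i]; ab <- pairs$alpha_bar[i]
    wv <- waveforms[[as.character(D)]]
    if (is.null(wv)) stop("no waveform supplied for D = ", D)
    ctrl <- event_controller(wv, dt = dt)
    z0 <- find_period(neuron_params())$spike_point
    for (kind in kinds) {
      net <- build_coupling(kind, N = N, alpha_bar = ab,
                            seed = master_seed + i)
      fe <- vapply(seq_len(n_realizations), function(r)
        simulate_population(net, ctrl, T = T, dt = dt, D = D,
                            seed = realization_seed(master_seed + i, r),
                            z0 = z0, record_every = 10000L)$energy,
        numeric(1))
      key <- sprintf("%s_%g", kind, D)
      energies[[key]] <- fe
      rows[[key]] <- data.frame(D = D, alpha_bar = ab, kind = kind,
                                mean = mean(fe), sd = sd(fe),
                                n = n_realizations)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "energies") <- energies
  out
}

#' Summary statistics of an energy sample
#'
#' Mean, n-1 standard deviation, median, quartiles (linear-interpolation
#' convention), whiskers at the most extreme points within 1.5 IQR of the
#' box, and the outliers beyond them.
#'
#' @param values numeric vector of per-realization energies.
#' @return an object of class `hh_energy_stats`.
#' @examples
#' summarize_energy(c(1, 2, 3, 4, 100))$outliers   # 100
#' @export
summarize_energy <- function(values) {
  if (length(values) == 0) stop("empty sample")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  structure(list(per_realization = values, n = length(values),
                 mean = mean(values), sd = if (length(values) > 1) sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = values[!inside]),
            class = "hh_energy_stats")
}

#' @export
print.hh_energy_stats <- function(x, ...) {
  cat(sprintf("Energy sample: n = %d, mean %.2f +/- %.2f (sd)\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  median %.2f, quartiles [%.2f, %.2f], whiskers [%.2f, %.2f], %d outlier(s)\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}
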