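test_that("coupling matrices honor kind, symmetry and zero diagonal", {
  net <- build_coupling("homogeneous", N = 4, alpha_bar = 0.25)
  expect_equal(diag(net$alpha), rep(0, 4))
  expect_true(all(net$alpha[upper.tri(net$alpha)] == 0.25))
  expect_identical(net$alpha, t(net$alpha))

  net <- build_coupling("heterogeneous", N = 100, alpha_bar = 0.2, seed = 3)
  off <- net$alpha[upper.tri(net$alpha)]
  se <- 0.2 * 0.2 / sqrt(length(off))
  expect_lt(abs(mean(off) - 0.2), 3 * se)
  expect_lt(abs(sd(off) - 0.04), 0.15 * 0.04)
  expect_identical(net$alpha, t(net$alpha))

  net <- build_coupling("sparse-heterogeneous", N = 100, alpha_bar = 0.2,
                        seed = 3)
  expect_equal(sum(net$alpha[upper.tri(net$alpha)] == 0), 990)
  expect_error(build_coupling("smallworld", N = 10, alpha_bar = 0.1))
})

test_that("coupling matrices regenerate bit-identically from a seed", {
  a <- build_coupling("sparse-heterogeneous", N = 30, alpha_bar = 0.1, seed = 7)
  b <- build_coupling("sparse-heterogeneous", N = 30, alpha_bar = 0.1, seed = 7)
  expect_identical(a$alpha, b$alpha)
})

test_that("the coupling drift is diffusive and conservative", {
  net <- build_coupling("homogeneous", N = 2, alpha_bar = 0.25)
  expect_equal(coupling_drift(c(0, -40), net), c(-5, 5))
  expect_equal(coupling_drift(c(-33, -33), net), c(0, 0))
  net0 <- build_coupling("homogeneous", N = 5, alpha_bar = 0)
  expect_equal(coupling_drift(c(1, 2, 3, 4, 5), net0), rep(0, 5))
  net <- build_coupling("homogeneous", N = 20, alpha_bar = 0.3)
  set.seed(2)
  expect_lt(abs(sum(coupling_drift(rnorm(20, -50, 20), net))), 1e-10)
})

test_that("the event controller replays one full cycle per upward crossing", {
  ctrl <- event_controller(data.frame(t = (0:9) * 0.005, u = 10:1),
                           threshold = -20, dt = 0.005)
  st <- NULL
  # mean voltage stays below threshold: no control at all
  for (k in 1:20) {
    out <- event_controller_step(ctrl, st, -40, -41, k * 0.005)
    st <- out$state
    expect_equal(out$u, 0)
  }
  expect_length(st$events, 0)

  # one crossing, then a second crossing while active: ignored
  vbar <- c(-30, -25, -19, -18, -30, -19, -15, -10, -5, -25, -30, -35, -40)
  st <- NULL; us <- numeric(0)
  for (k in 2:length(vbar)) {
    out <- event_controller_step(ctrl, st, vbar[k], vbar[k - 1], k * 0.005)
    st <- out$state
    us <- c(us, out$u)
  }
  # the crossing at step 3 starts the replay; the re-crossing at step 6
  # (after dipping below) falls inside the active window and is ignored
  expect_equal(us, c(0, 10:1, 0))
  expect_length(st$events, 1)
})

test_that("the controller re-arms after exactly one cycle", {
  ctrl <- event_controller(data.frame(t = (0:3) * 0.005, u = c(5, 4, 3, 2)),
                           threshold = -20, dt = 0.005)
  # crossing, full 4-step cycle, dip below, crossing again -> second replay
  vbar <- c(-30, -10, -10, -10, -10, -30, -10, -10, -10, -10)
  st <- NULL; us <- numeric(0)
  for (k in 2:length(vbar)) {
    out <- event_controller_step(ctrl, st, vbar[k], vbar[k - 1], k * 0.005)
    st <- out$state
    us <- c(us, out$u)
  }
  expect_equal(us, c(5, 4, 3, 2, 0, 5, 4, 3, 2))
  expect_length(st$events, 2)
})

test_that("synchrony is invariant for identical deterministic neurons", {
  net <- build_coupling("homogeneous", N = 5, alpha_bar = 0.3)
  rec <- simulate_population(net, NULL, T = 30, dt = 0.005, D = 0, seed = 1,
                             record_every = 20L, record_traces = TRUE)
  spread <- apply(rec$V_traces, 1, function(v) max(abs(v - v[1])))
  expect_lt(max(spread), 1e-10)
})

test_that("a lone uncoupled neuron reduces to the single-neuron integrator", {
  net <- build_coupling("homogeneous", N = 2, alpha_bar = 0)
  net$alpha <- net$alpha[1, 1, drop = FALSE]; net$N <- 1
  rec <- simulate_population(net, NULL, T = 50, dt = 0.005, D = 15, seed = 4,
                             z0 = c(-60, 0.4), record_every = 1L,
                             record_traces = TRUE)
  tr <- integrate_neuron(neuron_params(), c(-60, 0.4), T = 50, dt = 0.005,
                         D = 15, seed = 4)
  expect_identical(as.numeric(rec$V_traces[, 1]), tr$V)
  expect_identical(as.numeric(rec$n_traces[, 1]), tr$n)
})

test_that("control is zero outside event windows and bounded within", {
  w <- cached_waveform(48, 5)
  net <- build_coupling("homogeneous", N = 5, alpha_bar = 0.15)
  rec <- simulate_population(net, event_controller(w), T = 60, dt = 0.005,
                             D = 10, seed = 2, record_every = 1L)
  expect_gt(length(rec$event_times), 0)
  cyc <- rec$cycle_ms
  expect_equal(cyc, 7)
  active <- rep(FALSE, length(rec$t))
  for (te in rec$event_times)
    active <- active | (rec$t >= te & rec$t < te + cyc + 0.005 / 2)
  expect_true(all(rec$u[!active] == 0))
  # per-event energy bounded by u_max^2 * 7 = 700
  for (te in rec$event_times) {
    i0 <- which.min(abs(rec$t - te))
    i1 <- which.min(abs(rec$t - (te + cyc)))
    expect_lte(rec$cum_energy[i1] - rec$cum_energy[i0], 700 + 1e-9)
  }
  # events are separated by at least one full cycle
  if (length(rec$event_times) > 1)
    expect_true(all(diff(rec$event_times) >= cyc - 1e-9))
})

test_that("mean voltage equals the arithmetic mean of the traces", {
  net <- build_coupling("heterogeneous", N = 4, alpha_bar = 0.1, seed = 5)
  rec <- simulate_population(net, NULL, T = 10, dt = 0.005, D = 5, seed = 6,
                             record_every = 10L, record_traces = TRUE)
  expect_lt(max(abs(rec$V_bar - rowMeans(rec$V_traces))), 1e-12)
})

test_that("an unreachable threshold yields zero events and zero energy", {
  w <- cached_waveform(48, 5)
  ctrl <- event_controller(w, threshold = 100)
  net <- build_coupling("homogeneous", N = 3, alpha_bar = 0.2)
  rec <- simulate_population(net, ctrl, T = 30, dt = 0.005, D = 5, seed = 3)
  expect_length(rec$event_times, 0)
  expect_equal(rec$energy, 0)
})
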