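# a hand-built value function (analytic slices) for interpolation tests
fake_vf <- function(fun, nx = 21, ny = 21, ntimes = 3, T_end = 7,
                    u_max = 10) {
  g <- grid_spec(x_min = -1, x_max = 1, y_min = -1, y_max = 1,
                 nx = nx, ny = ny)
  times <- seq(0, T_end, length.out = ntimes)
  sl <- array(0, c(nx, ny, ntimes))
  for (k in seq_len(ntimes)) sl[, , k] <- outer(g$x, g$y, fun)
  structure(list(slices = sl, times = times, grid = g,
                 cost = cost_spec(target = c(0, 0)), params = neuron_params(),
                 D = 0, u_max = u_max, dt_pde = NA, n_steps = NA),
            class = "hh_value_function")
}

test_that("the saturated control law follows the gradient and clips", {
  expect_equal(optimal_control_from_gradient(0, 10, 100), 0)
  expect_equal(optimal_control_from_gradient(2000, 10, 100), -10)
  expect_equal(optimal_control_from_gradient(2000 + 1e-9, 10, 100), -10)
  expect_equal(optimal_control_from_gradient(-500, 10, 100), 2.5)
  # continuity at the switch (the linear branch has slope 1/(2K), so the
  # probe must sit within 2K * 1e-12 of the switch)
  eps <- 1e-10
  expect_lt(abs(optimal_control_from_gradient(2000 - eps, 10, 100) -
                  optimal_control_from_gradient(2000 + eps, 10, 100)), 1e-12)
})

test_that("bilinear interpolation is exact at nodes and for bilinear data", {
  g <- grid_spec(x_min = 0, x_max = 1, y_min = 0, y_max = 1,
                 nx = 17, ny = 17)
  f <- outer(g$x, g$y, function(x, y) 2 + 3 * x - y + 0.5 * x * y)
  expect_equal(bilinear_interpolate(f, g, g$x[5], g$y[9]), f[5, 9])
  cc <- bilinear_interpolate(f, g, g$x[3] + g$dx / 2, g$y[3] + g$dy / 2)
  expect_equal(cc, mean(f[3:4, 3:4]))
  set.seed(5)
  x <- runif(200); y <- runif(200)
  expect_lt(max(abs(bilinear_interpolate(f, g, x, y) -
                      (2 + 3 * x - y + 0.5 * x * y))), 1e-12)
})

test_that("feedback control matches the gradient map on analytic fields", {
  vf <- fake_vf(function(x, y) 0 * x + 7)        # constant field
  pol <- hh_policy(vf)
  expect_equal(feedback_control(pol, 0.3, -0.2, 1), 0)
  vf <- fake_vf(function(x, y) 400 * x)          # V_x = 400 -> u = -2
  pol <- hh_policy(vf)
  set.seed(8)
  xs <- runif(50, -0.9, 0.9); ys <- runif(50, -0.9, 0.9)
  expect_equal(feedback_control(pol, xs, ys, 3.5), rep(-2, 50),
               tolerance = 1e-12)
  expect_error(feedback_control(pol, 0, 0, 7.5), "outside")
})

test_that("emitted controls never exceed the bound", {
  vf <- fake_vf(function(x, y) 5000 * sin(8 * x) * cos(5 * y))
  pol <- hh_policy(vf)
  set.seed(13)
  u <- feedback_control(pol, runif(1e4, -1, 1), runif(1e4, -1, 1), 2)
  expect_true(all(abs(u) <= 10))
})

test_that("on-deterministic strategies are seed-independent", {
  pol <- hh_policy(cached_vf(48, 5), "stochastic-on-deterministic")
  z0 <- cached_orbit()$spike_point
  a <- run_single_neuron(pol, D_sim = 0, z0 = z0, seed = 1)
  b <- run_single_neuron(pol, D_sim = 0, z0 = z0, seed = 2024)
  expect_identical(a$trajectory$V, b$trajectory$V)
  expect_identical(a$energy, b$energy)
  expect_error(run_single_neuron(pol, D_sim = 5, z0 = z0), "must be 0")
})

test_that("all strategies coincide when D = 0 everywhere", {
  vf0 <- cached_vf(48, 0)
  z0 <- cached_orbit()$spike_point
  a <- run_single_neuron(hh_policy(vf0, "stochastic-on-stochastic"),
                         D_sim = 0, z0 = z0)
  b <- run_single_neuron(hh_policy(vf0, "deterministic-on-deterministic"),
                         D_sim = 0, z0 = z0)
  expect_identical(a$trajectory$V, b$trajectory$V)
  expect_identical(a$energy, b$energy)
})

test_that("the closed loop lands near the phaseless set", {
  fp <- cached_fp()
  for (D in c(0, 5)) {
    pol <- hh_policy(cached_vf(48, D), "stochastic-on-deterministic")
    run <- run_single_neuron(pol, D_sim = 0,
                             z0 = cached_orbit()$spike_point)
    d <- sqrt((run$z_end[1] / 100 - fp$V / 100)^2 +
                (run$z_end[2] - fp$n)^2)
    expect_lt(d, 0.05)
  }
})

test_that("waveforms round-trip through CSV with their cadence checked", {
  w <- cached_waveform(48, 5)
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  w2 <- read_waveform_csv(path, dt = 0.005)
  expect_equal(w2$u, w$u)
  expect_error(read_waveform_csv(path, dt = 0.01), "cadence")
})
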