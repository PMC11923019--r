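test_that("the terminal cost is zero at the target and Gaussian around it", {
  cost <- cost_spec()
  tg <- cost$target
  expect_equal(terminal_cost(tg[1], tg[2], cost), 0)
  sx <- sqrt(cost$sigma_x2)
  expect_equal(terminal_cost(tg[1] + sx, tg[2], cost),
               1000 * (1 - exp(-1)), tolerance = 1e-12)
  d <- 0.017
  expect_equal(terminal_cost(tg[1] + d, tg[2], cost),
               terminal_cost(tg[1] - d, tg[2], cost))
})

test_that("WENO5 derivatives are exact on constant and linear data", {
  x <- seq(0, 1, length.out = 41)
  d <- weno5_derivatives(rep(3.2, 41), x[2] - x[1])
  expect_lt(max(abs(d$left)), 1e-12)
  expect_lt(max(abs(d$right)), 1e-12)
  d <- weno5_derivatives(2 - 1.7 * x, x[2] - x[1])
  expect_lt(max(abs(d$left + 1.7)), 1e-12)
  expect_lt(max(abs(d$right + 1.7)), 1e-12)
  expect_error(weno5_derivatives(1:5, 0.1), "at least 7")
})

test_that("WENO5 converges at high order on smooth data", {
  # quartic on [0,1]; compare interior nodes (boundary stencils use
  # extrapolated ghosts)
  err <- function(n) {
    x <- seq(0, 1, length.out = n)
    h <- x[2] - x[1]
    f <- x^4 - 0.5 * x^2
    d <- weno5_derivatives(f, h)
    ex <- 4 * x^3 - x
    i <- 5:(n - 4)
    max(abs(d$left[i] - ex[i]), abs(d$right[i] - ex[i]))
  }
  expect_gt(err(81) / err(161), 16)
})

test_that("the optimal Hamiltonian has continuous saturation branches", {
  expect_equal(hamiltonian_optimal(0.3, -0.2, 0, 0, 10, 100), 0)
  # at the switch |p_x| = 2 K u_max both expressions coincide
  px <- 2 * 100 * 10
  h1 <- 0.5 * px - px^2 / (4 * 100^2)
  h2 <- 0.5 * px + 10^2 - px * 10 / 100
  expect_equal(h1, h2)
  expect_equal(hamiltonian_optimal(0.5, 0, px, 0, 10, 100), h1)
  expect_equal(hamiltonian_optimal(0.5, 0, px + 1e-9, 0, 10, 100), h1,
               tolerance = 1e-6)
  # direct evaluation on the interior branch with F = 0
  expect_equal(hamiltonian_optimal(0, 0, -500, 0, 10, 100),
               -500^2 / 40000)
})

test_that("the LLF flux reduces to the Hamiltonian and is linear in the jumps", {
  h0 <- llf_numerical_hamiltonian(30, 30, -5, -5, 0.4, -0.1, 2, 1, 10, 100)
  expect_equal(h0, hamiltonian_optimal(0.4, -0.1, 30, -5, 10, 100))
  h1 <- llf_numerical_hamiltonian(20, 40, -5, -5, 0.4, -0.1, 2, 1, 10, 100)
  h2 <- llf_numerical_hamiltonian(20, 40, -5, -5, 0.4, -0.1, 4, 1, 10, 100)
  expect_equal(h2 - h1, -(4 - 2) / 2 * (40 - 20))
})

test_that("the solver transports a profile at the advection speed", {
  # V_t + a V_x = 0 via F = (a, 0), u_max = 0: V(x, 0) = g(x + a T)
  a <- 1; Tend <- 0.5
  run <- function(nx) {
    g <- grid_spec(x_min = -2, x_max = 2, y_min = 0, y_max = 1,
                   nx = nx, ny = 16)
    Fx <- matrix(a, g$nx, g$ny)
    Fy <- matrix(0, g$nx, g$ny)
    prof <- function(x) exp(-((x - 0.5) / 0.25)^2)
    term <- matrix(prof(g$x), g$nx, g$ny)
    sol <- solve_hjb_grid(Fx, Fy, term, g, Tend, u_max = 0, K = 1,
                          store_dt = Tend)
    v0 <- sol$slices[, 8, 1]
    max(abs(v0 - prof(g$x + a * Tend)))
  }
  e1 <- run(101); e2 <- run(401)
  expect_lt(e2, 0.05)
  expect_gt(e1 / e2, 3)
})

test_that("the implicit diffusion step is exact for D = 0 and constants", {
  sl <- matrix(rnorm(30 * 20), 30, 20)
  expect_identical(implicit_diffusion_step(sl, 0, 100, 0.01, 0.1), sl)
  cs <- matrix(5.5, 30, 20)
  out <- implicit_diffusion_step(cs, 10, 100, 0.01, 0.1)
  expect_lt(max(abs(out - 5.5)), 1e-12)
})

test_that("repeated implicit diffusion matches the heat kernel", {
  # d/dt V = nu V_xx with nu = D/K^2 = 1: a Gaussian of variance s^2 widens
  # to s^2 + 2 nu t
  nx <- 401
  x <- seq(-6, 6, length.out = nx)
  dx <- x[2] - x[1]
  s0 <- 0.6
  sl <- matrix(exp(-x^2 / (2 * s0^2)), nx, 4)
  dt <- 5e-5; nstep <- 400
  for (k in seq_len(nstep)) sl <- implicit_diffusion_step(sl, 1, 1, dt, dx)
  tt <- dt * nstep
  s2 <- s0^2 + 2 * tt
  exact <- s0 / sqrt(s2) * exp(-x^2 / (2 * s2))
  expect_lt(max(abs(sl[, 2] - exact)) / max(exact), 1e-3)
})

test_that("the LQ problem matches the Riccati oracle", {
  # dz = (a z + u) dt, terminal cost z^2, effectively unbounded control
  # (the bound is never active: |p_x| <= 2 here, far from 2 K u_max):
  # V(z, t) = P(t) z^2 with -dP/dt = 2 a P - P^2, P(T) = 1
  a <- -0.5; Tend <- 1
  g <- grid_spec(x_min = -1, x_max = 1, y_min = -1, y_max = 1,
                 nx = 101, ny = 16)
  Fx <- matrix(a * g$x, g$nx, g$ny)
  Fy <- matrix(0, g$nx, g$ny)
  term <- matrix(g$x^2, g$nx, g$ny)
  sol <- solve_hjb_grid(Fx, Fy, term, g, Tend, u_max = 5, K = 1,
                        store_dt = Tend)
  # Riccati integrated backward with classical RK4
  P <- 1; nst <- 4000; h <- Tend / nst
  f <- function(P) 2 * a * P - P^2   # dP/ds in reverse time s = T - t
  for (k in seq_len(nst)) {
    k1 <- f(P); k2 <- f(P + h / 2 * k1); k3 <- f(P + h / 2 * k2)
    k4 <- f(P + h * k3)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  i <- which(abs(g$x) <= 0.6)
  v0 <- sol$slices[i, 8, 1]
  exact <- P * g$x[i]^2
  expect_lt(max(abs(v0 - exact)) / max(exact), 1e-2)
})

test_that("the terminal slice is the end-point cost, exactly", {
  vf <- cached_vf(48, 5)
  term <- outer(vf$grid$x, vf$grid$y, terminal_cost, cost = vf$cost)
  nt <- length(vf$times)
  expect_identical(vf$slices[, , nt], term)
  expect_equal(vf$times[nt], vf$cost$T_end)
})

test_that("the value function is bounded by the do-nothing cost", {
  vf <- cached_vf(48, 5)
  expect_gt(min(vf$slices), -1e-6 * 1000)
  expect_lt(max(vf$slices), 1000 * (1 + 1e-6))
})

test_that("D = 0 runs are deterministic and the diffusion step is inert", {
  vf1 <- cached_vf(48, 0)
  vf2 <- solve_hjb(grid = grid_spec(nx = 48, ny = 48), D = 0)
  expect_identical(vf1$slices, vf2$slices)
  # applying the diffusion operator with D = 0 changes nothing, bitwise
  sl <- vf1$slices[, , 1]
  expect_identical(implicit_diffusion_step(sl, 0, 100, vf1$dt_pde,
                                           vf1$grid$dx), sl)
})

test_that("noise smooths the value function: |V_x| shrinks with D", {
  vmax <- vapply(c(0, 1, 15), function(D) {
    pol <- hh_policy(cached_vf(48, D))
    max(abs(pol$Vx[, , 1]))
  }, numeric(1))
  expect_lt(vmax[2], vmax[1] * 1.01)
  expect_lt(vmax[3], vmax[2] * 1.01)
})
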