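test_that("gating rates evaluate their removable singularities by the limit", {
  g <- gating_rates(-40)
  expect_equal(g$a_m, 1.0)
  g <- gating_rates(-55)
  expect_equal(g$a_n, 0.1)
  g <- gating_rates(-65)
  expect_equal(g$b_m, 4.0)
  expect_equal(g$b_n, 0.125)
  expect_error(gating_rates(NaN), "non-finite")
})

test_that("gating rates are continuous across the singularity branch", {
  # just outside the |V - V0| < 1e-7 limit branch the exact formula must
  # agree with the analytic limit to within the local slope (about d/20)
  for (V0 in c(-40, -55)) {
    lim <- gating_rates(V0)
    lo <- gating_rates(V0 - 1.1e-7)
    hi <- gating_rates(V0 + 1.1e-7)
    comp <- if (V0 == -40) "a_m" else "a_n"
    expect_lt(abs(lo[[comp]] - lim[[comp]]), 1e-8)
    expect_lt(abs(hi[[comp]] - lim[[comp]]), 1e-8)
    # and inside the branch the limit value is returned exactly
    expect_identical(gating_rates(V0 + 1e-8)[[comp]], lim[[comp]])
  }
})

test_that("scaled and physical vector fields satisfy the scaling identity", {
  p <- neuron_params()
  set.seed(11)
  V <- runif(1000, -80, 45); n <- runif(1000, 0, 1)
  phys <- rhs_physical(V, n, p)
  scl <- rhs_scaled(V / p$K, n, p)
  expect_lt(max(abs(p$K * scl$dx - phys$dV)), 1e-12)
  expect_lt(max(abs(scl$dy - phys$dn)), 1e-12)
})

test_that("control enters the voltage equation additively through B", {
  p <- neuron_params()
  r0 <- rhs_physical(-30, 0.5, p, u = 0)
  r1 <- rhs_physical(-30, 0.5, p, u = 3.7)
  expect_equal(r1$dV - r0$dV, 3.7)
  expect_equal(r1$dn, r0$dn)
  # scaled: a u_max shift in dx of u_max / K
  s0 <- rhs_scaled(-0.3, 0.5, p, u = 0)
  s1 <- rhs_scaled(-0.3, 0.5, p, u = 10)
  expect_equal(s1$dx - s0$dx, 10 / p$K)
})

test_that("the sodium term vanishes when n = 0.8", {
  p <- neuron_params()
  # at n = 0.8 the (0.8 - n) factor kills the Na current: f_V must be
  # unchanged when gNa is altered
  p2 <- p; p2$gNa <- 999
  expect_equal(rhs_physical(-20, 0.8, p)$dV, rhs_physical(-20, 0.8, p2)$dV)
})

test_that("the unstable fixed point sits at (-59.6, 0.403)", {
  fp <- cached_fp()
  expect_equal(signif(fp$V, 3), -59.6)
  expect_equal(signif(fp$n, 3), 0.403)
  expect_lt(fp$residual, 1e-10)
  r <- rhs_physical(fp$V, fp$n)
  expect_lt(sqrt(r$dV^2 + r$dn^2), 1e-10)
})

test_that("the fixed point at I_b = 10 is unstable (independent Jacobian)", {
  fp <- cached_fp()
  # independent check: fresh finite-difference Jacobian at a different step
  h <- 1e-5
  f <- function(z) {
    r <- rhs_physical(z[1], z[2])
    c(r$dV, r$dn)
  }
  z <- c(fp$V, fp$n)
  J <- cbind((f(z + c(h, 0)) - f(z - c(h, 0))) / (2 * h),
             (f(z + c(0, h)) - f(z - c(0, h))) / (2 * h))
  ev <- eigen(J, only.values = TRUE)$values
  expect_true(all(Re(ev) > 0))
  expect_true(fp$unstable)
})

test_that("the spiking period is 11.85 ms and converges under refinement", {
  orb <- cached_orbit()
  expect_lt(abs(orb$period - 11.85), 0.02)
  orb2 <- find_period(dt = 0.0005)
  expect_lt(abs(orb2$period - orb$period), 1e-3)
  # spike point lies on the converged orbit at the voltage maximum
  expect_gt(orb$spike_point[1], 40)
})

test_that("the excitable regime raises a no-oscillation error", {
  p <- neuron_params(I_b = 5)
  expect_error(find_period(p), "no sustained oscillation")
})

test_that("the bistable band has a stable fixed point and a sustained orbit", {
  p <- neuron_params(I_b = 7)
  fp <- find_fixed_point(p)
  expect_lt(max(Re(fp$eigenvalues)), 0)
  expect_true(hhsoc:::sustained_oscillation(p, cached_orbit()$spike_point))
})

test_that("guesses outside the physiological box are rejected", {
  expect_error(find_fixed_point(guess = c(-200, 0.4)))
  expect_error(find_fixed_point(guess = c(-59, 1.5)))
})
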