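test_that("existence bound for the synchronized duplex state", {
  expect_equal(round(sync_existence_bound(-0.28 * pi), 3), 0.385)
  expect_equal(sync_existence_bound(0), 0)
  expect_equal(sync_existence_bound(pi / 2), 0.5)
  expect_equal(sync_existence_bound(0.28 * pi), sync_existence_bound(-0.28 * pi))
})

test_that("interlayer phase lag solves the frequency-matching condition", {
  expect_equal(round(sync_phase_lag(-0.28 * pi, 1) / pi, 3), 0.126)
  expect_equal(sync_phase_lag(0, 1), 0)
  expect_equal(sync_phase_lag(-0.28 * pi, 0.5) / pi, 0.28, tolerance = 1e-3)
  expect_error(sync_phase_lag(-0.28 * pi, 0.3), "no synchronized state")
  # returned lag satisfies the defining sine condition
  for (a0 in c(-0.28, -0.1, 0.35) * pi) for (sg in c(0.6, 1, 2)) {
    d <- sync_phase_lag(a0, sg)
    expect_equal(sin(d), -sin(a0) / (2 * sg), tolerance = 1e-12)
  }
})

test_that("reduced dynamics on the synchronized manifold", {
  expect_equal(reduced_sync_rhs(0.4, 0.4, alpha0 = 0, beta = 0.7, sigma = 1),
               c(0, 0))
  d <- sync_phase_lag(-0.28 * pi, 1)
  v <- reduced_sync_rhs(d, 0, alpha0 = -0.28 * pi, beta = 0.5 * pi, sigma = 1)
  expect_equal(v[1], v[2], tolerance = 1e-12)   # locked frequencies
  expect_equal(v[1], 1.15577, tolerance = 1e-5)
  # sum of components is independent of the lag (sigma terms cancel)
  for (dphi in c(0, 0.3, 1.2, -0.7)) {
    v <- reduced_sync_rhs(dphi, 0, alpha0 = -0.28 * pi, beta = 0.6 * pi,
                          sigma = 1.3)
    expect_equal(sum(v), -(1 + 2 * sin(0.6 * pi)) * sin(-0.28 * pi),
                 tolerance = 1e-12)
  }
})

test_that("common locked frequency follows from the reduced equations", {
  expect_equal(sync_common_frequency(0, 0.6, 1), 0)
  expect_equal(sync_common_frequency(-0.28 * pi, 0.5 * pi, 1), 1.15577,
               tolerance = 1e-5)
  expect_equal(sync_common_frequency(-0.28 * pi, pi, 1), 0.38526,
               tolerance = 1e-5)
  expect_error(sync_common_frequency(-0.28 * pi, 0.5 * pi, 0.2),
               "no synchronized state")
})

test_that("exponential kernel: constant and drifting phase differences", {
  # constant difference d: kernel integrates to -sin(d - beta)
  expect_equal(kappa_kernel(function(u) 0, eps = 0.3, beta = 0.5 * pi,
                            t = 10), 1, tolerance = 1e-8)
  expect_equal(kappa_kernel(function(u) 0.9, eps = 0.1, beta = 0.2,
                            t = 5), -sin(0.9 - 0.2), tolerance = 1e-8)
  # uniform drift: closed-form convolution of the exponential with the sine
  eps <- 0.3; Om <- 1; t <- 100; beta <- 0.5 * pi
  A <- Om * t - beta
  closed <- -eps * (eps * sin(A) - Om * cos(A)) / (eps^2 + Om^2)
  expect_equal(kappa_kernel(function(u) Om * u, eps, beta, t), closed,
               tolerance = 1e-8)
})

test_that("kernel representation agrees with the adaptation ODE", {
  # prescribe a non-trivial phase-difference history; the kernel value and
  # the integrated ODE (started from the matching initial condition) agree
  hist <- function(u) 0.5 * u + 0.3 * sin(0.2 * u)
  eps <- 0.3; beta <- 0.4 * pi
  k0 <- -sin(hist(0) - beta)
  sol <- deSolve::ode(y = c(k = k0), times = seq(0, 40, 0.1),
                      func = function(t, y, p)
                        list(-eps * (y + sin(hist(t) - beta))),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  for (t_eval in c(10, 25, 40)) {
    ode_val <- sol[sol[, 1] == t_eval, 2]
    expect_equal(kappa_kernel(hist, eps, beta, t_eval), unname(ode_val),
                 tolerance = 1e-6)
  }
})

test_that("reduced two-phase system converges to the analytic lock", {
  # random parameter sets above the existence bound: integrating the
  # reduced dynamics reaches the principal lag and the common frequency
  set.seed(77)
  n_ok <- 0
  while (n_ok < 20) {
    a0 <- runif(1, -0.45 * pi, 0.45 * pi)
    beta <- runif(1, 0, pi)
    sg <- runif(1, sync_existence_bound(a0) * 1.1 + 0.05, 2)
    rhs <- function(t, y, p)
      list(reduced_sync_rhs(y[1], y[2], a0, beta, sg))
    y0 <- c(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
    t_end <- 400 / sg
    sol <- deSolve::ode(y = y0, times = c(0, t_end - 1, t_end), func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
    lag <- unname(sol[3, 2] - sol[3, 3])
    expect_equal(sin(lag), sin(sync_phase_lag(a0, sg)), tolerance = 1e-6)
    expect_equal(cos(lag) > 0, TRUE)  # stable principal branch
    freq <- unname(sol[3, 2] - sol[2, 2]) / 1
    expect_equal(freq, sync_common_frequency(a0, beta, sg), tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
})
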