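test_that("mean phase velocities are endpoint differences over the window", {
  tr <- make_fixture("in-phase", N = 8, omega = 1.7)
  v <- mean_phase_velocities(tr, 50)
  expect_equal(v$v1, rep(1.7, 8))
  expect_equal(v$omega1, 1.7)
  tr0 <- make_fixture("in-phase", N = 8, omega = 0)
  expect_equal(mean_phase_velocities(tr0, 50)$v2, rep(0, 8))
  expect_error(mean_phase_velocities(tr, 1e4), "longer than")
})

test_that("two-cluster synthetic trajectory reproduces the arithmetic oracle", {
  tr <- make_fixture("two-frequency-cluster", N = 200,
                     sizes = c(150, 50), freqs = c(1, 0.8))
  v <- mean_phase_velocities(tr, 50)
  expect_equal(v$omega1, 0.95)
  expect_equal(sum(abs(v$v1 - v$omega1) > 0.1), 50)
  # brute-force oracle for the population standard deviation
  freqs <- c(rep(1, 150), rep(0.8, 50))
  oracle <- sqrt(sum((freqs - mean(freqs))^2) / 200)
  expect_equal(frequency_std(v$v1), oracle)
  expect_equal(oracle, 0.0866025, tolerance = 1e-6)
  cl <- detect_frequency_cluster(v$v1, delta = 0.01)
  expect_true(cl$has_cluster)
  expect_equal(sort(lengths(cl$partition)), c(50, 150))
  expect_equal(cl$partition[[1]], 151:200)  # slower cluster first
})

test_that("frequency_std matches hand arithmetic and scales linearly", {
  expect_equal(frequency_std(c(1, 1, 1, 2)), sqrt(0.75 / 4))
  expect_equal(frequency_std(rep(3.2, 10)), 0)
  set.seed(2)
  f <- rnorm(40)
  for (c in c(-2, 0.5, 7))
    expect_equal(frequency_std(c * f), abs(c) * frequency_std(f))
})

test_that("R2 separates antipodal, in-phase and splay configurations", {
  expect_equal(order_parameter_R2(rep(1.3, 17)), 1)
  expect_lt(order_parameter_R2(2 * pi * seq_len(200) / 200), 1e-12)
  expect_equal(order_parameter_R2(rep(c(0, pi), 10)), 1)
  expect_error(order_parameter_R2(numeric(0)), "empty")
  # invariance under global shift and node permutation
  set.seed(5)
  ph <- runif(30, 0, 2 * pi)
  expect_equal(order_parameter_R2(ph + 1.1), order_parameter_R2(ph))
  expect_equal(order_parameter_R2(sample(ph)), order_parameter_R2(ph))
  expect_true(all(vapply(1:20, function(i) {
    r <- order_parameter_R2(runif(25, 0, 2 * pi)); r >= 0 && r <= 1
  }, logical(1))))
})

test_that("cluster detection partitions by single-linkage gaps", {
  r <- detect_frequency_cluster(rep(1, 10), delta = 0.01)
  expect_false(r$has_cluster)
  expect_length(r$partition, 1L)
  f <- rep(1, 10); f[4] <- 1.02
  r <- detect_frequency_cluster(f, delta = 0.01)
  expect_true(r$has_cluster)
  expect_equal(sort(lengths(r$partition)), c(1, 9))
  expect_equal(r$partition[[2]], 4L)
  # three groups
  f3 <- c(rep(1, 5), rep(1.5, 3), rep(2, 2))
  expect_length(detect_frequency_cluster(f3, delta = 0.1)$partition, 3L)
  expect_error(detect_frequency_cluster(f, delta = 0), "delta")
})

test_that("splay detection requires frequency synchrony and low R2", {
  expect_false(detect_splay(make_fixture("in-phase", N = 20), window = 50))
  expect_true(detect_splay(make_fixture("splay", N = 200, omega = 1),
                           window = 50))
  tr <- make_fixture("two-frequency-cluster", N = 20, sizes = c(15, 5),
                     freqs = c(1, 0.8))
  expect_false(detect_splay(tr, window = 50))
})

test_that("interlayer locking detects constant offsets and rejects drift", {
  # artificial trajectory: difference 0.3 + 0.001 sin t
  times <- seq(0, 100, 0.5)
  N <- 6
  tr <- make_fixture("in-phase", N = N, omega = 1, times = times)
  tr$phi2 <- tr$phi1 - 0.3 - 0.001 * sin(times)
  lock <- detect_interlayer_locking(tr, window = 50, tol = 0.01)
  expect_true(lock$locked)
  expect_equal(lock$offsets, rep(0.3, N), tolerance = 0.01)
  drift <- make_fixture("drifting-layers", N = N, omega = 1, drift = 0.2)
  expect_false(detect_interlayer_locking(drift, window = 50)$locked)
})

test_that("state classification is total and matches the taxonomy", {
  lab <- function(tr) summary(tr, window = 50)$label
  expect_equal(lab(make_fixture("in-phase", N = 20, omega = 1)),
               "in-phase-healthy")
  expect_equal(lab(make_fixture("antipodal", N = 20, omega = 1)),
               "in-phase-healthy")  # antipodal: R2 = 1, healthy class
  expect_equal(lab(make_fixture("splay", N = 40, omega = 1)),
               "splay-vulnerable")
  expect_equal(lab(make_fixture("two-frequency-cluster", N = 20,
                                sizes = c(15, 5), freqs = c(1, 0.8))),
               "frequency-cluster-pathological")
  # immune-only cluster: parenchyma synchronized
  tr <- make_fixture("in-phase", N = 20, omega = 1)
  cl <- make_fixture("two-frequency-cluster", N = 20, sizes = c(15, 5),
                     freqs = c(1, 0.8))
  tr$phi2 <- cl$phi2
  expect_equal(lab(tr), "immune-activated-parenchyma-healthy")
  labels <- c("in-phase-healthy", "splay-vulnerable",
              "frequency-cluster-pathological",
              "immune-activated-parenchyma-healthy")
  expect_true(lab(make_fixture("drifting-layers", N = 10)) %in% labels)
})

test_that("summary bundles consistent flags", {
  s <- summary(make_fixture("splay", N = 50, omega = 1), window = 50)
  expect_false(s$has_frequency_cluster[1])
  expect_equal(s$freq_std[1], 0, tolerance = 1e-12)
  expect_true(s$is_splay[1])
  expect_true(s$R2[1] < 0.05 && s$R2[1] >= 0)
  expect_true(s$interlayer_locked)  # identical layers
})
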