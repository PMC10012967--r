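# Literal double-loop transcription of the model equations, used as the
# independent oracle for the vectorized/compiled right-hand side.
rhs_loop_oracle <- function(state, model) {
  N <- model$N
  A <- model$adjacency
  dphi1 <- numeric(N); dphi2 <- numeric(N)
  dk1 <- matrix(0, N, N); dk2 <- matrix(0, N, N)
  for (i in seq_len(N)) {
    s1 <- 0; s2 <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      s1 <- s1 + (A[i, j] + state$kappa1[i, j]) *
        sin(state$phi1[i] - state$phi1[j] + model$alpha11)
      s2 <- s2 + state$kappa2[i, j] *
        sin(state$phi2[i] - state$phi2[j] + model$alpha22)
      dk1[i, j] <- -model$eps1 * (state$kappa1[i, j] +
        sin(state$phi1[i] - state$phi1[j] - model$beta))
      dk2[i, j] <- -model$eps2 * (state$kappa2[i, j] +
        sin(state$phi2[i] - state$phi2[j] - model$beta))
    }
    dphi1[i] <- model$omega1 - s1 / N -
      model$sigma * sin(state$phi1[i] - state$phi2[i] + model$alpha12)
    dphi2[i] <- model$omega2 - s2 / N -
      model$sigma * sin(state$phi2[i] - state$phi1[i] + model$alpha21)
  }
  list(dphi1 = dphi1, dphi2 = dphi2, dkappa1 = dk1, dkappa2 = dk2)
}

random_state <- function(N, seed) {
  set.seed(seed)
  k1 <- matrix(runif(N * N, -1, 1), N, N); diag(k1) <- 0
  k2 <- matrix(runif(N * N, -1, 1), N, N); diag(k2) <- 0
  duplex_state(runif(N, 0, 2 * pi), runif(N, 0, 2 * pi), k1, k2)
}

random_model <- function(N, seed) {
  set.seed(seed)
  duplex_model(N = N,
               omega1 = runif(1, -1, 1), omega2 = runif(1, -1, 1),
               alpha11 = runif(1, -pi, pi), alpha22 = runif(1, -pi, pi),
               alpha12 = runif(1, -pi, pi), alpha21 = runif(1, -pi, pi),
               beta = runif(1, 0, pi),
               eps1 = runif(1, 0.01, 0.1), eps2 = runif(1, 0.1, 0.5),
               sigma = runif(1, 0, 1.5))
}

in_phase_state <- function(N, kappa = 0) {
  K <- matrix(kappa, N, N); diag(K) <- 0
  duplex_state(rep(0, N), rep(0, N), K, K)
}
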