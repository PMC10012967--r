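#' Generate the perturbed random initial condition
#'
#' Draws the initial state used throughout the regime scans: phases of both
#' layers i.i.d. uniform on \eqn{[0, 2\pi)}, parenchymal cytokine weights
#' \eqn{\kappa^1_{ij}} i.i.d. uniform on \eqn{[-1, 1]}, and an immune
#' cytokine matrix \eqn{\kappa^2} carrying the systemic activation: a
#' deterministic two-block cluster structure in which entries are 1 within
#' the first `C` indices and within the remaining `N - C` indices, and 0
#' between the blocks.  `C` models the size of the local infection that
#' activates the immune layer.  Diagonals of both weight matrices are 0.
#'
#' Draw order under the seed is fixed and documented: `phi1`, then `phi2`,
#' then `kappa1` filled row by row (diagonal positions drawn then zeroed),
#' so a given `(N, C, seed)` always yields the identical state.
#'
#' @param N oscillators per layer.
#' @param C small-cluster size of the immune activation, `1 < C < N`.
#' @param seed integer seed for the random draws.
#' @return A [duplex_state()].
#' @examples
#' s <- generate_initial_state(N = 20, C = 4, seed = 1)
#' sum(s$kappa2 == 1)  # C*(C-1) + (N-C)*(N-C-1)
#' @export
generate_initial_state <- function(N, C, seed) {
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 3)
    stop("'N' must be an integer >= 3", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || C != round(C))
    stop("'C' must be an integer", call. = FALSE)
  if (C <= 1 || C >= N)
    stop(sprintf("'C' must satisfy 1 < C < N (got C = %d, N = %d)",
                 as.integer(C), as.integer(N)), call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("'seed' must be an integer", call. = FALSE)
  N <- as.integer(N); C <- as.integer(C)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")

  phi1 <- stats::runif(N, 0, 2 * pi)
  phi2 <- stats::runif(N, 0, 2 * pi)
  kappa1 <- matrix(stats::runif(N * N, -1, 1), N, N, byrow = TRUE)
  diag(kappa1) <- 0

  kappa2 <- matrix(0, N, N)
  kappa2[seq_len(C), seq_len(C)] <- 1
  kappa2[(C + 1):N, (C + 1):N] <- 1
  diag(kappa2) <- 0

  duplex_state(phi1, phi2, kappa1, kappa2)
}

#' Spawn reproducible ensemble member seeds
#'
#' Derives `n` distinct child seeds from a master seed.  A parameter sweep
#' reuses the identical seed list at every grid point so that each grid cell
#' sees the same ensemble of random initial conditions; differences across
#' cells are then attributable to the parameters alone.
#'
#' @param master_seed integer master seed.
#' @param n number of ensemble members (>= 1).
#' @return An integer vector of `n` distinct seeds, a deterministic function
#'   of `master_seed`.
#' @examples
#' spawn_member_seeds(42, 5)
#' @export
spawn_member_seeds <- function(master_seed, n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1)
    stop("'n' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      master_seed != round(master_seed))
    stop("'master_seed' must be an integer", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed), kind = "Mersenne-Twister")
  sample.int(.Machine$integer.max - 1L, as.integer(n))
}
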