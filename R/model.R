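#' Define a two-layer adaptive phase-oscillator model
#'
#' Constructs the parameter set of a duplex (two-layer multiplex) network of
#' `N` adaptively coupled phase oscillators per layer.  Layer 1 represents
#' the parenchyma of an organ: its oscillators interact through a fixed
#' binary adjacency `A` plus an adaptive cytokine weight matrix
#' \eqn{\kappa^1}.  Layer 2 represents the immune system (stroma): its
#' coupling is purely adaptive (\eqn{\kappa^2}).  Corresponding nodes of the
#' two layers are linked bidirectionally with fixed strength `sigma`.
#'
#' The dynamics are
#' \deqn{\dot\phi^1_i = \omega^1 - \frac{1}{N}\sum_{j \ne i}
#'   (a_{ij} + \kappa^1_{ij})\sin(\phi^1_i - \phi^1_j + \alpha^{11})
#'   - \sigma \sin(\phi^1_i - \phi^2_i + \alpha^{12}),}
#' \deqn{\dot\kappa^\mu_{ij} = -\epsilon^\mu\left(\kappa^\mu_{ij} +
#'   \sin(\phi^\mu_i - \phi^\mu_j - \beta)\right),}
#' and symmetrically for layer 2 (with no fixed adjacency term).  Sums run
#' over \eqn{j \ne i} and the diagonal of each \eqn{\kappa} is held at zero.
#'
#' The phase lag `beta` of the adaptation rule is the "age parameter": a
#' physiological sum parameter (age, inflammaging, comorbidity, ...).
#' `beta = pi/2` is a Hebbian rule maximally reinforcing synchrony;
#' larger `beta` delays adaptation and favours pathological frequency
#' clustering.
#'
#' @param N number of oscillators per layer (>= 2).
#' @param omega1,omega2 natural frequencies of the two layers (rad/time);
#'   the default co-rotating frame sets both to 0.
#' @param alpha11,alpha22 intralayer phase lags (rad).
#' @param alpha12,alpha21 interlayer phase lags (rad).
#' @param beta adaptation phase lag, the age parameter (rad).
#' @param eps1,eps2 adaptation rates of the parenchymal and immune cytokine
#'   weights (1/time); must be positive.  `eps1 << eps2 << 1` gives the
#'   slow--fast--faster structure of the model.
#' @param sigma interlayer coupling strength (>= 0).
#' @param adjacency either the string `"global"` (all-to-all, the default:
#'   \eqn{a_{ij} = 1} for \eqn{i \ne j}) or an explicit `N` x `N` binary
#'   matrix for the fixed parenchymal connectivity.
#'
#' @return An object of class `"duplex_model"`: a list of validated
#'   parameters with the adjacency resolved to a matrix.
#'
#' @examples
#' m <- duplex_model(N = 20, beta = 0.5 * pi, sigma = 1)
#' m
#' @seealso [simulate.duplex_model()], [generate_initial_state()],
#'   [sync_phase_lag()]
#' @export
duplex_model <- function(N = 200,
                         omega1 = 0, omega2 = 0,
                         alpha11 = -0.28 * pi, alpha22 = -0.28 * pi,
                         alpha12 = 0, alpha21 = 0,
                         beta = 0.5 * pi,
                         eps1 = 0.03, eps2 = 0.3,
                         sigma = 1,
                         adjacency = "global") {
  stop_if_not_scalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || N != round(N) || N < 2)
    stop("'N' must be an integer >= 2", call. = FALSE)
  N <- as.integer(N)
  for (nm in c("omega1", "omega2", "alpha11", "alpha22", "alpha12",
               "alpha21", "beta", "eps1", "eps2", "sigma"))
    stop_if_not_scalar(get(nm), nm)
  if (eps1 <= 0) stop("'eps1' must be > 0", call. = FALSE)
  if (eps2 <= 0) stop("'eps2' must be > 0", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)

  if (is.character(adjacency)) {
    adjacency <- match.arg(adjacency, "global")
    A <- matrix(1, N, N)
    diag(A) <- 0
  } else {
    A <- as.matrix(adjacency)
    if (!is.numeric(A) || nrow(A) != N || ncol(A) != N)
      stop(sprintf("'adjacency' must be an %d x %d numeric matrix", N, N),
           call. = FALSE)
    if (!all(A %in% c(0, 1)))
      stop("'adjacency' entries must be 0 or 1", call. = FALSE)
    if (any(diag(A) != 0))
      stop("'adjacency' must have a zero diagonal", call. = FALSE)
  }

  structure(
    list(N = N, omega1 = omega1, omega2 = omega2,
         alpha11 = alpha11, alpha22 = alpha22,
         alpha12 = alpha12, alpha21 = alpha21,
         beta = beta, eps1 = eps1, eps2 = eps2, sigma = sigma,
         adjacency = A),
    class = "duplex_model"
  )
}

#' @export
print.duplex_model <- function(x, ...) {
  cat("Two-layer adaptive phase-oscillator model (duplex network)\n")
  cat(sprintf("  N = %d oscillators per layer\n", x$N))
  cat(sprintf("  intralayer lags  alpha11 = %s, alpha22 = %s\n",
              format_pi(x$alpha11), format_pi(x$alpha22)))
  cat(sprintf("  interlayer       sigma = %g, alpha12 = %s, alpha21 = %s\n",
              x$sigma, format_pi(x$alpha12), format_pi(x$alpha21)))
  cat(sprintf("  adaptation       beta = %s (age parameter), eps1 = %g, eps2 = %g\n",
              format_pi(x$beta), x$eps1, x$eps2))
  cat(sprintf("  natural freq.    omega1 = %g, omega2 = %g\n",
              x$omega1, x$omega2))
  glob <- all(x$adjacency[row(x$adjacency) != col(x$adjacency)] == 1)
  cat(sprintf("  parenchymal adjacency: %s\n",
              if (glob) "global (all-to-all)" else "explicit matrix"))
  invisible(x)
}

format_pi <- function(x) {
  if (x == 0) return("0")
  sprintf("%.4gpi", x / pi)
}

# flat parameter vector consumed by the compiled right-hand side
model_parms <- function(model) {
  c(model$N, model$omega1, model$omega2,
    model$alpha11, model$alpha22, model$alpha12, model$alpha21,
    model$beta, model$eps1, model$eps2, model$sigma,
    as.double(model$adjacency))
}

#' Construct a duplex network state
#'
#' Bundles the dynamical variables of the two-layer model: the phase vectors
#' of both layers (unwrapped, i.e. not reduced modulo \eqn{2\pi}) and the
#' two cytokine weight matrices.  Diagonal entries of both weight matrices
#' are identically zero; off-diagonal weights live in \eqn{[-1, 1]} and stay
#' there under the adaptation dynamics.
#'
#' @param phi1,phi2 numeric length-`N` phase vectors (rad) of the
#'   parenchymal and immune layer.
#' @param kappa1,kappa2 `N` x `N` cytokine weight matrices with zero
#'   diagonal.
#' @return An object of class `"duplex_state"`.
#' @examples
#' s <- duplex_state(phi1 = rep(0, 4), phi2 = rep(0, 4),
#'                   kappa1 = matrix(0, 4, 4), kappa2 = matrix(0, 4, 4))
#' @export
duplex_state <- function(phi1, phi2, kappa1, kappa2) {
  N <- length(phi1)
  check <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid duplex state: '%s' %s", field, what),
                  call. = FALSE)
  }
  check(is.numeric(phi1) && all(is.finite(phi1)), "phi1", "must be finite numeric")
  check(is.numeric(phi2) && length(phi2) == N && all(is.finite(phi2)),
        "phi2", sprintf("must be finite numeric of length %d", N))
  for (nm in c("kappa1", "kappa2")) {
    K <- get(nm)
    check(is.matrix(K) && nrow(K) == N && ncol(K) == N,
          nm, sprintf("must be a %d x %d matrix", N, N))
    check(all(is.finite(K)), nm, "must be finite")
    check(all(diag(K) == 0), nm, "must have a zero diagonal")
  }
  structure(list(phi1 = as.double(phi1), phi2 = as.double(phi2),
                 kappa1 = kappa1, kappa2 = kappa2, N = N),
            class = "duplex_state")
}

#' @export
print.duplex_state <- function(x, ...) {
  cat(sprintf("Duplex network state, N = %d per layer\n", x$N))
  cat(sprintf("  phi1 in [%.3f, %.3f], phi2 in [%.3f, %.3f] rad\n",
              min(x$phi1), max(x$phi1), min(x$phi2), max(x$phi2)))
  cat(sprintf("  kappa1 in [%.3f, %.3f], kappa2 in [%.3f, %.3f]\n",
              min(x$kappa1), max(x$kappa1), min(x$kappa2), max(x$kappa2)))
  invisible(x)
}

# state <-> flat vector, layout: phi1, phi2, kappa1 (col-major), kappa2
pack_state <- function(state) {
  c(state$phi1, state$phi2, as.double(state$kappa1), as.double(state$kappa2))
}

unpack_state <- function(y, N) {
  duplex_state(phi1 = y[seq_len(N)],
               phi2 = y[N + seq_len(N)],
               kappa1 = matrix(y[2 * N + seq_len(N * N)], N, N),
               kappa2 = matrix(y[2 * N + N * N + seq_len(N * N)], N, N))
}

#' Evaluate the model right-hand side
#'
#' Computes the exact time derivative of every dynamical variable of the
#' two-layer system at a given state: phase velocities of both layers and
#' the adaptation rates of both cytokine weight matrices.  Coupling sums run
#' over \eqn{j \ne i}; the diagonal derivative of each weight matrix is 0.
#'
#' @param state a [duplex_state()].
#' @param model a [duplex_model()] with `N` matching the state.
#' @return A list with components `dphi1`, `dphi2` (rad/time) and `dkappa1`,
#'   `dkappa2` (1/time), the same shapes as the state fields.
#' @examples
#' m <- duplex_model(N = 4, beta = 0.5 * pi)
#' s <- duplex_state(rep(0, 4), rep(0, 4), matrix(0, 4, 4), matrix(0, 4, 4))
#' d <- duplex_rhs(s, m)
#' d$dkappa2[1, 2]  # eps2 * sin(beta) = 0.3 at beta = pi/2
#' @export
duplex_rhs <- function(state, model) {
  if (!inherits(state, "duplex_state")) stop("'state' must be a duplex_state")
  if (!inherits(model, "duplex_model")) stop("'model' must be a duplex_model")
  if (state$N != model$N)
    stop(sprintf("dimension mismatch: state has N = %d, model has N = %d",
                 state$N, model$N), call. = FALSE)
  dy <- .Call(C_duplex_rhs, pack_state(state), model_parms(model))
  N <- model$N
  list(dphi1 = dy[seq_len(N)],
       dphi2 = dy[N + seq_len(N)],
       dkappa1 = matrix(dy[2 * N + seq_len(N * N)], N, N),
       dkappa2 = matrix(dy[2 * N + N * N + seq_len(N * N)], N, N))
}

#' Fixed-point cytokine weight of a phase-synchronized layer
#'
#' In a fully phase-synchronized layer all pairwise phase differences vanish
#' and every off-diagonal weight relaxes to \eqn{\kappa^* = \sin\beta}.
#' For the Hebbian rule `beta = pi/2` all weights tend to unity; for
#' `beta = 0` or `beta = pi` the synchronized coupling vanishes.
#'
#' @param beta age parameter (rad).
#' @return The asymptotic weight \eqn{\sin\beta}.
#' @examples
#' kappa_sync_fixed_point(0.5 * pi)  # 1
#' @export
kappa_sync_fixed_point <- function(beta) sin(beta)

#' Shift all phases of a state by a constant
#'
#' Adds `c` to every phase in both layers, leaving the weight matrices
#' untouched.  Because only phase differences enter the dynamics, the
#' right-hand side is invariant under this shift (for `omega = 0` the model
#' is rotationally symmetric); the helper exists to exercise that symmetry.
#'
#' @param state a [duplex_state()].
#' @param c phase shift (rad).
#' @return The shifted `duplex_state`.
#' @export
shift_all_phases <- function(state, c) {
  state$phi1 <- state$phi1 + c
  state$phi2 <- state$phi2 + c
  state
}
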