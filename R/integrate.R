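#' Simulate the two-layer adaptive network
#'
#' Integrates the coupled phase/weight system from an initial state and
#' returns a sampled trajectory.  Phases are returned unwrapped (the ODE
#' solution is continuous in time, never reduced modulo \eqn{2\pi}), which
#' is what the endpoint-difference definition of the mean phase velocities
#' requires.  The full \eqn{O(N^2)} weight history is not stored: the
#' trajectory keeps the phase history at every sample time plus the weight
#' matrices at the final time (and optionally at a coarser snapshot stride).
#'
#' The system is non-stiff but slow--fast (adaptation rates `eps1`, `eps2`
#' well below the phase timescale); it is integrated with an adaptive-order
#' Adams multistep scheme (via \pkg{deSolve}, compiled right-hand side),
#' with an adaptive Runge-Kutta 4(5) pair available through `method`.
#' Integration proceeds in internal chunks so that memory stays bounded for
#' large `N`.
#'
#' @param object a [duplex_model()].
#' @param nsim number of trajectories; only `nsim = 1` is supported (use
#'   [run_ensemble()] for ensembles).
#' @param seed optional integer; when `state0` is missing, the initial state
#'   is drawn with [generate_initial_state()] under this seed.
#' @param state0 a [duplex_state()]; overrides `seed`.
#' @param C small-cluster size for the generated initial condition when
#'   `state0` is missing (default `0.2 * N` rounded).
#' @param t_end final time (time units), default 2000.
#' @param sample_dt sampling interval of the stored trajectory, default 0.5.
#' @param method \pkg{deSolve} integration method: `"adams"` (default) or
#'   `"ode45"`.
#' @param rtol,atol relative and absolute error tolerances.
#' @param kappa_stride optional integer: store weight-matrix snapshots every
#'   `kappa_stride`-th sample (in addition to the final matrices).
#' @param ... unused.
#' @return An object of class `"duplex_trajectory"`: list with `times`,
#'   phase matrices `phi1`, `phi2` (samples x N), final weight matrices
#'   `kappa1`, `kappa2`, optional `kappa_snapshots`, the `model`, and `meta`
#'   (integrator settings and seed).
#' @examples
#' m <- duplex_model(N = 10, beta = 0.5 * pi, sigma = 1)
#' tr <- simulate(m, seed = 1, C = 2, t_end = 50)
#' tr
#' @importFrom stats simulate
#' @export
simulate.duplex_model <- function(object, nsim = 1, seed = NULL,
                                  state0 = NULL, C = NULL,
                                  t_end = 2000, sample_dt = 0.5,
                                  method = c("adams", "ode45"),
                                  rtol = 1e-6, atol = 1e-8,
                                  kappa_stride = NULL, ...) {
  if (nsim != 1)
    stop("simulate() integrates a single trajectory; use run_ensemble() for ensembles")
  method <- match.arg(method)
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (sample_dt <= 0 || sample_dt > t_end)
    stop("'sample_dt' must lie in (0, t_end]", call. = FALSE)

  if (is.null(state0)) {
    if (is.null(seed))
      stop("either 'state0' or 'seed' must be supplied", call. = FALSE)
    if (is.null(C)) C <- max(2L, round(0.2 * object$N))
    state0 <- generate_initial_state(object$N, C, seed)
  } else if (!inherits(state0, "duplex_state")) {
    stop("'state0' must be a duplex_state", call. = FALSE)
  }
  if (state0$N != object$N)
    stop(sprintf("dimension mismatch: state0 has N = %d, model has N = %d",
                 state0$N, object$N), call. = FALSE)

  N <- object$N
  times <- seq(0, t_end, by = sample_dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  n_t <- length(times)
  neq <- 2L * N + 2L * N * N

  .Call(C_duplex_set_parms, model_parms(object))

  phi1 <- matrix(NA_real_, n_t, N)
  phi2 <- matrix(NA_real_, n_t, N)
  snapshots <- if (!is.null(kappa_stride)) list() else NULL

  # chunked integration keeps the deSolve output below ~40 MB per call
  chunk <- max(2L, min(n_t, as.integer(ceiling(5e6 / neq)) + 1L))
  y <- pack_state(state0)
  phi1[1, ] <- y[seq_len(N)]
  phi2[1, ] <- y[N + seq_len(N)]
  i0 <- 1L
  while (i0 < n_t) {
    i1 <- min(n_t, i0 + chunk - 1L)
    tt <- times[i0:i1]
    sol <- deSolve::ode(y = y, times = tt, func = "duplex_derivs",
                        parms = NULL, dllname = "duplexsep",
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = 1e5)
    if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(tt))
      stop(sprintf("integration failed near t = %.3f (last successful sample)",
                   sol[nrow(sol), 1L]), call. = FALSE)
    if (anyNA(sol[nrow(sol), -1L]))
      stop("integration produced NaN/NA state values", call. = FALSE)
    idx <- i0:i1
    phi1[idx, ] <- sol[, 1L + seq_len(N), drop = FALSE]
    phi2[idx, ] <- sol[, 1L + N + seq_len(N), drop = FALSE]
    if (!is.null(kappa_stride)) {
      keep <- idx[(idx - 1L) %% kappa_stride == 0L]
      for (k in keep) {
        r <- which(idx == k)
        snapshots[[as.character(times[k])]] <- list(
          kappa1 = matrix(sol[r, 1L + 2 * N + seq_len(N * N)], N, N),
          kappa2 = matrix(sol[r, 1L + 2 * N + N * N + seq_len(N * N)], N, N))
      }
    }
    y <- as.double(sol[nrow(sol), -1L])
    i0 <- i1
  }

  structure(
    list(times = times,
         phi1 = phi1, phi2 = phi2,
         kappa1 = matrix(y[2 * N + seq_len(N * N)], N, N),
         kappa2 = matrix(y[2 * N + N * N + seq_len(N * N)], N, N),
         kappa_snapshots = snapshots,
         model = object,
         meta = list(method = method, rtol = rtol, atol = atol,
                     sample_dt = sample_dt, seed = seed,
                     C = if (is.null(state0)) C else NA)),
    class = "duplex_trajectory"
  )
}

#' @export
print.duplex_trajectory <- function(x, ...) {
  cat(sprintf("Duplex trajectory: N = %d per layer, t in [%g, %g], %d samples\n",
              ncol(x$phi1), x$times[1L], x$times[length(x$times)],
              length(x$times)))
  cat(sprintf("  integrator %s (rtol %g, atol %g), sample_dt = %g\n",
              x$meta$method, x$meta$rtol, x$meta$atol, x$meta$sample_dt))
  cat(sprintf("  final kappa1 in [%.3f, %.3f], kappa2 in [%.3f, %.3f]\n",
              min(x$kappa1), max(x$kappa1), min(x$kappa2), max(x$kappa2)))
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj a `duplex_trajectory`.
#' @return The [duplex_state()] at the last sample time.
#' @export
final_state <- function(traj) {
  n <- length(traj$times)
  duplex_state(phi1 = traj$phi1[n, ], phi2 = traj$phi2[n, ],
               kappa1 = traj$kappa1, kappa2 = traj$kappa2)
}

#' Check a trajectory for phase-sampling aliasing
#'
#' Mean phase velocities are computed from endpoint differences of the
#' unwrapped phases, which is only meaningful if the stored samples resolve
#' the rotation.  This guard returns `TRUE` iff no phase advances by more
#' than `guard * pi` between consecutive samples in either layer.
#'
#' @param traj a `duplex_trajectory`.
#' @param guard fraction of \eqn{\pi} allowed per sampling step (default 0.9).
#' @return Logical flag.
#' @export
unwrap_check <- function(traj, guard = 0.9) {
  jump <- function(M) if (nrow(M) < 2L) 0 else max(abs(diff(M)))
  max(jump(traj$phi1), jump(traj$phi2)) < guard * pi
}
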