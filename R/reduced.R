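#' Exponential-kernel representation of an adaptive weight
#'
#' The adaptation equation \eqn{\dot\kappa = -\epsilon(\kappa +
#' \sin(\Delta\phi(t) - \beta))} has the particular solution
#' \deqn{\kappa(t) = -\epsilon \int_0^\infty e^{-\epsilon s}
#'   \sin(\Delta\phi(t - s) - \beta)\, ds,}
#' i.e. the weight is a distributed-delay functional of the whole phase
#' history with exponential memory of depth \eqn{1/\epsilon}.  The integral
#' is evaluated by adaptive quadrature, truncated at
#' \eqn{s_{max} = -\ln(10^{-10})/\epsilon} where the kernel mass is
#' negligible.  The history is extended backwards by its value at the start
#' of the supplied domain.
#'
#' @param phase_difference_history a function of time returning
#'   \eqn{\Delta\phi(u)}; evaluated on `[t - s_max, t]` and held constant
#'   at `phase_difference_history(0)` for negative arguments.
#' @param eps adaptation rate (1/time).
#' @param beta age parameter (rad).
#' @param t evaluation time.
#' @param rel.tol quadrature tolerance.
#' @return \eqn{\kappa(t)} (dimensionless, in `[-1, 1]`).
#' @examples
#' kappa_kernel(function(u) 0, eps = 0.3, beta = 0.5 * pi, t = 10)  # 1
#' @export
kappa_kernel <- function(phase_difference_history, eps, beta, t,
                         rel.tol = 1e-9) {
  if (eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  s_max <- -log(1e-10) / eps
  h <- function(u) ifelse(u < 0, phase_difference_history(0), phase_difference_history(u))
  integrand <- function(s) exp(-eps * s) * sin(h(t - s) - beta)
  # piecewise quadrature: exponential decay over s_max with an oscillatory
  # integrand; split into ~1/eps-length panels for robustness
  breaks <- seq(0, s_max, length.out = max(16L, ceiling(eps * s_max) * 8L) + 1L)
  val <- 0
  for (k in seq_len(length(breaks) - 1L)) {
    q <- stats::integrate(integrand, breaks[k], breaks[k + 1L],
                          rel.tol = rel.tol, abs.tol = rel.tol,
                          subdivisions = 400L)
    if (q$message != "OK")
      stop("quadrature failed: ", q$message, call. = FALSE)
    val <- val + q$value
  }
  -eps * val
}

#' Reduced dynamics on the synchronized manifold
#'
#' On the fully synchronized manifold (all oscillators of a layer share one
#' phase) the adaptive weights integrate out to \eqn{\sin\beta} and the
#' duplex system collapses to two coupled scalar phases (intralayer lags
#' equal to `alpha0`, interlayer lags zero):
#' \deqn{\dot\phi^1 = -(1 + \sin\beta)\sin\alpha^0 -
#'   \sigma\sin(\phi^1 - \phi^2),\quad
#'   \dot\phi^2 = -\sin\beta\,\sin\alpha^0 - \sigma\sin(\phi^2 - \phi^1).}
#'
#' @param phi1,phi2 scalar layer phases (rad).
#' @param alpha0 common intralayer phase lag (rad).
#' @param beta age parameter (rad).
#' @param sigma interlayer coupling (>= 0).
#' @return Numeric length-2 vector `c(dphi1, dphi2)` (rad/time).
#' @examples
#' reduced_sync_rhs(0.126 * pi, 0, alpha0 = -0.28 * pi, beta = 0.5 * pi, sigma = 1)
#' @export
reduced_sync_rhs <- function(phi1, phi2, alpha0, beta, sigma) {
  c(-(1 + sin(beta)) * sin(alpha0) - sigma * sin(phi1 - phi2),
    -sin(beta) * sin(alpha0) - sigma * sin(phi2 - phi1))
}

#' Existence bound for the fully synchronized duplex state
#'
#' Frequency synchronization of the two reduced layer phases requires
#' \eqn{|\sin(\phi^1 - \phi^2)| = |\sin\alpha^0|/(2\sigma) \le 1}, i.e. the
#' fully in-phase synchronized duplex state exists only for
#' \eqn{\sigma > |\sin\alpha^0| / 2}.
#'
#' @param alpha0 common intralayer phase lag (rad).
#' @return The critical interlayer coupling \eqn{|\sin\alpha^0|/2}.
#' @examples
#' sync_existence_bound(-0.28 * pi)  # 0.385...
#' @export
sync_existence_bound <- function(alpha0) abs(sin(alpha0)) / 2

#' Interlayer phase lag of the synchronized state
#'
#' Equating the two reduced layer frequencies yields
#' \eqn{\sin(\phi^1 - \phi^2) = -\sin\alpha^0 / (2\sigma)}.  The principal
#' arcsin branch is returned; the second branch \eqn{\pi - \Delta} is the
#' unstable companion lock.
#'
#' @param alpha0 common intralayer phase lag (rad).
#' @param sigma interlayer coupling strength.
#' @return The locked interlayer phase difference \eqn{\Delta} (rad).
#' @examples
#' sync_phase_lag(-0.28 * pi, 1) / pi  # 0.126
#' @export
sync_phase_lag <- function(alpha0, sigma) {
  x <- -sin(alpha0) / (2 * sigma)
  if (!is.finite(x) || abs(x) > 1)
    stop(sprintf(paste0("no synchronized state: sigma = %g is below the ",
                        "existence bound %g for alpha0 = %g"),
                 sigma, sync_existence_bound(alpha0), alpha0), call. = FALSE)
  asin(x)
}

#' Common frequency of the locked synchronized state
#'
#' Substituting the locked phase lag back into the reduced dynamics gives
#' the common drift of both layers,
#' \eqn{\dot\phi = -\sin\alpha^0\,(\sin\beta + 1/2)} (rad/time, in the
#' co-rotating frame).
#'
#' @inheritParams sync_phase_lag
#' @param beta age parameter (rad).
#' @return The locked common frequency (rad/time).
#' @examples
#' sync_common_frequency(-0.28 * pi, 0.5 * pi, 1)  # 1.15576
#' @export
sync_common_frequency <- function(alpha0, beta, sigma) {
  sync_phase_lag(alpha0, sigma)  # errors below the existence bound
  -sin(alpha0) * (sin(beta) + 0.5)
}
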