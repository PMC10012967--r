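#' Construct an analytic test trajectory
#'
#' Builds a `duplex_trajectory` from a closed-form phase law, bypassing the
#' integrator entirely, so that the synchronization measures can be tested
#' against inputs whose properties hold exactly.  Available kinds:
#' \describe{
#'   \item{`in-phase`}{\eqn{\phi_j^\mu(t) = \omega t} for all nodes, both
#'     layers: antipodal (`R2 = 1`), frequency-synchronized.}
#'   \item{`splay`}{\eqn{\phi_j^\mu(t) = 2\pi j/N + \omega t}: `R2 = 0`,
#'     frequency-synchronized.}
#'   \item{`antipodal`}{half the nodes at phase 0, half at \eqn{\pi}, plus
#'     rigid rotation \eqn{\omega t}: `R2 = 1`.}
#'   \item{`two-frequency-cluster`}{the first `sizes[1]` nodes run at
#'     `freqs[1]`, the remaining `sizes[2]` at `freqs[2]` (both layers).}
#'   \item{`drifting-layers`}{layer 1 at frequency `omega`, layer 2 at
#'     `omega + drift`: no interlayer locking.}
#' }
#' Weight matrices are set to the synchronized fixed point \eqn{\sin\beta}
#' off-diagonal (`beta = pi/2` by default, hence 1).
#'
#' @param kind fixture kind, see Details.
#' @param N nodes per layer.
#' @param omega base frequency (rad/time).
#' @param times sample times (default `seq(0, 100, 0.5)`).
#' @param sizes,freqs cluster sizes and frequencies for
#'   `"two-frequency-cluster"`.
#' @param drift layer-2 frequency offset for `"drifting-layers"`.
#' @param beta age parameter used for the weight fixed point.
#' @return A `duplex_trajectory`.
#' @examples
#' tr <- make_fixture("two-frequency-cluster", N = 200,
#'                    sizes = c(150, 50), freqs = c(1, 0.8))
#' summary(tr, window = 50)$label
#' @export
make_fixture <- function(kind = c("in-phase", "splay", "antipodal",
                                  "two-frequency-cluster", "drifting-layers"),
                         N = 20, omega = 1, times = seq(0, 100, by = 0.5),
                         sizes = NULL, freqs = NULL, drift = 0.2,
                         beta = 0.5 * pi) {
  kind <- match.arg(kind)
  n_t <- length(times)
  base <- switch(kind,
    "in-phase" = rep(0, N),
    "splay" = 2 * pi * seq_len(N) / N,
    "antipodal" = rep(c(0, pi), length.out = N),
    "two-frequency-cluster" = ,
    "drifting-layers" = rep(0, N))

  if (kind == "two-frequency-cluster") {
    if (is.null(sizes) || is.null(freqs) || length(sizes) != 2L ||
        length(freqs) != 2L)
      stop("'sizes' and 'freqs' (length 2 each) are required", call. = FALSE)
    if (sum(sizes) != N) stop("sum(sizes) must equal N", call. = FALSE)
    node_freq <- rep(freqs, sizes)
    phi <- outer(times, node_freq)
    phi1 <- phi
    phi2 <- phi
  } else if (kind == "drifting-layers") {
    phi1 <- outer(times, rep(omega, N))
    phi2 <- outer(times, rep(omega + drift, N))
  } else {
    phi1 <- outer(rep(1, n_t), base) + omega * times
    phi2 <- phi1
  }

  K <- matrix(kappa_sync_fixed_point(beta), N, N)
  diag(K) <- 0
  structure(
    list(times = times, phi1 = phi1, phi2 = phi2,
         kappa1 = K, kappa2 = K, kappa_snapshots = NULL,
         model = NULL,
         meta = list(method = "analytic-fixture", kind = kind,
                     rtol = NA, atol = NA,
                     sample_dt = if (n_t > 1) times[2L] - times[1L] else NA,
                     seed = NA)),
    class = "duplex_trajectory")
}
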