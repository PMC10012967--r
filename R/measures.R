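#' Mean phase velocities over a trailing window
#'
#' The mean phase velocity of oscillator `j` in layer `mu` is the endpoint
#' difference of its unwrapped phase over the trailing averaging window:
#' \eqn{\langle\dot\phi_j^\mu\rangle = (\phi_j^\mu(t_{end}) -
#' \phi_j^\mu(t_{end} - T)) / T}.  The layer mean frequency
#' \eqn{\bar\omega^\mu} is the node average.
#'
#' @param traj a `duplex_trajectory` spanning at least `window` time units.
#' @param window averaging window `T` (time units).
#' @return List with `v1`, `v2` (per-node velocities, rad/time), `omega1`,
#'   `omega2` (layer means) and `window` (the realized window, snapped to
#'   the sampling grid).
#' @examples
#' tr <- make_fixture("in-phase", N = 5, omega = 1.7)
#' mean_phase_velocities(tr, 50)$omega1  # 1.7
#' @export
mean_phase_velocities <- function(traj, window) {
  times <- traj$times
  n <- length(times)
  t_end <- times[n]
  if (window <= 0) stop("'window' must be > 0", call. = FALSE)
  if (t_end - times[1L] < window - 1e-9)
    stop(sprintf("window (%g) longer than trajectory span (%g)",
                 window, t_end - times[1L]), call. = FALSE)
  i0 <- which.min(abs(times - (t_end - window)))
  Tw <- t_end - times[i0]
  v1 <- (traj$phi1[n, ] - traj$phi1[i0, ]) / Tw
  v2 <- (traj$phi2[n, ] - traj$phi2[i0, ]) / Tw
  list(v1 = v1, v2 = v2, omega1 = mean(v1), omega2 = mean(v2), window = Tw)
}

#' Second-moment Kuramoto--Daido order parameter
#'
#' \eqn{R_2 = |N^{-1}\sum_j e^{i 2\phi_j}|}, the modulus of the second
#' circular moment of the phase distribution.  `R2 = 1` characterizes
#' antipodal states (in-phase and anti-phase synchrony included), `R2 = 0`
#' splay states; it is the discriminating coherence measure for adaptive
#' networks, where first-moment order parameters are blind to anti-phase
#' structure.
#'
#' @param phases numeric vector of phases (rad).
#' @return `R2` in `[0, 1]`.
#' @examples
#' order_parameter_R2(rep(0.3, 10))          # 1
#' order_parameter_R2(2 * pi * (1:10) / 10)  # 0
#' @export
order_parameter_R2 <- function(phases) {
  if (length(phases) == 0L) stop("empty phase vector", call. = FALSE)
  Mod(mean(exp(2i * phases)))
}

# time-averaged R2 over the trailing window, one value per layer
r2_window <- function(traj, window) {
  times <- traj$times
  n <- length(times)
  idx <- which(times >= times[n] - window - 1e-9)
  c(r2_1 = mean(apply(traj$phi1[idx, , drop = FALSE], 1L, order_parameter_R2)),
    r2_2 = mean(apply(traj$phi2[idx, , drop = FALSE], 1L, order_parameter_R2)))
}

#' Standard deviation of the mean phase velocities
#'
#' Population standard deviation (divisor `N`) of the per-node mean phase
#' velocities about the layer mean: \eqn{\sigma_\chi(\bar\omega) =
#' \sqrt{N^{-1}\sum_j (\langle\dot\phi_j\rangle - \bar\omega)^2}}.  A
#' non-zero value indicates frequency clustering — the model's pathological
#' (parenchyma) or activated (immune layer) signature.
#'
#' @param freqs numeric vector of per-node mean phase velocities.
#' @return \eqn{\sigma_\chi} (rad/time).
#' @examples
#' frequency_std(c(1, 1, 1, 2))  # sqrt(0.75/4)
#' @export
frequency_std <- function(freqs) {
  sqrt(mean((freqs - mean(freqs))^2))
}

#' Detect a frequency cluster in a layer
#'
#' A layer holds a frequency cluster (pathological/activated state) if any
#' node's mean phase velocity deviates from the layer mean by more than
#' `delta`.  Nodes are partitioned into frequency groups by single-linkage
#' on the sorted velocities: a gap larger than `delta` starts a new group.
#'
#' @param freqs per-node mean phase velocities (rad/time).
#' @param delta deviation tolerance (rad/time); the default 0.01 comfortably
#'   exceeds finite-window noise for the default averaging window.
#' @return List with `has_cluster` (logical) and `partition` (list of node
#'   index vectors, ordered by increasing frequency).
#' @examples
#' detect_frequency_cluster(c(rep(1, 8), rep(0.8, 2)))$has_cluster
#' @export
detect_frequency_cluster <- function(freqs, delta = 0.01) {
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  has <- any(abs(freqs - mean(freqs)) > delta)
  ord <- order(freqs)
  gaps <- which(diff(freqs[ord]) > delta)
  bounds <- c(0L, gaps, length(freqs))
  partition <- lapply(seq_len(length(bounds) - 1L), function(k)
    sort(ord[(bounds[k] + 1L):bounds[k + 1L]]))
  list(has_cluster = has, partition = partition)
}

#' Detect a splay state
#'
#' A splay state is frequency-synchronized but maximally phase-spread:
#' \eqn{R_2 = 0} (e.g. \eqn{\phi_j = 2\pi j/N}).  Physiologically it is a
#' healthy but vulnerable configuration.  The detector requires the layer
#' to be frequency-synchronized (no cluster at tolerance `delta`) and the
#' time-averaged `R2` over the trailing window to fall below `threshold`.
#'
#' @param traj a `duplex_trajectory`.
#' @param window trailing averaging window (time units).
#' @param layer 1 (parenchyma) or 2 (immune).
#' @param threshold splay threshold on time-averaged `R2` (default 0.05).
#' @param delta frequency tolerance passed to the cluster check.
#' @return Logical flag.
#' @export
detect_splay <- function(traj, window, layer = 1, threshold = 0.05,
                         delta = 0.01) {
  v <- mean_phase_velocities(traj, window)
  freqs <- if (layer == 1) v$v1 else v$v2
  if (detect_frequency_cluster(freqs, delta)$has_cluster) return(FALSE)
  r2 <- r2_window(traj, window)[layer]
  unname(r2 < threshold)
}

#' Detect interlayer phase locking
#'
#' The layers are phase-locked when each interlayer difference
#' \eqn{\phi^1_i(t) - \phi^2_i(t)} stays (approximately) constant: the
#' standard deviation of every difference over the trailing window must be
#' below `tol`.  Offsets \eqn{\Delta_i} are window means reduced to
#' \eqn{[0, 2\pi)}.
#'
#' @param traj a `duplex_trajectory`.
#' @param window trailing window (time units).
#' @param tol locking tolerance on the per-node standard deviation (rad).
#' @return List with `locked` (logical) and `offsets` (`Delta_i`, rad in
#'   `[0, 2pi)`).
#' @export
detect_interlayer_locking <- function(traj, window, tol = 0.01) {
  times <- traj$times
  n <- length(times)
  idx <- which(times >= times[n] - window - 1e-9)
  d <- traj$phi1[idx, , drop = FALSE] - traj$phi2[idx, , drop = FALSE]
  sds <- apply(d, 2L, stats::sd)
  list(locked = all(sds < tol),
       offsets = colMeans(d) %% (2 * pi))
}

#' Summarize a trajectory: all synchronization measures
#'
#' Computes, over the trailing averaging window, the full measure set: mean
#' phase velocities and layer frequencies, per-layer frequency standard
#' deviation (absolute and normalized by the layer frequency), time-averaged
#' second-moment order parameters, frequency-cluster and splay flags with
#' partitions, interlayer locking, and the resulting state label.
#'
#' @param object a `duplex_trajectory`.
#' @param window averaging window `T` (time units); defaults to half the
#'   trajectory span.
#' @param delta frequency-cluster tolerance (rad/time).
#' @param splay_threshold time-averaged `R2` below which a
#'   frequency-synchronized layer counts as splay.
#' @param lock_tol interlayer locking tolerance (rad).
#' @param ... unused.
#' @return An object of class `"duplex_measures"`.
#' @examples
#' tr <- make_fixture("splay", N = 20, omega = 1)
#' summary(tr)
#' @export
summary.duplex_trajectory <- function(object, window = NULL, delta = 0.01,
                                      splay_threshold = 0.05,
                                      lock_tol = 0.01, ...) {
  span <- object$times[length(object$times)] - object$times[1L]
  if (is.null(window)) window <- span / 2
  v <- mean_phase_velocities(object, window)
  cl1 <- detect_frequency_cluster(v$v1, delta)
  cl2 <- detect_frequency_cluster(v$v2, delta)
  r2 <- r2_window(object, window)
  lock <- detect_interlayer_locking(object, window, lock_tol)
  s <- structure(
    list(mean_phase_velocity = list(v$v1, v$v2),
         layer_mean_frequency = c(v$omega1, v$omega2),
         freq_std = c(frequency_std(v$v1), frequency_std(v$v2)),
         freq_std_normalized = c(frequency_std(v$v1) / v$omega1,
                                 frequency_std(v$v2) / v$omega2),
         R2 = unname(r2),
         has_frequency_cluster = c(cl1$has_cluster, cl2$has_cluster),
         cluster_partition = list(cl1$partition, cl2$partition),
         is_splay = c(!cl1$has_cluster && unname(r2[1L]) < splay_threshold,
                      !cl2$has_cluster && unname(r2[2L]) < splay_threshold),
         interlayer_locked = lock$locked,
         locking_offsets = lock$offsets,
         window = v$window, delta = delta),
    class = "duplex_measures")
  s$label <- classify_state(s)
  s
}

#' Classify the asymptotic state
#'
#' Maps a measure summary to one of four labels:
#' \describe{
#'   \item{`frequency-cluster-pathological`}{the parenchyma holds a
#'     frequency cluster — organ-threatening desynchronization (sepsis).}
#'   \item{`immune-activated-parenchyma-healthy`}{parenchyma synchronized
#'     while the immune layer holds a cluster — persistent activation with
#'     parenchymal resilience.}
#'   \item{`splay-vulnerable`}{both layers frequency-synchronized with
#'     \eqn{R_2 \approx 0} in the parenchyma — healthy but vulnerable.}
#'   \item{`in-phase-healthy`}{both layers frequency-synchronized with high
#'     parenchymal phase coherence.}
#' }
#'
#' @param summary a `"duplex_measures"` object.
#' @return A single label string.
#' @export
classify_state <- function(summary) {
  if (summary$has_frequency_cluster[1L]) return("frequency-cluster-pathological")
  if (summary$has_frequency_cluster[2L]) return("immune-activated-parenchyma-healthy")
  if (summary$is_splay[1L]) return("splay-vulnerable")
  "in-phase-healthy"
}

#' @export
print.duplex_measures <- function(x, ...) {
  cat("Synchronization measures (trailing window", format(x$window), "time units)\n")
  cat(sprintf("  layer frequencies   omega1 = %.5f, omega2 = %.5f rad/time\n",
              x$layer_mean_frequency[1L], x$layer_mean_frequency[2L]))
  cat(sprintf("  freq. std sigma_chi %.3g / %.3g  (clusters: %s / %s)\n",
              x$freq_std[1L], x$freq_std[2L],
              x$has_frequency_cluster[1L], x$has_frequency_cluster[2L]))
  cat(sprintf("  time-averaged R2    %.4f / %.4f  (splay: %s / %s)\n",
              x$R2[1L], x$R2[2L], x$is_splay[1L], x$is_splay[2L]))
  cat(sprintf("  interlayer locked:  %s", x$interlayer_locked))
  if (x$interlayer_locked)
    cat(sprintf("  (mean offset %.4fpi)", mean(x$locking_offsets) / pi))
  cat("\n  state label:        ", x$label, "\n", sep = "")
  invisible(x)
}
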