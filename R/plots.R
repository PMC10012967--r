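#' Diagnostic panels for a simulated trajectory
#'
#' Renders the standard per-run diagnostic layout: snapshots of the two
#' cytokine weight matrices (colour-coded), the mean-phase-velocity profile
#' of both layers, a snapshot of the instantaneous phases (nodes sorted
#' first by mean phase velocity, then by phase), and a space--time plot of
#' the phases modulo \eqn{2\pi}.  A flat velocity profile with uniform
#' weight matrices signals the healthy synchronized state; a step in the
#' profile and an off-coloured block in the weight matrix mark a
#' pathological frequency cluster.
#'
#' @param x a `duplex_trajectory`.
#' @param window averaging window for the velocity profile (default half
#'   the span).
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.duplex_trajectory <- function(x, window = NULL, ...) {
  span <- x$times[length(x$times)] - x$times[1L]
  if (is.null(window)) window <- span / 2
  v <- mean_phase_velocities(x, window)
  N <- ncol(x$phi1)
  n <- length(x$times)
  ord1 <- order(v$v1, x$phi1[n, ] %% (2 * pi))
  ord2 <- order(v$v2, x$phi2[n, ] %% (2 * pi))

  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)

  graphics::image(seq_len(N), seq_len(N), x$kappa1, zlim = c(-1, 1),
                  col = pal, xlab = "j", ylab = "i",
                  main = expression(kappa^1 ~ "(parenchyma)"))
  graphics::image(seq_len(N), seq_len(N), x$kappa2, zlim = c(-1, 1),
                  col = pal, xlab = "j", ylab = "i",
                  main = expression(kappa^2 ~ "(immune)"))
  graphics::plot(seq_len(N), v$v1[ord1], pch = 19, cex = 0.5, col = "firebrick",
                 ylim = range(c(v$v1, v$v2)),
                 xlab = "node (sorted)", ylab = "mean phase velocity",
                 main = "frequency profile")
  graphics::points(seq_len(N), v$v2[ord2], pch = 19, cex = 0.5, col = "navy")
  graphics::legend("topleft", c("layer 1", "layer 2"), pch = 19, bty = "n",
                   col = c("firebrick", "navy"), cex = 0.8)
  graphics::plot(seq_len(N), (x$phi1[n, ] %% (2 * pi))[ord1], pch = 19,
                 cex = 0.5, col = "firebrick", ylim = c(0, 2 * pi),
                 xlab = "node (sorted)", ylab = expression(phi ~ mod ~ 2 * pi),
                 main = "phase snapshot")
  graphics::points(seq_len(N), (x$phi2[n, ] %% (2 * pi))[ord2], pch = 19,
                   cex = 0.5, col = "navy")
  # space-time plots on a thinned time grid
  keep <- unique(round(seq(1L, n, length.out = min(n, 400L))))
  graphics::image(x$times[keep], seq_len(N),
                  x$phi1[keep, ord1, drop = FALSE] %% (2 * pi),
                  col = grDevices::hcl.colors(64, "Viridis"),
                  xlab = "t", ylab = "node",
                  main = expression(phi^1 * "(t) space-time"))
  graphics::image(x$times[keep], seq_len(N),
                  x$phi2[keep, ord2, drop = FALSE] %% (2 * pi),
                  col = grDevices::hcl.colors(64, "Viridis"),
                  xlab = "t", ylab = "node",
                  main = expression(phi^2 * "(t) space-time"))
  invisible(x)
}

#' Heat maps of a regime map
#'
#' For a two-axis sweep, draws per-layer heat maps of the chosen statistic
#' in the swept parameter plane (bright colours = frequency clustering).
#' For a single-axis sweep, draws the statistic as curves per layer.
#'
#' @param x a `"regime_map"`.
#' @param stat one of `"s"`, `"s_norm"`, `"f"`, `"splay_ratio"`, `"R2"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.regime_map <- function(x, stat = c("f", "s", "s_norm", "splay_ratio", "R2"),
                            ...) {
  stat <- match.arg(stat)
  axes <- attr(x, "axes")
  df <- as.data.frame(x)
  if (nrow(df) == 0L) {
    warning("empty regime map; nothing to plot")
    return(invisible(x))
  }
  two_axes <- !is.null(axes$axis2)
  op <- graphics::par(mfrow = c(1, if (two_axes) 2 else 1),
                      mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  if (two_axes) {
    a1 <- sort(unique(df$axis1)); a2 <- sort(unique(df$axis2))
    for (ly in 1:2) {
      z <- matrix(NA_real_, length(a1), length(a2))
      sub <- df[df$layer == ly, ]
      z[cbind(match(sub$axis1, a1), match(sub$axis2, a2))] <- sub[[stat]]
      graphics::image(a1, a2, z, col = grDevices::hcl.colors(64, "Inferno"),
                      xlab = axes$axis1$param, ylab = axes$axis2$param,
                      main = sprintf("%s, layer %d", stat, ly))
    }
  } else {
    rng <- range(df[[stat]], na.rm = TRUE)
    sub1 <- df[df$layer == 1L, ]; sub2 <- df[df$layer == 2L, ]
    graphics::plot(sub1$axis1, sub1[[stat]], type = "b", pch = 19,
                   col = "firebrick", ylim = rng,
                   xlab = axes$axis1$param, ylab = stat,
                   main = sprintf("%s vs %s", stat, axes$axis1$param))
    graphics::lines(sub2$axis1, sub2[[stat]], type = "b", pch = 19,
                    col = "navy")
    graphics::legend("topleft", c("parenchyma", "immune"), pch = 19,
                     col = c("firebrick", "navy"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
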