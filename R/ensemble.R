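#' Run a seeded ensemble of simulations
#'
#' Integrates the model once per member seed from the perturbed random
#' initial conditions and summarizes each run, then aggregates: the
#' ensemble averages \eqn{s^\mu} of the frequency standard deviations, the
#' normalized variant, the frequency-cluster ratios \eqn{f^\mu} (fraction
#' of members whose layer holds a cluster — the probability proxy for a
#' pathological parenchyma / activated immune layer), splay-state ratios
#' and mean order parameters.  Aggregates are independent of member
#' execution order.  A failing member is recorded (with its error message)
#' and excluded from the aggregates rather than aborting the ensemble.
#'
#' @param model a [duplex_model()].
#' @param C immune activation cluster size for [generate_initial_state()].
#' @param seeds integer vector of member seeds (see [spawn_member_seeds()]).
#' @param t_end simulation horizon (time units).
#' @param window trailing averaging window `T` (time units).
#' @param sample_dt trajectory sampling interval.
#' @param delta frequency-cluster tolerance (rad/time).
#' @param ... further arguments passed to [simulate.duplex_model()].
#' @return An object of class `"duplex_ensemble"`: list with `members`
#'   (per-member `duplex_measures`, `NULL` where failed), `failed`
#'   (messages), and the aggregate fields `s`, `s_norm`, `f`,
#'   `splay_ratio`, `R2` (each length 2: parenchyma, immune) plus
#'   `n_members`, `n_ok`.
#' @examples
#' m <- duplex_model(N = 10, sigma = 1)
#' e <- run_ensemble(m, C = 2, seeds = spawn_member_seeds(1, 2),
#'                   t_end = 100, window = 50)
#' e$f
#' @export
run_ensemble <- function(model, C, seeds, t_end = 2000, window = 1000,
                         sample_dt = 0.5, delta = 0.01, ...) {
  if (length(seeds) < 1L) stop("'seeds' must be non-empty", call. = FALSE)
  members <- vector("list", length(seeds))
  failed <- character(0)
  for (k in seq_along(seeds)) {
    members[[k]] <- tryCatch({
      tr <- simulate(model, seed = seeds[k], C = C, t_end = t_end,
                     sample_dt = sample_dt, ...)
      summary(tr, window = window, delta = delta)
    }, error = function(e) {
      failed[[length(failed) + 1L]] <<-
        sprintf("seed %d: %s", seeds[k], conditionMessage(e))
      NULL
    })
  }
  ok <- !vapply(members, is.null, logical(1L))
  agg <- aggregate_members(members[ok])
  structure(c(list(members = members, seeds = seeds, failed = failed,
                   n_members = length(seeds), n_ok = sum(ok)),
              agg),
            class = "duplex_ensemble")
}

aggregate_members <- function(ms) {
  if (length(ms) == 0L)
    return(list(s = c(NA_real_, NA_real_), s_norm = c(NA_real_, NA_real_),
                f = c(NA_real_, NA_real_), splay_ratio = c(NA_real_, NA_real_),
                R2 = c(NA_real_, NA_real_)))
  get2 <- function(field) {
    m <- vapply(ms, function(x) as.double(x[[field]]), numeric(2L))
    rowMeans(m)
  }
  list(s = get2("freq_std"),
       s_norm = get2("freq_std_normalized"),
       f = rowMeans(vapply(ms, function(x)
         as.double(x$has_frequency_cluster), numeric(2L))),
       splay_ratio = rowMeans(vapply(ms, function(x)
         as.double(x$is_splay), numeric(2L))),
       R2 = get2("R2"))
}

#' @export
print.duplex_ensemble <- function(x, ...) {
  cat(sprintf("Seeded ensemble: %d members (%d ok)\n", x$n_members, x$n_ok))
  cat(sprintf("  s      = %.4g / %.4g  (parenchyma / immune)\n", x$s[1L], x$s[2L]))
  cat(sprintf("  f      = %.3f / %.3f  (frequency-cluster ratio)\n",
              x$f[1L], x$f[2L]))
  cat(sprintf("  splay  = %.3f / %.3f\n", x$splay_ratio[1L], x$splay_ratio[2L]))
  cat(sprintf("  mean R2 = %.3f / %.3f\n", x$R2[1L], x$R2[2L]))
  invisible(x)
}

#' Sweep one or two parameters over a seeded ensemble grid
#'
#' Runs [run_ensemble()] at every grid point of one or two swept parameters
#' and assembles a regime map.  Sweepable parameters: `"beta"` (age),
#' `"sigma"` (interlayer coupling), `"alpha_inter"` (interlayer lag, sets
#' `alpha12 = alpha21`), `"C"` (immune activation size, given as the
#' fraction `C/N`).  The identical member seed list (from the master seed)
#' is reused at every grid point, so each cell sees the same ensemble of
#' random initial conditions and differences across cells are attributable
#' to the parameters alone.
#'
#' @param model a [duplex_model()] supplying all non-swept parameters.
#' @param axis1 named list `list(param = <name>, values = <numeric>)`.
#' @param axis2 optional second axis in the same form.
#' @param n_ensemble ensemble size per grid point.
#' @param master_seed integer; member seeds are spawned from it once.
#' @param C_frac immune activation size as a fraction of `N` (used when `C`
#'   is not itself the swept parameter).
#' @param t_end,window,sample_dt,delta run controls, as in [run_ensemble()].
#' @param verbose print one progress line per grid cell.
#' @return An object of class `"regime_map"`: a data frame with one row per
#'   (cell, layer) and columns `axis1`, `axis2` (values of the swept
#'   parameters), `layer`, `s`, `s_norm`, `f`, `splay_ratio`, `R2`,
#'   `n_members`, plus attributes `axes` and `seeds`.
#' @examples
#' \donttest{
#' m <- duplex_model(N = 20)
#' rm_ <- sweep_grid(m, axis1 = list(param = "beta",
#'                                   values = c(0.45, 0.65) * pi),
#'                   n_ensemble = 2, master_seed = 1, t_end = 200,
#'                   window = 100)
#' }
#' @export
sweep_grid <- function(model, axis1, axis2 = NULL, n_ensemble = 10,
                       master_seed = 1, C_frac = 0.2,
                       t_end = 1000, window = 500, sample_dt = 0.5,
                       delta = 0.01, verbose = FALSE) {
  check_axis <- function(ax, nm) {
    if (!is.list(ax) || !all(c("param", "values") %in% names(ax)))
      stop(sprintf("'%s' must be list(param =, values =)", nm), call. = FALSE)
    ax$param <- match.arg(ax$param, c("beta", "sigma", "alpha_inter", "C"))
    if (!is.numeric(ax$values) || !all(is.finite(ax$values)))
      stop(sprintf("'%s$values' must be finite numeric", nm), call. = FALSE)
    ax
  }
  axis1 <- check_axis(axis1, "axis1")
  if (!is.null(axis2)) axis2 <- check_axis(axis2, "axis2")
  seeds <- spawn_member_seeds(master_seed, n_ensemble)

  v2 <- if (is.null(axis2)) NA_real_ else axis2$values
  grid <- expand.grid(a1 = axis1$values, a2 = v2, KEEP.OUT.ATTRS = FALSE)

  apply_param <- function(model, param, value) {
    switch(param,
      beta = { model$beta <- value; model },
      sigma = { model$sigma <- value; model },
      alpha_inter = { model$alpha12 <- value; model$alpha21 <- value; model },
      C = model)  # C acts on the initial condition, not the model
  }
  cell_C <- function(param, value, default_C) {
    if (param == "C") as.integer(round(value * model$N)) else default_C
  }

  default_C <- as.integer(round(C_frac * model$N))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    mg <- apply_param(model, axis1$param, grid$a1[g])
    Cg <- cell_C(axis1$param, grid$a1[g], default_C)
    if (!is.null(axis2)) {
      mg <- apply_param(mg, axis2$param, grid$a2[g])
      Cg <- cell_C(axis2$param, grid$a2[g], Cg)
    }
    e <- run_ensemble(mg, C = Cg, seeds = seeds, t_end = t_end,
                      window = window, sample_dt = sample_dt, delta = delta)
    rows[[g]] <- data.frame(
      axis1 = grid$a1[g], axis2 = grid$a2[g], layer = c(1L, 2L),
      s = e$s, s_norm = e$s_norm, f = e$f,
      splay_ratio = e$splay_ratio, R2 = e$R2, n_members = e$n_ok)
    if (verbose)
      message(sprintf("[%d/%d] %s = %.4g%s: f = %.2f / %.2f",
                      g, nrow(grid), axis1$param, grid$a1[g],
                      if (is.null(axis2)) "" else
                        sprintf(", %s = %.4g", axis2$param, grid$a2[g]),
                      e$f[1L], e$f[2L]))
  }
  out <- do.call(rbind, rows)
  structure(out,
            axes = list(axis1 = axis1, axis2 = axis2),
            seeds = seeds,
            controls = list(n_ensemble = n_ensemble, master_seed = master_seed,
                            C_frac = C_frac, t_end = t_end, window = window,
                            N = model$N),
            class = c("regime_map", "data.frame"))
}

#' Trailing moving average for regime-map curves
#'
#' Smooths a 1-D series with a trailing window of `window` points; at the
#' edges the window is truncated to the available neighbors (the first
#' value is untouched, the second averages two points, and so on).
#'
#' @param values numeric series.
#' @param window window length in points (default 4).
#' @return The smoothed series, same length as the input.
#' @examples
#' smooth_curve(c(0, 0, 0, 0, 4, 4, 4, 4))
#' @export
smooth_curve <- function(values, window = 4) {
  n <- length(values)
  if (n < window)
    stop(sprintf("series length %d shorter than window %d", n, window),
         call. = FALSE)
  vapply(seq_len(n), function(i)
    mean(values[max(1L, i - window + 1L):i]), numeric(1L))
}

#' Write a regime map as tidy CSV
#'
#' @param map a `"regime_map"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  df <- as.data.frame(map)
  axes <- attr(map, "axes")
  names(df)[names(df) == "axis1"] <- axes$axis1$param
  if (!is.null(axes$axis2))
    names(df)[names(df) == "axis2"] <- axes$axis2$param
  else df$axis2 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.regime_map <- function(x, ...) {
  axes <- attr(x, "axes")
  cat(sprintf("Regime map over %s%s: %d cells x 2 layers\n",
              axes$axis1$param,
              if (is.null(axes$axis2)) "" else paste0(" x ", axes$axis2$param),
              nrow(x) / 2L))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
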