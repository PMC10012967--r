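#' Parse an angle given in radians or in multiples of pi
#'
#' Configuration files and the command line quote angles the way the model
#' literature does, in units of \eqn{\pi}: the string suffix `"pi"` marks a
#' multiple (e.g. `"-0.28pi"`, `"0.5pi"`).  Plain numbers are taken as
#' radians.
#'
#' @param x numeric scalar (radians) or string with optional `"pi"` suffix.
#' @return The angle in radians.
#' @examples
#' parse_angle("-0.28pi")
#' parse_angle(0.5)
#' @export
parse_angle <- function(x) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x)) stop("angle must be a finite scalar")
    return(as.double(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("angle must be a number or a string like \"-0.28pi\"", call. = FALSE)
  s <- trimws(x)
  if (grepl("pi$", s)) {
    num <- sub("pi$", "", s)
    if (num %in% c("", "+", "-")) num <- paste0(num, "1")
    v <- suppressWarnings(as.numeric(num))
    if (is.na(v)) stop(sprintf("cannot parse angle '%s'", x), call. = FALSE)
    return(v * pi)
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop(sprintf("cannot parse angle '%s'", x), call. = FALSE)
  v
}

# full default configuration: the reference simulation settings
default_config <- function() {
  list(
    model = list(N = 200L, omega1 = 0, omega2 = 0,
                 alpha11 = -0.28 * pi, alpha22 = -0.28 * pi,
                 alpha12 = 0, alpha21 = 0,
                 beta = 0.5 * pi, eps1 = 0.03, eps2 = 0.3, sigma = 1),
    init = list(C = 40L, seed = 1L),
    integrator = list(t_end = 2000, sample_dt = 0.5, method = "adams",
                      rtol = 1e-6, atol = 1e-8),
    measures = list(window = 1000, delta = 0.01,
                    splay_threshold = 0.05, lock_tol = 0.01),
    ensemble = list(n_ensemble = 50L, master_seed = 1L)
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, validates every key against the schema of
#' known sections and fields, resolves all omitted fields to the reference
#' defaults (`N = 200`, `alpha11 = alpha22 = -0.28pi`,
#' `alpha12 = alpha21 = 0`, `eps1 = 0.03`, `eps2 = 0.3`,
#' `omega1 = omega2 = 0`, `C = 40`, `sigma = 1`, `beta = 0.5pi`,
#' `t_end = 2000`, averaging window 1000, ensemble size 50), and returns
#' the fully resolved configuration.  Angle-valued fields accept the
#' `"pi"`-suffix syntax of [parse_angle()].  Unknown sections or fields are
#' rejected with an error naming the offending key.
#'
#' @param path path to a JSON file; an empty object `{}` yields the full
#'   defaults.
#' @return A named list of class `"duplex_config"` with sections `model`,
#'   `init`, `integrator`, `measures`, `ensemble`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"model": {"beta": "0.6pi"}}', f)
#' cfg <- load_config(f)
#' cfg$model$beta / pi
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(raw) == 0L) raw <- list()
  defs <- default_config()
  angle_fields <- c("alpha11", "alpha22", "alpha12", "alpha21", "beta",
                    "omega1", "omega2")

  bad <- setdiff(names(raw), names(defs))
  if (length(bad))
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg <- defs
  for (sec in names(raw)) {
    fields <- raw[[sec]]
    if (!is.list(fields))
      stop(sprintf("config section '%s' must be an object", sec), call. = FALSE)
    bad <- setdiff(names(fields), names(defs[[sec]]))
    if (length(bad))
      stop(sprintf("unknown field(s) in section '%s': %s",
                   sec, paste(bad, collapse = ", ")), call. = FALSE)
    for (f in names(fields)) {
      v <- fields[[f]]
      if (f %in% angle_fields) v <- parse_angle(v)
      cfg[[sec]][[f]] <- v
    }
  }
  validate_config(cfg)
  class(cfg) <- "duplex_config"
  cfg
}

validate_config <- function(cfg) {
  m <- cfg$model
  # constructor re-checks all model invariants (N, eps > 0, sigma >= 0, ...)
  do.call(duplex_model, m)
  if (cfg$init$C <= 1 || cfg$init$C >= m$N)
    stop(sprintf("config field init.C: must satisfy 1 < C < N (C = %s, N = %s)",
                 cfg$init$C, m$N), call. = FALSE)
  if (cfg$integrator$t_end <= 0)
    stop("config field integrator.t_end: must be > 0", call. = FALSE)
  if (cfg$measures$window <= 0 || cfg$measures$window > cfg$integrator$t_end)
    stop("config field measures.window: must lie in (0, t_end]", call. = FALSE)
  if (cfg$ensemble$n_ensemble < 1)
    stop("config field ensemble.n_ensemble: must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Save a configuration as JSON
#'
#' Writes the resolved configuration so that `load_config(save_config(cfg))`
#' round-trips exactly.
#'
#' @param cfg a configuration list as returned by [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a model from a configuration
#'
#' @param cfg a `"duplex_config"`.
#' @return The [duplex_model()] described by `cfg$model`.
#' @export
config_model <- function(cfg) do.call(duplex_model, cfg$model)
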