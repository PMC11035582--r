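#' Reaction and population parameters for the Allee-based detection algorithm
#'
#' Bundles the rate and threshold constants shared by the Allee-based
#' algorithm and the three comparison algorithms. Units are fixed
#' package-wide: densities in mL^-1, rates in h^-1, time in h.
#'
#' @param kappa Hold (quorum-sensing amplification) rate constant, h^-1.
#' @param K Half-activation density of the Hill function, mL^-1.
#' @param n Hill coefficient (dimensionless); the bistability analysis
#'   requires `n > 1`.
#' @param rho Reset rate constant (H -> L decay), h^-1.
#' @param P Total population density, mL^-1 (cell replication and death are
#'   neglected, so P is conserved).
#' @param sigma_A Per-analyte detection rate coefficient, h^-1 per analyte
#'   unit.
#' @param sigma_err Erroneous (spurious) detection rate, h^-1.
#' @param kappa_bcast Relay rate constant of the broadcasting algorithm,
#'   mL h^-1. Its units differ from `kappa` (the relay reaction is
#'   bimolecular); the default `kappa / P` makes the maximal per-capita relay
#'   rate `kappa_bcast * P` equal to `kappa`, for comparability.
#'
#' @return An object of class `allee_params`: a named list with the fields
#'   above.
#' @examples
#' p <- allee_params()            # literature defaults
#' p2 <- allee_params(rho = 20)   # override one rate
#' @export
allee_params <- function(kappa = 35, K = 8e7, n = 4, rho = 14, P = 1.5e8,
                         sigma_A = 1, sigma_err = 0,
                         kappa_bcast = kappa / P) {
  p <- list(kappa = kappa, K = K, n = n, rho = rho, P = P,
            sigma_A = sigma_A, sigma_err = sigma_err,
            kappa_bcast = kappa_bcast)
  validate_allee_params(p)
  class(p) <- "allee_params"
  p
}

validate_allee_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("kappa", "K", "n", "rho", "P", "sigma_A", "sigma_err",
              "kappa_bcast")) {
    if (is.null(p[[f]]) || !num1(p[[f]]))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  # kappa = 0 is admitted as the set-reset nesting (no quorum feedback)
  if (p$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (p$K <= 0) stop("K must be > 0", call. = FALSE)
  if (p$rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (p$P <= 0) stop("P must be > 0", call. = FALSE)
  if (p$sigma_A < 0) stop("sigma_A must be >= 0", call. = FALSE)
  if (p$sigma_err < 0) stop("sigma_err must be >= 0", call. = FALSE)
  if (p$n <= 1) stop("Hill coefficient n must be > 1", call. = FALSE)
  if (p$kappa_bcast < 0) stop("kappa_bcast must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.allee_params <- function(x, ...) {
  cat("Allee-based detection algorithm parameters\n")
  cat(sprintf("  kappa   = %g h^-1   (Hold rate constant)\n", x$kappa))
  cat(sprintf("  rho     = %g h^-1   (Reset rate constant)\n", x$rho))
  cat(sprintf("  n       = %g        (Hill coefficient)\n", x$n))
  cat(sprintf("  K       = %g mL^-1  (half-activation density)\n", x$K))
  cat(sprintf("  P       = %g mL^-1  (total population density)\n", x$P))
  cat(sprintf("  sigma_A = %g h^-1 per analyte unit\n", x$sigma_A))
  cat(sprintf("  sigma_err = %g h^-1 (erroneous detection rate)\n",
              x$sigma_err))
  cat(sprintf("  kappa_bcast = %g mL h^-1 (broadcast relay rate)\n",
              x$kappa_bcast))
  invisible(x)
}

#' Write / read a parameter set as a flat key-value config file
#'
#' The file format is chosen from the extension: `.yaml`/`.yml` or `.json`.
#' Keys are the fields of [allee_params()]. A run is reproducible from its
#' config plus seed alone.
#'
#' @param p An `allee_params` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params` returns `path` invisibly; `read_params` returns an
#'   `allee_params` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(allee_params(), f)
#' read_params(f)
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "allee_params"))
  vals <- unclass(p)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(vals, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: '", ext, "'", call. = FALSE)
  }
  known <- names(formals(allee_params))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown parameter key in config: '", extra[1L], "'", call. = FALSE)
  do.call(allee_params, vals)
}

#' Combined rare-event detection rate
#'
#' The rate at which low-state cells switch to the high state, combining
#' genuine analyte detection and spurious switching:
#' `sigma = sigma_A * A + sigma_err`.
#'
#' @param A Analyte concentration (arbitrary analyte units), `A >= 0`.
#'   Vectorized.
#' @param p An [allee_params()] object.
#' @return Rate(s) in h^-1, linear and non-decreasing in `A`.
#' @examples
#' effective_sigma(2, allee_params(sigma_A = 1.5, sigma_err = 0.5))  # 3.5
#' @export
effective_sigma <- function(A, p) {
  stopifnot(inherits(p, "allee_params"))
  if (any(!is.finite(A)) || any(A < 0))
    stop("analyte concentration A must be finite and >= 0", call. = FALSE)
  p$sigma_A * A + p$sigma_err
}

#' Piecewise-constant analyte time-profile
#'
#' Describes the analyte concentration A(t) driving the time-varying
#' detection rate in transient and memory experiments.
#'
#' * `constant`: A(t) = amplitude for all t.
#' * `step_down`: A(t) = amplitude for t < t_step, then baseline.
#' * `pulse`: A(t) = baseline except amplitude on `[t_start, t_start + width)`.
#'
#' @param kind One of `"constant"`, `"step_down"`, `"pulse"`.
#' @param amplitude Analyte concentration during the active phase, >= 0.
#' @param t_step Step-down time, h (for `kind = "step_down"`).
#' @param t_start,width Pulse start and duration, h (for `kind = "pulse"`).
#' @param baseline Analyte concentration outside the active phase (default 0).
#' @return An `analyte_profile` object. Evaluate it with [analyte_at()].
#' @examples
#' pr <- analyte_profile("pulse", amplitude = 5, t_start = 1, width = 0.5)
#' analyte_at(pr, c(0.5, 1.2, 2))
#' @export
analyte_profile <- function(kind = c("constant", "step_down", "pulse"),
                            amplitude, t_step = NULL, t_start = NULL,
                            width = NULL, baseline = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.finite(amplitude), amplitude >= 0,
            is.numeric(baseline), baseline >= 0)
  breaks <- numeric(0)
  if (kind == "step_down") {
    if (is.null(t_step) || t_step < 0)
      stop("step_down profile needs t_step >= 0", call. = FALSE)
    breaks <- t_step
  } else if (kind == "pulse") {
    if (is.null(t_start) || is.null(width) || t_start < 0 || width <= 0)
      stop("pulse profile needs t_start >= 0 and width > 0", call. = FALSE)
    breaks <- c(t_start, t_start + width)
  }
  structure(list(kind = kind, amplitude = amplitude, t_step = t_step,
                 t_start = t_start, width = width, baseline = baseline,
                 breaks = breaks),
            class = "analyte_profile")
}

#' Evaluate an analyte profile
#'
#' @param profile An [analyte_profile()] object.
#' @param t Time(s), h, `t >= 0`. Vectorized.
#' @return Analyte concentration(s), finite and non-negative.
#' @export
analyte_at <- function(profile, t) {
  stopifnot(inherits(profile, "analyte_profile"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("time t must be finite and >= 0", call. = FALSE)
  with(profile, switch(kind,
    constant  = rep(amplitude, length(t)),
    step_down = ifelse(t < t_step, amplitude, baseline),
    pulse     = ifelse(t >= t_start & t < t_start + width, amplitude, baseline)
  ))
}

#' @export
print.analyte_profile <- function(x, ...) {
  cat("Analyte profile:", x$kind, "\n")
  cat("  amplitude:", x$amplitude, " baseline:", x$baseline, "\n")
  if (length(x$breaks)) cat("  breakpoints (h):", x$breaks, "\n")
  invisible(x)
}
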