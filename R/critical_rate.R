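#' Upper bracket rate for the critical-rate search
#'
#' Finds a detection rate at which the dynamics are monostable (exactly one
#' equilibrium), by doubling upward from the reset rate `rho`. Any rate at or
#' above the returned value is also monostable, so it is a valid right
#' bracket for the bisection in [binary_search_sigma_c()].
#'
#' @param p An [allee_params()] object; the bistability condition of
#'   [theorem1_condition()] must hold (otherwise even `sigma = 0` is
#'   monostable and no saddle-node exists).
#' @param max_doublings Safety cap on the doubling search.
#' @return A rate in h^-1 with exactly one equilibrium.
#' @export
sigma_utr <- function(p, max_doublings = 60L) {
  stopifnot(inherits(p, "allee_params"))
  if (!theorem1_condition(p)$satisfied)
    stop("bistability condition not satisfied: system is monostable at all sigma",
         call. = FALSE)
  s <- p$rho
  for (i in seq_len(max_doublings)) {
    if (length(find_equilibria(s, p)$roots) == 1L) return(s)
    s <- s * 2
  }
  stop("no monostable sigma found after ", max_doublings, " doublings",
       call. = FALSE)
}

#' Critical rare-event detection rate by binary search
#'
#' Locates the saddle-node rate `sigma_c` at which the low (negative
#' detection) and middle (unstable threshold) equilibria of the Allee-based
#' dynamics merge. Below `sigma_c` the system is bistable and spurious
#' detections die out; above it every trajectory converges to the high
#' (detected) state.
#'
#' The search starts from the interval \[0, [sigma_utr()]\] — three
#' equilibria at the left end, one at the right — and repeatedly bisects,
#' keeping the midpoint on the side matching its equilibrium count. It
#' terminates when the bracket is narrower than `precision`, or immediately
#' if a midpoint exhibits the two-solution (tangent double root) case.
#'
#' @param p An [allee_params()] object satisfying the bistability condition.
#' @param precision Requested bracket width, h^-1.
#' @param max_iter Iteration cap.
#' @return An object of class `critical_rate`: list with `sigma_c` (h^-1),
#'   `bracket` (final `c(low, high)`), `iterations`, `terminated_by`
#'   (`"precision"` or `"tangency"`), `feasible`, `precision`.
#' @examples
#' \donttest{
#' binary_search_sigma_c(allee_params())  # sigma_c ~ 3.05 h^-1
#' }
#' @export
binary_search_sigma_c <- function(p, precision = 1e-3, max_iter = 64L) {
  stopifnot(inherits(p, "allee_params"), precision > 0)
  hi <- sigma_utr(p)             # errors out when infeasible
  lo <- 0
  it <- 0L
  terminated_by <- "precision"
  while (hi - lo >= precision && it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    eq <- find_equilibria(mid, p)
    if (any(eq$stability == "tangent")) {
      lo <- hi <- mid
      terminated_by <- "tangency"
      break
    }
    if (length(eq$roots) >= 3L) lo <- mid else hi <- mid
  }
  structure(list(sigma_c = (lo + hi) / 2, bracket = c(lo, hi),
                 iterations = it, terminated_by = terminated_by,
                 feasible = TRUE, precision = precision),
            class = "critical_rate")
}

#' @export
print.critical_rate <- function(x, ...) {
  cat(sprintf("Critical detection rate sigma_c = %.6g h^-1\n", x$sigma_c))
  cat(sprintf("  bracket [%.6g, %.6g], %d iterations, terminated by %s\n",
              x$bracket[1L], x$bracket[2L], x$iterations, x$terminated_by))
  invisible(x)
}

#' Critical-rate sweep over (kappa, rho) grids
#'
#' Computes `sigma_c` for every combination of hold rate `kappa` and reset
#' rate `rho` at fixed total density `P`, encoding infeasible cells (where
#' the bistability condition fails, typically `rho` dominating `kappa`) as
#' 0. Cells are computed in a fixed order, so grids are reproducible
#' bit-for-bit.
#'
#' @param kappa_values,rho_values Positive rate grids, h^-1.
#' @param p_base An [allee_params()] object supplying `K`, `n`, `P`.
#' @param precision Bisection precision per cell, h^-1.
#' @return Object of class `sigma_c_sweep`: list with `kappa_values`,
#'   `rho_values`, `P`, `precision` and `matrix`
#'   (`length(kappa_values)` x `length(rho_values)`, entries >= 0).
#' @export
sweep_sigma_c <- function(kappa_values, rho_values, p_base = allee_params(),
                          precision = 1e-3) {
  stopifnot(length(kappa_values) >= 1L, length(rho_values) >= 1L,
            all(kappa_values > 0), all(rho_values > 0))
  m <- matrix(0, nrow = length(kappa_values), ncol = length(rho_values),
              dimnames = list(kappa = signif(kappa_values, 8),
                              rho = signif(rho_values, 8)))
  for (i in seq_along(kappa_values)) {
    for (j in seq_along(rho_values)) {
      p <- allee_params(kappa = kappa_values[i], K = p_base$K, n = p_base$n,
                        rho = rho_values[j], P = p_base$P,
                        sigma_A = p_base$sigma_A,
                        sigma_err = p_base$sigma_err)
      if (theorem1_condition(p)$satisfied) {
        m[i, j] <- binary_search_sigma_c(p, precision = precision)$sigma_c
      }                                   # else infeasible: stays 0
    }
  }
  structure(list(kappa_values = kappa_values, rho_values = rho_values,
                 P = p_base$P, precision = precision, matrix = m),
            class = "sigma_c_sweep")
}

#' Default log-spaced sweep grid
#'
#' @param n Number of points.
#' @param from,to Range, h^-1.
#' @return Log-spaced rate grid.
#' @export
sweep_grid <- function(n = 64L, from = 1, to = 100) {
  exp(seq(log(from), log(to), length.out = n))
}

#' @export
print.sigma_c_sweep <- function(x, ...) {
  cat(sprintf("sigma_c sweep: %d kappa x %d rho at P = %g mL^-1\n",
              length(x$kappa_values), length(x$rho_values), x$P))
  cat(sprintf("  feasible cells: %d / %d; max sigma_c = %.4g h^-1\n",
              sum(x$matrix > 0), length(x$matrix), max(x$matrix)))
  invisible(x)
}

#' @describeIn sweep_sigma_c Heat-map rendering of a sweep (to the active
#'   graphics device; side-effect-free if none is open beyond the device).
#' @param x A `sigma_c_sweep` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sigma_c_sweep <- function(x, ...) {
  graphics::image(x = log10(x$kappa_values), y = log10(x$rho_values),
                  z = x$matrix,
                  xlab = "log10 kappa (h^-1)", ylab = "log10 rho (h^-1)",
                  main = "critical rate sigma_c (0 = infeasible)", ...)
  invisible(x)
}

#' Write a sweep grid as CSV plus a JSON sidecar
#'
#' The CSV carries kappa rows and rho columns with `#`-prefixed header
#' comments; the sidecar records `P` and the bisection precision.
#'
#' @param sweep A `sigma_c_sweep` object.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sigma_c_sweep"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sigma_c sweep grid (h^-1); rows = kappa, columns = rho; 0 = infeasible",
    sprintf("# P = %.8g mL^-1, precision = %g h^-1, package alleeSensor %s",
            sweep$P, sweep$precision,
            as.character(utils::packageVersion("alleeSensor")))), con)
  df <- data.frame(kappa = sweep$kappa_values, sweep$matrix,
                   check.names = FALSE)
  names(df) <- c("kappa", format(sweep$rho_values, trim = TRUE))
  utils::write.csv(df, con, row.names = FALSE)
  jsonlite::write_json(list(P = sweep$P, precision = sweep$precision,
                            kappa_values = sweep$kappa_values,
                            rho_values = sweep$rho_values),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
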