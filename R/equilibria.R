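#' Equilibria of the Allee-based detection dynamics
#'
#' Finds all roots of `dH/dt = 0` for the Allee-based algorithm in
#' \[0, P\] at a fixed rare-event detection rate `sigma`, and classifies
#' each as stable, unstable or tangent (double root at a saddle-node).
#'
#' For integer Hill coefficients the denominator is cleared, giving a
#' degree-(n+1) polynomial in the dimensionless density x = H/P:
#' `(sigma (1 - x) - rho x)(x^n + k^n) + kappa x^n (1 - x) = 0` with
#' `k = K/P`; its roots come from the companion matrix (`polyroot`), so no
#' root can be missed. For non-integer `n` a dense sign-change scan with
#' bisection refinement is used instead.
#'
#' @param sigma Rare-event detection rate, h^-1, `sigma >= 0`.
#' @param p An [allee_params()] object.
#' @param grid_n Scan resolution for the non-integer-`n` fallback.
#' @return An object of class `equilibrium_set` with fields:
#'   \describe{
#'     \item{sigma}{the rate analysed}
#'     \item{roots}{sorted root densities, mL^-1, deduplicated at 1e-6 P}
#'     \item{stability}{per-root label: `"stable"`, `"unstable"` or
#'       `"tangent"`}
#'     \item{H_c_sigma}{the middle (unstable) root when three roots exist —
#'       the detection threshold density at this sigma — otherwise `NA`}
#'     \item{H_c_0}{at `sigma = 0` only: the second lowest non-negative
#'       root, i.e. the unstable threshold of the undriven system}
#'     \item{residuals}{|dH/dt| at each root (certification)}
#'   }
#' @examples
#' eq <- find_equilibria(1.5, allee_params())
#' eq$roots / 1e8   # low ~0.149, middle, high ~0.965
#' @export
find_equilibria <- function(sigma, p, grid_n = 8192L) {
  stopifnot(inherits(p, "allee_params"))
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be finite and >= 0", call. = FALSE)

  k <- p$K / p$P
  # dimensionless rhs: f(x) = dH/dt / P at H = x P
  f <- function(x) {
    act <- ifelse(x > 0, 1 / (1 + (k / x)^p$n), 0)
    (sigma + p$kappa * act) * (1 - x) - p$rho * x
  }

  n_int <- abs(p$n - round(p$n)) < 1e-12 && p$kappa > 0
  if (n_int) {
    n <- as.integer(round(p$n))
    co <- numeric(n + 2L)                    # ascending powers of x
    co[1L] <- sigma * k^n
    co[2L] <- -(sigma + p$rho) * k^n
    co[n + 1L] <- co[n + 1L] + sigma + p$kappa
    co[n + 2L] <- co[n + 2L] - (sigma + p$rho) - p$kappa
    z <- polyroot(co)
    x <- Re(z)[abs(Im(z)) < 1e-6 * pmax(1, Mod(z))]
    x <- x[x >= -1e-9 & x <= 1 + 1e-9]
    x <- sort(pmin(pmax(x, 0), 1))
  } else {
    xs <- seq(0, 1, length.out = grid_n + 1L)
    v <- f(xs)
    x <- numeric(0)
    if (abs(v[1L]) == 0) x <- 0        # H = 0 is a root only when sigma = 0
    sc <- which(v[-1L] * v[-length(v)] < 0)
    for (i in sc) {
      r <- stats::uniroot(f, c(xs[i], xs[i + 1L]), tol = 1e-14)$root
      x <- c(x, r)
    }
    # exact zeros on grid nodes (rare): treat as roots
    x <- sort(unique(c(x, xs[v == 0])))
  }

  # deduplicate at 1e-6 of the population scale
  if (length(x) > 1L) x <- x[c(TRUE, diff(x) > 1e-6)]
  roots <- x * p$P

  eps <- 1e-5
  stab <- character(length(x))
  for (i in seq_along(x)) {
    left <- if (x[i] - eps > 0) f(x[i] - eps) else Inf   # boundary: inflow
    right <- if (x[i] + eps < 1) f(x[i] + eps) else -Inf
    stab[i] <- if (left > 0 && right < 0) "stable"
               else if (left < 0 && right > 0) "unstable"
               else "tangent"
  }

  resid <- abs(f(x)) * p$P
  tol <- 1e-6 * (sigma + p$kappa + p$rho) * p$P + 1e-9
  if (any(resid > tol))
    stop("root certification failed: residual ", max(resid),
         " exceeds tolerance ", tol, call. = FALSE)

  H_c_sigma <- if (length(roots) == 3L && stab[2L] == "unstable")
    roots[2L] else NA_real_
  H_c_0 <- if (sigma == 0 && length(roots) >= 2L) roots[2L] else NA_real_

  structure(list(sigma = sigma, roots = roots, stability = stab,
                 H_c_sigma = H_c_sigma, H_c_0 = H_c_0, residuals = resid),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Equilibria at sigma = %g h^-1: %d root(s)\n",
              x$sigma, length(x$roots)))
  for (i in seq_along(x$roots))
    cat(sprintf("  H = %.6g mL^-1  [%s]\n", x$roots[i], x$stability[i]))
  if (!is.na(x$H_c_sigma))
    cat(sprintf("  threshold H_c = %.6g mL^-1\n", x$H_c_sigma))
  invisible(x)
}

#' @export
format.equilibrium_set <- function(x, ...) {
  paste0("equilibrium_set(sigma=", x$sigma, ", k=", length(x$roots), ")")
}

#' Serialize an equilibrium set to JSON
#'
#' @param x An `equilibrium_set` or `feasibility_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
equilibria_json <- function(x, path = NULL) {
  obj <- unclass(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Bistability feasibility condition
#'
#' Checks the condition under which the Allee-based algorithm is bistable at
#' `sigma = 0`: the undriven net birth rate
#' `g(H) = kappa H^n/(H^n + K^n) (P - H) - rho H` must be positive somewhere
#' on \[0, P\]. When it holds, the undriven system has three equilibria
#' `0 < alpha_i P < alpha_f P`, defining the detection threshold fraction
#' `alpha_i` and the detected-state floor fraction `alpha_f`.
#'
#' `g_max` is located by a coarse grid (4096 points) followed by local
#' refinement with `optimize`; Hill-type `g` has at most a few interior
#' extrema, so the grid cannot skip the global maximum basin.
#'
#' @param p An [allee_params()] object.
#' @param grid_n Coarse grid resolution.
#' @return An object of class `feasibility_report` with fields `g_max`
#'   (mL^-1 h^-1), `H_at_max` (mL^-1), `satisfied` (logical), `alpha_i`,
#'   `alpha_f` (fractions in \]0,1\[, `NA` when not satisfied).
#' @examples
#' theorem1_condition(allee_params())$satisfied        # TRUE
#' theorem1_condition(allee_params(kappa = 1, rho = 100))$satisfied  # FALSE
#' @export
theorem1_condition <- function(p, grid_n = 4096L) {
  stopifnot(inherits(p, "allee_params"))
  g <- function(H) allee_rhs(H, 0, p)
  Hs <- seq(0, p$P, length.out = grid_n + 1L)
  v <- g(Hs)
  i <- which.max(v)
  lo <- Hs[max(i - 1L, 1L)]; hi <- Hs[min(i + 1L, length(Hs))]
  opt <- stats::optimize(g, c(lo, hi), maximum = TRUE,
                         tol = 1e-10 * p$P + 1e-12)
  g_max <- max(opt$objective, v[i])
  H_at_max <- if (opt$objective >= v[i]) opt$maximum else Hs[i]
  satisfied <- g_max > 0

  alpha_i <- alpha_f <- NA_real_
  if (satisfied) {
    eq0 <- find_equilibria(0, p)
    if (length(eq0$roots) >= 3L) {
      alpha_i <- eq0$roots[2L] / p$P
      alpha_f <- eq0$roots[3L] / p$P
    }
  }
  structure(list(g_max = g_max, H_at_max = H_at_max, satisfied = satisfied,
                 alpha_i = alpha_i, alpha_f = alpha_f),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("Bistability feasibility:", if (x$satisfied) "satisfied" else
      "NOT satisfied", "\n")
  cat(sprintf("  max g(H) = %.6g mL^-1 h^-1 at H = %.6g mL^-1\n",
              x$g_max, x$H_at_max))
  if (x$satisfied)
    cat(sprintf("  alpha_i = %.4f, alpha_f = %.4f\n", x$alpha_i, x$alpha_f))
  invisible(x)
}

#' Threshold and detected-state fractions of the undriven system
#'
#' Returns `alpha_i` (unstable threshold fraction) and `alpha_f` (lowest
#' detected-state fraction): the middle and high roots of the undriven
#' dynamics, divided by P. Populations pushed above `alpha_i * P` converge
#' to at least `alpha_f * P` even after the analyte is removed (memory).
#'
#' @param p An [allee_params()] object; the bistability condition must hold.
#' @return Named numeric vector `c(alpha_i = , alpha_f = )` with
#'   `0 < alpha_i < alpha_f < 1`.
#' @export
alpha_bounds <- function(p) {
  rep_ <- theorem1_condition(p)
  if (!rep_$satisfied)
    stop("bistability condition not satisfied: no alpha_i/alpha_f exist",
         call. = FALSE)
  if (is.na(rep_$alpha_i))
    stop("undriven system does not have three distinct equilibria",
         call. = FALSE)
  c(alpha_i = rep_$alpha_i, alpha_f = rep_$alpha_f)
}

#' Unstable threshold density at a given detection rate
#'
#' The middle (unstable) equilibrium separating the two basins of
#' attraction: trajectories started below it converge to the low (negative
#' detection) state, above it to the high (positive detection) state.
#' Absent (`NA`) when the system is monostable at this `sigma`.
#'
#' @param sigma Rare-event detection rate, h^-1.
#' @param p An [allee_params()] object.
#' @return Density in mL^-1, or `NA_real_` when no unstable root exists.
#' @export
critical_point <- function(sigma, p) {
  find_equilibria(sigma, p)$H_c_sigma
}
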