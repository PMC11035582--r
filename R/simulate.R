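#' Integrate a detection-algorithm model over time
#'
#' Solves the chosen model ODE with a stiff-capable adaptive integrator
#' (`deSolve::lsoda`) under a constant detection rate or a time-varying
#' analyte profile. Piecewise-constant profiles are integrated segment by
#' segment with the solver restarted at each discontinuity, since adaptive
#' steppers mis-handle jumps otherwise.
#'
#' @param model One of `"allee"`, `"set_reset"`, `"broadcast"`,
#'   `"dist_amp"`.
#' @param p An [allee_params()] object.
#' @param sigma Either a constant rate (h^-1) or an [analyte_profile()]; a
#'   profile is converted to `sigma(t)` through [effective_sigma()].
#' @param H0 Initial high-state density, mL^-1 (default 0: all cells start
#'   undecided in the low state).
#' @param S0 Initial reporter density (dist_amp only).
#' @param t_end Integration horizon, h.
#' @param n_out Number of output grid points (dense output for
#'   threshold-crossing interpolation).
#' @param rtol,atol Solver tolerances. The defaults (1e-8 relative, 1 mL^-1
#'   absolute at a state scale of 1e8) resolve the near-tangency bottleneck
#'   at rates close to the critical rate.
#' @return Object of class `allee_trajectory`: list with `times` (h), `H`
#'   (mL^-1), `S` (mL^-1 or `NULL`), `sigma` (h^-1 per sample),
#'   `steady_state` (terminal H, or terminal S for dist_amp), `converged`
#'   (|dH/dt| below 1e-6 rho P at the end), `convergence_time` (h, time to
#'   95% of the terminal value when converged; see [convergence_time()]),
#'   plus `model`, `p`, `H0`, `t_end`.
#' @examples
#' tr <- integrate_model("allee", allee_params(), sigma = 4, t_end = 2)
#' tr$steady_state / 1e8   # ~1.01
#' @export
integrate_model <- function(model = c("allee", "set_reset", "broadcast",
                                      "dist_amp"),
                            p, sigma, H0 = 0, S0 = 0, t_end,
                            n_out = 2001L, rtol = 1e-8, atol = 1) {
  model <- match.arg(model)
  stopifnot(inherits(p, "allee_params"), t_end > 0)
  if (H0 < 0 || H0 > p$P) stop("H0 must lie in [0, P]", call. = FALSE)
  if (S0 < 0) stop("S0 must be >= 0", call. = FALSE)

  profile <- NULL
  if (inherits(sigma, "analyte_profile")) {
    profile <- sigma
  } else {
    stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  }
  sigma_at <- function(t) {
    if (is.null(profile)) rep(sigma, length(t))
    else effective_sigma(analyte_at(profile, t), p)
  }

  breaks <- if (is.null(profile)) numeric(0) else
    profile$breaks[profile$breaks > 0 & profile$breaks < t_end]
  times <- sort(unique(c(seq(0, t_end, length.out = n_out), breaks)))
  seg_bounds <- c(0, breaks, t_end)

  deriv <- switch(model,
    allee = function(t, y, s) {
      H <- min(max(y[1L], 0), p$P)
      list((s + p$kappa * hill_activation(H, p$K, p$n)) * (p$P - H) -
           p$rho * H)
    },
    set_reset = function(t, y, s) {
      H <- min(max(y[1L], 0), p$P)
      list(s * (p$P - H) - p$rho * H)
    },
    broadcast = function(t, y, s) {
      H <- min(max(y[1L], 0), p$P)
      list((s + p$kappa_bcast * H) * (p$P - H))
    },
    dist_amp = function(t, y, s) {
      H <- min(max(y[1L], 0), p$P)
      S <- max(y[2L], 0)
      list(c(s * (p$P - H) - p$rho * H,
             p$kappa * hill_activation(H, p$K, p$n) * p$P - p$rho * S))
    })

  y <- if (model == "dist_amp") c(H = H0, S = S0) else c(H = H0)
  out_t <- numeric(0); out_y <- NULL
  for (k in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1L]
    seg_times <- sort(unique(c(a, times[times >= a & times <= b], b)))
    s_seg <- sigma_at((a + b) / 2)   # constant within a segment
    sol <- deSolve::lsoda(y = y, times = seg_times,
                          func = function(t, y, parms) deriv(t, y, s_seg),
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed for model '", model, "' at t in [", a, ", ",
           b, "]", call. = FALSE)
    keep <- if (k == 1L) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1L])
    out_y <- rbind(out_y, sol[keep, -1L, drop = FALSE])
    y <- sol[nrow(sol), -1L]
  }

  H <- pmin(pmax(out_y[, 1L], 0), p$P)
  if (any(out_y[, 1L] < -1e-7 * p$P) || any(out_y[, 1L] > p$P * (1 + 1e-7)))
    stop("integration left the physical domain [0, P]", call. = FALSE)
  S <- if (model == "dist_amp") pmax(out_y[, 2L], 0) else NULL
  sig <- sigma_at(out_t)

  terminal <- if (model == "dist_amp") S[length(S)] else H[length(H)]
  dend <- deriv(out_t[length(out_t)], out_y[nrow(out_y), ],
                sig[length(sig)])[[1L]]
  converged <- abs(dend[1L]) < 1e-6 * p$rho * p$P

  traj <- structure(list(model = model, times = out_t, H = H, S = S,
                         sigma = sig, p = p, H0 = H0, t_end = t_end,
                         steady_state = terminal, converged = converged,
                         convergence_time = NA_real_),
                    class = "allee_trajectory")
  if (converged && is.null(profile)) {
    ref <- H[length(H)]
    traj$convergence_time <- if (ref <= 0) 0 else
      tryCatch(convergence_time(traj, ref), error = function(e) NA_real_)
  }
  traj
}

#' @export
print.allee_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: t in [0, %g] h, %d samples\n",
              x$model, x$t_end, length(x$times)))
  cat(sprintf("  H(0) = %.4g -> H(end) = %.4g mL^-1 (%s)\n",
              x$H0, x$H[length(x$H)],
              if (x$converged) "converged" else "not converged"))
  if (!is.na(x$convergence_time))
    cat(sprintf("  95%% convergence time: %.3g h\n", x$convergence_time))
  invisible(x)
}

#' @export
plot.allee_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$H, type = "l", xlab = "time (h)",
                 ylab = "H (mL^-1)", main = paste(x$model, "trajectory"),
                 ...)
  invisible(x)
}

#' Steady state under a constant detection rate
#'
#' Integrates until the rate of change falls below
#' `eps_ss * rho * P` sustained over a 0.1 h window, or a hard time cap is
#' hit. The returned value is the model's reporter output: the terminal H
#' density for the three two-state models, the terminal reporter density S
#' for the distributed-amplification model.
#'
#' @param model,p,sigma,H0,S0 As in [integrate_model()] (`sigma` constant).
#' @param eps_ss Relative stopping threshold on |dH/dt| (and |dS/dt|).
#' @param t_cap Hard cap on simulated time, h.
#' @return Reporter density in mL^-1, with attributes `state` (named vector
#'   of terminal densities), `converged` (logical) and `time` (h simulated).
#' @examples
#' steady_state("allee", allee_params(), sigma = 1.5)  # ~0.149e8
#' @export
steady_state <- function(model = c("allee", "set_reset", "broadcast",
                                   "dist_amp"),
                         p, sigma, H0 = 0, S0 = 0, eps_ss = 1e-6,
                         t_cap = 1000) {
  model <- match.arg(model)
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  thr_H <- eps_ss * p$rho * p$P
  thr_S <- eps_ss * max(p$kappa, p$rho) * p$P
  t_done <- 0; chunk <- 1
  H <- H0; S <- S0
  converged <- FALSE
  while (t_done < t_cap) {
    chunk <- min(chunk, t_cap - t_done)
    tr <- integrate_model(model, p, sigma, H0 = H, S0 = S, t_end = chunk,
                          n_out = 401L)
    nlast <- length(tr$times)
    H <- tr$H[nlast]
    if (model == "dist_amp") S <- tr$S[nlast]
    t_done <- t_done + chunk
    # sustained stationarity over the trailing 0.1 h of the chunk
    win <- tr$times >= chunk - min(0.1, chunk / 2)
    dH <- if (model == "dist_amp")
      dist_amp_rhs(tr$H[win], tr$S[win], sigma, p) else
      switch(model,
             allee = allee_rhs(tr$H[win], sigma, p),
             set_reset = set_reset_rhs(tr$H[win], sigma, p),
             broadcast = broadcast_rhs(tr$H[win], sigma, p))
    ok <- if (model == "dist_amp")
      all(abs(dH$dH) < thr_H) && all(abs(dH$dS) < thr_S) else
      all(abs(dH) < thr_H)
    if (ok) { converged <- TRUE; break }
    chunk <- min(chunk * 2, 50)
  }
  val <- if (model == "dist_amp") S else H
  state <- if (model == "dist_amp") c(H = H, S = S) else c(H = H)
  structure(val, state = state, converged = converged, time = t_done)
}

#' Time to reach 95% of a steady-state density
#'
#' First time at which the trajectory reaches 95% of the given steady-state
#' density, located by linear interpolation on the dense solver output.
#' Returns 0 for a zero steady state.
#'
#' @param traj An `allee_trajectory` from [integrate_model()].
#' @param steady Steady-state density, mL^-1.
#' @return Time in h.
#' @examples
#' p <- allee_params()
#' tr <- integrate_model("allee", p, sigma = 5, t_end = 2)
#' convergence_time(tr, tr$steady_state)   # ~0.29 h
#' @export
convergence_time <- function(traj, steady) {
  stopifnot(inherits(traj, "allee_trajectory"))
  if (steady == 0) return(0)
  thr <- 0.95 * steady
  idx <- which(traj$H >= thr)
  if (!length(idx))
    stop("trajectory never reaches 95% of the steady state", call. = FALSE)
  i <- idx[1L]
  if (i == 1L) return(traj$times[1L])
  t0 <- traj$times[i - 1L]; t1 <- traj$times[i]
  h0 <- traj$H[i - 1L]; h1 <- traj$H[i]
  t0 + (thr - h0) / (h1 - h0) * (t1 - t0)
}

#' Analyte memory experiment
#'
#' Drives the Allee-based algorithm through a transient analyte profile
#' (which must end at zero analyte), then observes the population for a
#' post-removal window of several reset time-constants. The exposure is
#' memorized when the final density stays at or above the detected-state
#' floor `alpha_f * P`.
#'
#' @param p An [allee_params()] object satisfying the bistability condition.
#' @param profile An [analyte_profile()] ending at baseline 0.
#' @param H0 Initial density, mL^-1.
#' @param post_window Post-removal observation window, h (default
#'   `10 / rho`).
#' @return Object of class `memory_outcome`: list with `profile`,
#'   `memorized` (logical), `final_H`, `alpha_f` and the full `trajectory`.
#' @export
memory_experiment <- function(p, profile, H0 = 0, post_window = 10 / p$rho) {
  stopifnot(inherits(p, "allee_params"), inherits(profile, "analyte_profile"))
  prof_end <- if (length(profile$breaks)) max(profile$breaks) else 0
  if (analyte_at(profile, prof_end + 1) != 0)
    stop("memory experiment requires a profile ending at 0 analyte",
         call. = FALSE)
  ab <- alpha_bounds(p)
  t_end <- prof_end + post_window
  tr <- integrate_model("allee", p, profile, H0 = H0, t_end = t_end)
  final_H <- tr$H[length(tr$H)]
  structure(list(profile = profile,
                 memorized = unname(final_H >= ab[["alpha_f"]] * p$P),
                 final_H = final_H, alpha_f = unname(ab["alpha_f"]),
                 trajectory = tr),
            class = "memory_outcome")
}

#' @export
print.memory_outcome <- function(x, ...) {
  cat(sprintf("Memory experiment (%s profile): %s\n", x$profile$kind,
              if (x$memorized) "MEMORIZED" else "not memorized"))
  cat(sprintf("  final H = %.4g mL^-1 (alpha_f P = %.4g mL^-1)\n",
              x$final_H, x$alpha_f * x$trajectory$p$P))
  invisible(x)
}

#' Dose-response comparison of the four algorithms
#'
#' Steady-state reporter output over a grid of analyte concentrations, all
#' runs started from H(0) = 0 (and S(0) = 0), with
#' `sigma = effective_sigma(A, p)`. The reporter is H for the Allee-based,
#' set-reset and broadcasting algorithms and S for distributed
#' amplification.
#'
#' @param p An [allee_params()] object.
#' @param analyte_values Non-empty analyte concentration grid.
#' @param algorithms Algorithms to include.
#' @return Object of class `comparison_curve`: a data frame with column `A`
#'   and one non-negative steady-state column per algorithm.
#' @export
dose_response <- function(p, analyte_values,
                          algorithms = c("allee", "set_reset", "broadcast",
                                         "dist_amp")) {
  stopifnot(length(analyte_values) >= 1L, all(analyte_values >= 0))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  out <- data.frame(A = analyte_values)
  for (alg in algorithms) {
    out[[alg]] <- vapply(analyte_values, function(A) {
      as.numeric(steady_state(alg, p, effective_sigma(A, p)))
    }, numeric(1L))
  }
  structure(out, class = c("comparison_curve", "data.frame"),
            params = p)
}

#' @export
plot.comparison_curve <- function(x, ...) {
  algs <- setdiff(names(x), "A")
  graphics::matplot(x$A, as.matrix(x[algs]), type = "l", lty = 1,
                    xlab = "analyte concentration A",
                    ylab = "steady-state reporter density (mL^-1)", ...)
  graphics::legend("bottomright", legend = algs, lty = 1,
                   col = seq_along(algs))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns `t, H, L, sigma` (plus `S` for distributed amplification), with
#' `#`-prefixed header comments carrying the parameter provenance.
#'
#' @param traj An `allee_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "allee_trajectory"))
  p <- traj$p
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s model trajectory; t in h, densities in mL^-1, sigma in h^-1",
            traj$model),
    sprintf("# kappa=%g rho=%g n=%g K=%g P=%g sigma_A=%g sigma_err=%g",
            p$kappa, p$rho, p$n, p$K, p$P, p$sigma_A, p$sigma_err),
    sprintf("# package alleeSensor %s",
            as.character(utils::packageVersion("alleeSensor")))), con)
  df <- data.frame(t = traj$times, H = traj$H, L = p$P - traj$H,
                   sigma = traj$sigma)
  if (!is.null(traj$S)) df$S <- traj$S
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
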