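#' Exact stochastic simulation of a birth-death noise process
#'
#' Event-driven (Gillespie) simulation of the auxiliary noise species that
#' models stochastically fluctuating spurious detections: constant-rate
#' births (`0 -> A` at rate `beta`) and per-capita deaths (`A -> 0` at rate
#' `gamma` per copy), started from count 0. The stationary distribution of
#' this process is Poisson with mean `beta / gamma`. Reproducible from its
#' integer seed (Mersenne-Twister, exponential next-event times).
#'
#' @param beta Birth rate, h^-1, `beta >= 0`.
#' @param gamma Per-capita death rate, h^-1, `gamma > 0`.
#' @param t_end Simulated horizon, h.
#' @param seed Integer seed.
#' @return Object of class `noise_trajectory`: list with `event_times`
#'   (strictly increasing, all <= `t_end`), `counts` (copy number after
#'   each event, changes by +-1), `beta`, `gamma`, `seed`, `t_end`.
#' @examples
#' nz <- simulate_birth_death(0.5, 2, t_end = 100, seed = 1)
#' noise_time_average(nz)   # near beta/gamma = 0.25
#' @export
simulate_birth_death <- function(beta, gamma, t_end, seed) {
  stopifnot(beta >= 0, gamma > 0, t_end > 0,
            is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  t <- 0; x <- 0L
  times <- numeric(0); counts <- integer(0)
  repeat {
    rate <- beta + gamma * x
    if (rate <= 0) break                 # beta = 0 and extinct: no events
    t <- t + stats::rexp(1L, rate)
    if (t > t_end) break
    x <- if (stats::runif(1L) < beta / rate) x + 1L else x - 1L
    times <- c(times, t); counts <- c(counts, x)
  }
  structure(list(event_times = times, counts = counts, beta = beta,
                 gamma = gamma, seed = as.integer(seed), t_end = t_end),
            class = "noise_trajectory")
}

#' @export
print.noise_trajectory <- function(x, ...) {
  cat(sprintf("Birth-death noise: beta=%g gamma=%g h^-1, %d events over %g h (seed %d)\n",
              x$beta, x$gamma, length(x$event_times), x$t_end, x$seed))
  cat(sprintf("  time-average count: %.4g (stationary mean %.4g)\n",
              noise_time_average(x), x$beta / x$gamma))
  invisible(x)
}

#' Piecewise-constant count of a noise trajectory
#'
#' @param noise A `noise_trajectory`.
#' @param t Time(s) in h. Vectorized.
#' @return Copy number(s) at `t` (0 before the first event).
#' @export
noise_count_at <- function(noise, t) {
  stopifnot(inherits(noise, "noise_trajectory"))
  idx <- findInterval(t, noise$event_times)
  ifelse(idx == 0L, 0L, noise$counts[pmax(idx, 1L)])
}

#' @describeIn noise_count_at Time-average copy number over `[0, t_end]`.
#' @export
noise_time_average <- function(noise) {
  stopifnot(inherits(noise, "noise_trajectory"))
  bounds <- c(0, noise$event_times, noise$t_end)
  levels <- c(0, noise$counts)
  sum(levels * diff(bounds)) / noise$t_end
}

#' Write / read a noise trajectory as CSV
#'
#' Columns `t, count` (the count after the event at `t`), with a
#' `#`-prefixed header recording the rates, seed and horizon, so that the
#' stochastic stage can be handed off to the deterministic stage through a
#' plain-text file.
#'
#' @param noise A `noise_trajectory`.
#' @param path CSV path.
#' @return `write_noise_csv`: `path` invisibly; `read_noise_csv`: a
#'   `noise_trajectory`.
#' @export
write_noise_csv <- function(noise, path) {
  stopifnot(inherits(noise, "noise_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# birth-death noise: beta=%.15g gamma=%.15g seed=%d t_end=%.15g",
                     noise$beta, noise$gamma, noise$seed, noise$t_end), con)
  utils::write.csv(data.frame(t = noise$event_times, count = noise$counts),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_noise_csv
#' @export
read_noise_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE+]+", hdr))[[1L]]
  kv <- stats::setNames(as.numeric(sub(".*=", "", m)), sub("=.*", "", m))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(event_times = df$t, counts = as.integer(df$count),
                 beta = unname(kv["beta"]), gamma = unname(kv["gamma"]),
                 seed = as.integer(kv["seed"]), t_end = unname(kv["t_end"])),
            class = "noise_trajectory")
}

#' Hybrid stochastic-deterministic robustness simulation
#'
#' Feeds a stochastic noise trajectory into the deterministic Allee-based
#' dynamics: the detection rate is the piecewise-constant
#' `sigma(t) = sigma_unit * count(t)`, and the ODE is integrated segment by
#' segment with the solver restarted at every noise event. A false positive
#' is declared when the density ever reaches the detected-state floor
#' `alpha_f * P`.
#'
#' @param noise A [simulate_birth_death()] trajectory covering `[0, t_end]`.
#' @param p An [allee_params()] object satisfying the bistability condition.
#' @param sigma_unit Detection rate per noise copy, h^-1 (default 1: a unit
#'   rate constant for the noise-driven switching reaction).
#' @param t_end Horizon, h; must not exceed the noise horizon.
#' @param H0 Initial density, mL^-1.
#' @param dt_out Output sampling step, h.
#' @return A list with `trajectory` (an `allee_trajectory` whose `sigma`
#'   holds the noise-driven rate) and `report` (class `robustness_report`:
#'   `max_H`, `fraction_time_low` — time fraction with H below
#'   `alpha_f * P` — and `false_positive`).
#' @export
hybrid_simulation <- function(noise, p, sigma_unit = 1, t_end = noise$t_end,
                              H0 = 0, dt_out = 0.01) {
  stopifnot(inherits(noise, "noise_trajectory"), inherits(p, "allee_params"),
            sigma_unit >= 0)
  if (noise$t_end < t_end)
    stop("noise trajectory (", noise$t_end, " h) is shorter than t_end (",
         t_end, " h)", call. = FALSE)
  ab <- alpha_bounds(p)
  ev <- noise$event_times[noise$event_times < t_end]
  seg_bounds <- unique(c(0, ev, t_end))

  out_t <- numeric(0); out_H <- numeric(0); out_s <- numeric(0)
  H <- H0
  for (k in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1L]
    s <- sigma_unit * noise_count_at(noise, (a + b) / 2)
    seg_times <- unique(c(seq(a, b, by = dt_out), b))
    if (length(seg_times) < 2L) seg_times <- c(a, b)
    sol <- deSolve::lsoda(y = c(H = H), times = seg_times,
                          func = function(t, y, parms) {
                            Hc <- min(max(y[1L], 0), p$P)
                            list((s + p$kappa *
                                  hill_activation(Hc, p$K, p$n)) *
                                 (p$P - Hc) - p$rho * Hc)
                          }, parms = NULL, rtol = 1e-8, atol = 1)
    keep <- if (k == 1L) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1L])
    out_H <- c(out_H, sol[keep, 2L])
    out_s <- c(out_s, rep(s, length(sol[keep, 1L])))
    H <- sol[nrow(sol), 2L]
  }
  out_H <- pmin(pmax(out_H, 0), p$P)

  thr <- ab[["alpha_f"]] * p$P
  dt <- diff(out_t)
  low <- out_H < thr
  frac_low <- sum(dt * (low[-length(low)] & low[-1L])) / (t_end - out_t[1L])
  report <- structure(list(max_H = max(out_H),
                           fraction_time_low = frac_low,
                           false_positive = max(out_H) >= thr,
                           alpha_f = ab[["alpha_f"]], seed = noise$seed),
                      class = "robustness_report")
  traj <- structure(list(model = "allee", times = out_t, H = out_H, S = NULL,
                         sigma = out_s, p = p, H0 = H0, t_end = t_end,
                         steady_state = out_H[length(out_H)],
                         converged = NA, convergence_time = NA_real_),
                    class = "allee_trajectory")
  list(trajectory = traj, report = report)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Robustness report (seed %s): %s\n",
              if (is.null(x$seed)) "-" else x$seed,
              if (x$false_positive) "FALSE POSITIVE" else "no false positive"))
  cat(sprintf("  max H = %.4g mL^-1; time fraction below alpha_f P: %.4f\n",
              x$max_H, x$fraction_time_low))
  invisible(x)
}

#' Seeded ensemble of robustness runs
#'
#' Independent replicates of [simulate_birth_death()] +
#' [hybrid_simulation()] at seeds `base_seed + 0:(n_runs-1)`, summarising
#' the false-positive frequency of the detector under spurious-detection
#' noise.
#'
#' @param p An [allee_params()] object.
#' @param beta,gamma Birth-death rates, h^-1.
#' @param n_runs Number of replicates, >= 1.
#' @param t_end Horizon per run, h.
#' @param base_seed Integer seed of the first replicate.
#' @param sigma_unit Detection rate per noise copy, h^-1.
#' @return Object of class `robustness_ensemble`: list with `reports` (one
#'   `robustness_report` per seed) and `false_positive_rate`.
#' @export
robustness_ensemble <- function(p, beta = 0.5, gamma = 2, n_runs = 20L,
                                t_end = 100, base_seed = 1L,
                                sigma_unit = 1) {
  stopifnot(n_runs >= 1L)
  reports <- lapply(seq_len(n_runs) - 1L, function(i) {
    nz <- simulate_birth_death(beta, gamma, t_end, seed = base_seed + i)
    hybrid_simulation(nz, p, sigma_unit = sigma_unit, t_end = t_end)$report
  })
  structure(list(reports = reports,
                 false_positive_rate =
                   mean(vapply(reports, `[[`, logical(1L), "false_positive")),
                 beta = beta, gamma = gamma, t_end = t_end,
                 base_seed = base_seed, n_runs = n_runs),
            class = "robustness_ensemble")
}

#' @export
print.robustness_ensemble <- function(x, ...) {
  cat(sprintf("Robustness ensemble: %d runs x %g h (beta=%g, gamma=%g)\n",
              x$n_runs, x$t_end, x$beta, x$gamma))
  cat(sprintf("  false-positive rate: %.3f\n", x$false_positive_rate))
  invisible(x)
}
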