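#' Hill activation function
#'
#' Cooperative activation profile of the quorum-sensing-driven Hold
#' reaction: `H^n / (H^n + K^n)`. Evaluated as `1 / (1 + (K/H)^n)` so that
#' densities of order 1e8 raised to the Hill coefficient never overflow.
#'
#' @param H High-state cell density, mL^-1, `H >= 0`. Vectorized.
#' @param K Half-activation density, mL^-1, `K > 0`.
#' @param n Hill coefficient, `n > 1`.
#' @return Activation fraction in \[0, 1\]; 0 at `H = 0`, 1/2 at `H = K`,
#'   monotone non-decreasing in `H`, approaching 1 as `H` grows.
#' @examples
#' hill_activation(8e7, K = 8e7, n = 4)   # 0.5
#' hill_activation(1.6e8, K = 8e7, n = 4) # 16/17
#' @export
hill_activation <- function(H, K, n) {
  if (any(!is.finite(H)) || any(H < 0))
    stop("H must be finite and >= 0", call. = FALSE)
  if (!is.finite(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 1) stop("n must be > 1", call. = FALSE)
  out <- numeric(length(H))
  pos <- H > 0
  out[pos] <- 1 / (1 + (K / H[pos])^n)
  out
}

# shared state check for the two-state models; tolerance avoids spurious
# failures from solver round-off at the domain boundary
check_H <- function(H, P) {
  if (any(!is.finite(H)) || any(H < -1e-9 * P) || any(H > P * (1 + 1e-9)))
    stop("state H must lie in [0, P]", call. = FALSE)
  pmin(pmax(H, 0), P)
}

#' ODE right-hand sides of the four detection algorithms
#'
#' Rates of change of the high-state cell density H (mL^-1 h^-1), with the
#' low-state density eliminated as `L = P - H` (population conservation).
#'
#' * `allee_rhs`: the Allee-based algorithm,
#'   `dH/dt = sigma (P - H) + kappa H^n/(H^n + K^n) (P - H) - rho H`.
#' * `set_reset_rhs`: no quorum feedback (`kappa = 0` nesting),
#'   `dH/dt = sigma (P - H) - rho H`, unique steady state
#'   `P sigma / (rho + sigma)`.
#' * `broadcast_rhs`: detection relayed by mass-action contact,
#'   `dH/dt = sigma (P - H) + kappa_bcast H (P - H)`.
#' * `dist_amp_rhs`: distributed amplification through a quorum-sensing
#'   reporter S secreted by all cells at a rate gated by the H density,
#'   `dH/dt = sigma (P - H) - rho H`,
#'   `dS/dt = kappa H^n/(H^n + K^n) P - rho S`.
#'
#' @param H High-state cell density, mL^-1, in \[0, P\]. Vectorized.
#' @param sigma Rare-event detection rate, h^-1 (recycled against `H`).
#' @param p An [allee_params()] object.
#' @param kappa_bcast Broadcast relay rate, mL h^-1; defaults to
#'   `p$kappa_bcast`.
#' @param S Reporter molecule density, mL^-1, `S >= 0` (dist_amp only).
#' @return `allee_rhs`, `set_reset_rhs`, `broadcast_rhs`: dH/dt in
#'   mL^-1 h^-1. `dist_amp_rhs`: a list with elements `dH` and `dS`.
#' @examples
#' p <- allee_params()
#' allee_rhs(0.15e8, sigma = 1.5, p)   # ~ 0: a Table-row steady state
#' set_reset_rhs(p$P / 2, sigma = p$rho, p)  # 0: symmetric steady state
#' @export
allee_rhs <- function(H, sigma, p) {
  stopifnot(inherits(p, "allee_params"))
  H <- check_H(H, p$P)
  (sigma + p$kappa * hill_activation(H, p$K, p$n)) * (p$P - H) - p$rho * H
}

#' @rdname allee_rhs
#' @export
set_reset_rhs <- function(H, sigma, p) {
  stopifnot(inherits(p, "allee_params"))
  H <- check_H(H, p$P)
  sigma * (p$P - H) - p$rho * H
}

#' @rdname allee_rhs
#' @export
broadcast_rhs <- function(H, sigma, p, kappa_bcast = p$kappa_bcast) {
  stopifnot(inherits(p, "allee_params"))
  H <- check_H(H, p$P)
  (sigma + kappa_bcast * H) * (p$P - H)
}

#' @rdname allee_rhs
#' @export
dist_amp_rhs <- function(H, S, sigma, p) {
  stopifnot(inherits(p, "allee_params"))
  H <- check_H(H, p$P)
  if (any(!is.finite(S)) || any(S < 0))
    stop("reporter density S must be finite and >= 0", call. = FALSE)
  list(dH = sigma * (p$P - H) - p$rho * H,
       dS = p$kappa * hill_activation(H, p$K, p$n) * p$P - p$rho * S)
}
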