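# Shared fixtures: the literature default parameter set and a generator of
# random (feasibility-unconstrained) parameter sets for property tests.

table1_params <- function(...) allee_params(...)

# random parameter sets spanning bistable and monostable regimes; integer
# Hill coefficients so the polynomial root path is exercised
random_params <- function(k) {
  allee_params(kappa = stats::runif(1, 1, 100),
               rho = stats::runif(1, 1, 100),
               n = sample(2:6, 1),
               K = stats::runif(1, 0.2, 0.9) * 1.5e8,
               P = 1.5e8)
}

# independent oracle: root locations of dH/dt = 0 by dense sign-change scan
scan_roots <- function(sigma, p, n_grid = 1e6) {
  H <- seq(0, p$P, length.out = n_grid + 1)
  v <- allee_rhs(H, sigma, p)
  hit <- which(v[-1] * v[-length(v)] < 0)
  mids <- (H[hit] + H[hit + 1]) / 2
  if (sigma == 0) mids <- c(0, mids)   # exact boundary root at sigma = 0
  mids
}

# independent oracle: equilibrium-count transition rate by dense sigma scan
scan_sigma_c <- function(p, lo, hi, step, n_grid = 1e5) {
  sigmas <- seq(lo, hi, by = step)
  counts <- vapply(sigmas, function(s) length(scan_roots(s, p, n_grid)),
                   numeric(1))
  i <- which(counts[-1] < counts[-length(counts)])[1]
  (sigmas[i] + sigmas[i + 1]) / 2
}
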