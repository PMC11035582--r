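test_that("Hill activation matches its closed form and is numerically stable", {
  expect_equal(hill_activation(8e7, 8e7, 4), 0.5)
  expect_equal(hill_activation(8e7, 8e7, 2.7), 0.5)   # H = K for any n
  expect_equal(hill_activation(0, 8e7, 4), 0)
  expect_equal(hill_activation(1.6e8, 8e7, 4), 16 / 17)
  # no overflow at extreme densities (1e300^4 would overflow naively)
  expect_equal(hill_activation(1e300, 8e7, 4), 1)
  expect_equal(hill_activation(1e-300, 8e7, 4), 0)
  # monotone non-decreasing
  H <- seq(0, 3e8, length.out = 200)
  expect_true(all(diff(hill_activation(H, 8e7, 4)) >= 0))
  expect_error(hill_activation(-1, 8e7, 4))
  expect_error(hill_activation(1, -8e7, 4))
})

test_that("Hill activation and its complement sum to one", {
  set.seed(11)
  H <- stats::runif(50, 0, 3e8)
  act <- hill_activation(H, 8e7, 4)
  comp <- 1 / (1 + (H / 8e7)^4)   # K^n / (H^n + K^n)
  expect_equal(act + comp, rep(1, 50), tolerance = 1e-12)
})

test_that("effective detection rate is linear in analyte concentration", {
  expect_equal(effective_sigma(0, allee_params(sigma_err = 0.1)), 0.1)
  expect_equal(effective_sigma(0, allee_params(sigma_err = 0)), 0)
  expect_equal(effective_sigma(2, allee_params(sigma_A = 1.5,
                                               sigma_err = 0.5)), 3.5)
  expect_error(effective_sigma(-1, allee_params()))
})

test_that("Allee RHS vanishes at the origin and drains at saturation", {
  p <- table1_params()
  expect_equal(allee_rhs(0, 0, p), 0)
  expect_equal(allee_rhs(p$P, 3, p), -p$rho * p$P)
  expect_equal(allee_rhs(p$P, 0, p), -p$rho * p$P)
  # the reported steady state at sigma = 1.5 is a near-root of the RHS:
  # small against the natural rate scale rho * P (the exact root is at
  # 0.1488e8; 0.15e8 is that value at printed precision)
  expect_lt(abs(allee_rhs(0.15e8, 1.5, p)), 1e-3 * p$rho * p$P)
  expect_error(allee_rhs(-1e6, 1, p))
  expect_error(allee_rhs(p$P * 1.01, 1, p))
})

test_that("Allee RHS is strictly increasing in sigma below saturation", {
  p <- table1_params()
  set.seed(21)
  for (i in 1:25) {
    H <- stats::runif(1, 0, 0.999 * p$P)
    s <- sort(stats::runif(2, 0, 10))
    expect_lt(allee_rhs(H, s[1], p), allee_rhs(H, s[2], p))
  }
})

test_that("set-reset dynamics are the kappa = 0 nesting of the Allee model", {
  p0 <- allee_params(kappa = 0)
  H <- seq(0, p0$P, length.out = 101)
  expect_equal(allee_rhs(H, 2.5, p0), set_reset_rhs(H, 2.5, p0))
  # unique root at P sigma / (rho + sigma); symmetric case sigma = rho
  expect_equal(set_reset_rhs(p0$P / 2, p0$rho, p0), 0)
  s <- 3.7
  expect_equal(set_reset_rhs(p0$P * s / (p0$rho + s), s, p0), 0,
               tolerance = 1e-9)
  expect_equal(set_reset_rhs(0, 0, p0), 0)
})

test_that("broadcast RHS carries the (P - H) factor in both terms", {
  p <- table1_params()
  expect_equal(broadcast_rhs(p$P, 4, p), 0)
  expect_equal(broadcast_rhs(0, 0, p), 0)
  expect_gt(broadcast_rhs(1, 1e-6, p), 0)   # any sigma > 0 pushes upward
})

test_that("distributed amplification has the expected two-variable structure", {
  p <- table1_params()
  z <- dist_amp_rhs(0, 0, 0, p)
  expect_equal(z$dH, 0)
  expect_equal(z$dS, 0)
  # with H = 0 the reporter only decays
  z2 <- dist_amp_rhs(0, 1e6, 0, p)
  expect_equal(z2$dS, -p$rho * 1e6)
  # closed-form steady state zeroes both rates
  s <- 2
  Hst <- p$P * s / (p$rho + s)
  Sst <- p$kappa / p$rho * p$P * hill_activation(Hst, p$K, p$n)
  z3 <- dist_amp_rhs(Hst, Sst, s, p)
  expect_equal(z3$dH, 0, tolerance = 1e-6 * p$rho * p$P)
  expect_equal(z3$dS, 0, tolerance = 1e-6 * p$rho * p$P)
})

test_that("parameter validation enforces the model preconditions", {
  expect_error(allee_params(rho = 0), "rho")
  expect_error(allee_params(n = 1), "n must be > 1")
  expect_error(allee_params(P = -1), "P")
  expect_error(allee_params(sigma_err = -0.1), "sigma_err")
  expect_silent(allee_params(kappa = 0))   # set-reset nesting is legal
})

test_that("parameter sets round-trip through YAML and JSON configs", {
  p <- allee_params(kappa = 17.5, rho = 3.25, n = 3, K = 5e7, P = 1.2e8,
                    sigma_A = 0.8, sigma_err = 0.05)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_params(p, f)
    q <- read_params(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(f)
  }
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kappa = 5, bogus_key = 1), bad)
  expect_error(read_params(bad), "bogus_key")
  unlink(bad)
})

test_that("analyte profiles evaluate piecewise and stay non-negative", {
  pr <- analyte_profile("constant", amplitude = 2)
  expect_equal(analyte_at(pr, c(0, 5, 100)), c(2, 2, 2))
  st <- analyte_profile("step_down", amplitude = 3, t_step = 1.5)
  expect_equal(analyte_at(st, c(0, 1.49, 1.5, 9)), c(3, 3, 0, 0))
  pu <- analyte_profile("pulse", amplitude = 4, t_start = 1, width = 0.5)
  expect_equal(analyte_at(pu, c(0.9, 1, 1.49, 1.5, 3)), c(0, 4, 4, 0, 0))
  expect_error(analyte_at(pu, -1))
  expect_error(analyte_profile("pulse", amplitude = 1, t_start = 1))
  expect_error(analyte_profile("constant", amplitude = -1))
})
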