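test_that("integration reproduces the reference transients", {
  p <- table1_params()
  tr0 <- integrate_model("allee", p, 0, H0 = 0, t_end = 1)
  expect_true(all(tr0$H == 0))

  tr4 <- integrate_model("allee", p, 4, H0 = 0, t_end = 2)
  expect_equal(tr4$H[length(tr4$H)], 1.01e8, tolerance = 0.01)

  trb <- integrate_model("broadcast", p, 1e-3, H0 = 0, t_end = 5)
  expect_equal(trb$H[length(trb$H)], p$P, tolerance = 1e-4)
})

test_that("trajectories stay inside [0, P] for all four models", {
  p <- table1_params()
  for (m in c("allee", "set_reset", "broadcast")) {
    for (s in c(0, 1.5, 5)) {
      tr <- integrate_model(m, p, s, H0 = 0.3 * p$P, t_end = 3)
      expect_true(all(tr$H >= 0 & tr$H <= p$P))
    }
  }
  trd <- integrate_model("dist_amp", p, 3, t_end = 3)
  expect_true(all(trd$H >= 0 & trd$H <= p$P))
  expect_true(all(trd$S >= 0))
  expect_true(all(diff(trd$times) > 0))
})

test_that("steady states match the equilibrium roots and closed forms", {
  p <- table1_params()
  ss15 <- steady_state("allee", p, 1.5)
  expect_equal(as.numeric(ss15), 0.15e8, tolerance = 0.02)
  expect_true(attr(ss15, "converged"))
  # cross-check against the nearest equilibrium root
  eq <- find_equilibria(1.5, p)
  expect_lt(min(abs(as.numeric(ss15) - eq$roots)), 0.005 * p$P)

  expect_equal(as.numeric(steady_state("allee", p, 0)), 0)
  expect_equal(as.numeric(steady_state("set_reset", p, p$rho)), p$P / 2,
               tolerance = 1e-6)
  s <- 2
  sd <- steady_state("dist_amp", p, s)
  Hst <- p$P * s / (p$rho + s)
  expect_equal(attr(sd, "state")[["H"]], Hst, tolerance = 1e-5)
  expect_equal(as.numeric(sd),
               p$kappa / p$rho * p$P * hill_activation(Hst, p$K, p$n),
               tolerance = 1e-4)
})

test_that("95% convergence times match the reference values and closed form", {
  p <- table1_params()
  tr5 <- integrate_model("allee", p, 5, t_end = 2)
  expect_equal(convergence_time(tr5, tr5$steady_state), 0.3,
               tolerance = 0.05 / 0.3)
  expect_equal(convergence_time(tr5, 0), 0)

  # pure set-reset limit: H(t) = H_ss (1 - exp(-(sigma+rho) t)) gives
  # t_95 = ln(20) / (sigma + rho) exactly
  p0 <- allee_params(kappa = 0)
  s <- 3
  tr <- integrate_model("set_reset", p0, s, t_end = 2)
  expect_equal(convergence_time(tr, tr$steady_state),
               log(20) / (s + p0$rho), tolerance = 1e-3)
  expect_error(convergence_time(tr, 10 * p0$P), "never reaches")
})

test_that("detection outcome flips across the critical rate from empty start", {
  p <- table1_params()
  ab <- alpha_bounds(p)
  sc <- binary_search_sigma_c(p)$sigma_c
  for (s in c(0.5 * sc, 0.9 * sc)) {
    end_H <- as.numeric(steady_state("allee", p, s))
    expect_lt(end_H, ab[["alpha_i"]] * p$P)
  }
  for (s in c(1.1 * sc, 2 * sc)) {
    end_H <- as.numeric(steady_state("allee", p, s))
    expect_gt(end_H, ab[["alpha_f"]] * p$P)
  }
})

test_that("bistable hysteresis: branch selection depends on history", {
  p <- table1_params()
  sc <- binary_search_sigma_c(p)$sigma_c
  s <- 1.5   # inside the bistable window (0, sigma_c)
  expect_lt(s, sc)
  up <- as.numeric(steady_state("allee", p, s, H0 = 0))
  down <- as.numeric(steady_state("allee", p, s, H0 = p$P))
  eq <- find_equilibria(s, p)
  expect_equal(up, eq$roots[1], tolerance = 1e-3)
  expect_equal(down, eq$roots[3], tolerance = 1e-3)
  expect_gt(down / up, 5)
})

test_that("halving solver tolerances leaves reference outputs unchanged", {
  p <- table1_params()
  a <- integrate_model("allee", p, 4, t_end = 2)
  b <- integrate_model("allee", p, 4, t_end = 2, rtol = 5e-9, atol = 0.5)
  expect_equal(a$steady_state, b$steady_state, tolerance = 1e-3)
  expect_equal(convergence_time(a, a$steady_state),
               convergence_time(b, b$steady_state), tolerance = 1e-3)
})

test_that("memory requires sufficient exposure amplitude and duration", {
  p <- table1_params()
  sc <- binary_search_sigma_c(p)$sigma_c

  none <- memory_experiment(p, analyte_profile("step_down", amplitude = 0,
                                               t_step = 1))
  expect_false(none$memorized)
  expect_lt(none$final_H, 1e-3 * p$P)

  long_strong <- memory_experiment(p, analyte_profile("step_down",
                                                      amplitude = 1.5 * sc,
                                                      t_step = 2))
  expect_true(long_strong$memorized)

  short <- memory_experiment(p, analyte_profile("step_down",
                                                amplitude = 1.5 * sc,
                                                t_step = 0.05))
  expect_false(short$memorized)

  # at long fixed duration, the minimal memorizing pulse amplitude brackets
  # sigma_c / sigma_A
  lo_amp <- (sc - 0.15) / p$sigma_A
  hi_amp <- (sc + 0.15) / p$sigma_A
  pulse <- function(a) memory_experiment(
    p, analyte_profile("pulse", amplitude = a, t_start = 0.1, width = 4))
  expect_false(pulse(lo_amp)$memorized)
  expect_true(pulse(hi_amp)$memorized)

  expect_error(memory_experiment(p, analyte_profile("constant",
                                                    amplitude = 2)),
               "ending at 0")
})

test_that("dose-response curves show the four characteristic shapes", {
  p <- table1_params()
  ab <- alpha_bounds(p)
  sc <- binary_search_sigma_c(p)$sigma_c
  A <- c(0, 1, 2, 0.95 * sc, 1.05 * sc, 4, 6)   # sigma_A = 1, sigma_err = 0
  cv <- dose_response(p, A)
  expect_true(all(as.matrix(cv[-1]) >= 0))

  # set-reset: closed form pointwise, no threshold
  expect_equal(cv$set_reset, p$P * A / (p$rho + A), tolerance = 1e-5)
  # broadcast: strong threshold at zero
  expect_equal(cv$broadcast[1], 0)
  expect_true(all(cv$broadcast[-1] > 0.999 * p$P))
  # Allee: jump across A = sigma_c / sigma_A from below alpha_i P to
  # above alpha_f P
  expect_lt(cv$allee[4], ab[["alpha_i"]] * p$P)
  expect_gt(cv$allee[5], ab[["alpha_f"]] * p$P)
  # distributed amplification: thresholding but weaker amplification than
  # the Allee jump
  jump_allee <- cv$allee[5] - cv$allee[4]
  jump_damp <- cv$dist_amp[5] - cv$dist_amp[4]
  expect_gt(jump_allee, 5 * jump_damp)
})

test_that("trajectory CSV export preserves population conservation", {
  p <- table1_params()
  tr <- integrate_model("allee", p, 1.5, t_end = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- utils::read.csv(f, comment.char = "#")
  expect_equal(df$H + df$L, rep(p$P, nrow(df)), tolerance = 1e-9)
  expect_equal(df$sigma, rep(1.5, nrow(df)))
  unlink(f)
})
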