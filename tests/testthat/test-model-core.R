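test_that("right-hand side reduces to production terms at the origin", {
  p <- lr_params()
  d <- model_rhs(system_state(0, 0, 0, 0), p, alpha_current = 1560)
  expect_equal(unname(d), c(1560, 14500, 0, 0))
})

test_that("phosphorylation drive vanishes when the GSK3beta pool is saturated", {
  for (p in list(lr_params(), replus_params())) {
    s <- system_state(0, 1e5, 0, p$g_tot)
    d <- model_rhs(s, p, alpha_current = 0)
    expect_equal(d[["gsk3b_p"]], -p$kappa * p$g_tot)
  }
})

test_that("closed-form steady state zeroes the right-hand side", {
  for (p in list(lr_params(), replus_params())) {
    for (alpha in c(p$alpha_baseline, p$alpha_infection, 15000)) {
      ss <- steady_state(p, alpha)
      d <- model_rhs(as_system_state(ss), p, alpha)
      scale <- max(alpha, p$tau)
      expect_lt(max(abs(d)) / scale, 1e-8)
    }
  }
})

test_that("closed form agrees with the fixed-point iteration oracle", {
  # canonical profiles at baseline and infection rates
  cases <- list(list(p = lr_params(), a = 1560), list(p = lr_params(), a = 44000),
                list(p = replus_params(), a = 7020),
                list(p = replus_params(), a = 109000))
  for (cs in cases) {
    ss <- steady_state(cs$p, cs$a)
    orc <- oracle_steady_state(cs$p, cs$a)
    expect_lt(rel_diff(ss$a_beta, orc[["a_beta"]]), 1e-8)
    expect_lt(rel_diff(ss$reelin, orc[["reelin"]]), 1e-8)
    expect_lt(rel_diff(ss$a_beta_reelin, orc[["a_beta_reelin"]]), 1e-8)
    expect_lt(rel_diff(ss$gsk3b_p, orc[["gsk3b_p"]]), 1e-8)
  }
  # frozen oracle values for the two baseline states
  lr <- steady_state(lr_params())
  expect_equal(lr$reelin, 2.588e5, tolerance = 1e-3)
  expect_equal(lr$a_beta, 1.2, tolerance = 0.01)
  expect_equal(lr$a_beta_reelin, 7.80e4, tolerance = 1e-3)
  expect_equal(steady_state(replus_params())$reelin, 1.4396e6, tolerance = 1e-4)
  # random parameter sets
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    a <- stats::runif(1, 0, 2e5)
    ss <- steady_state(p, a)
    orc <- oracle_steady_state(p, a)
    expect_lt(rel_diff(ss$reelin, orc[["reelin"]]), 1e-6)
    expect_lt(rel_diff(ss$a_beta + 1, orc[["a_beta"]] + 1), 1e-6)
  }
})

test_that("zero production collapses the steady state to the reelin-only state", {
  for (p in list(lr_params(), replus_params())) {
    ss <- steady_state(p, 0)
    expect_equal(ss$a_beta, 0)
    expect_equal(ss$reelin, p$tau / p$rho, tolerance = 1e-12)
    expect_equal(ss$a_beta_reelin, 0)
    expect_equal(ss$q, p$beta * p$rho + p$gamma * p$tau)
  }
})

test_that("gamma = 0 branch returns the decoupled closed form", {
  p0 <- unclass(lr_params()); p0$gamma <- 0
  p0 <- do.call(model_parameters, p0)
  ss <- steady_state(p0, 1560)
  expect_equal(ss$a_beta, 1560 / 0.1)
  expect_equal(ss$reelin, 14500 / 0.05)
  expect_equal(ss$a_beta_reelin, 0)
  expect_equal(ss$gsk3b_p,
               12 * ss$reelin * 5e4 / (0.65 * 5e4 + 12 * ss$reelin))
  tot <- steady_state_totals(p0, 1560)
  expect_equal(unname(tot), c(14500 / 0.05, 1560 / 0.1))
})

test_that("reported long-form phospho-GSK3beta expression equals the fixed point", {
  for (p in list(lr_params(), replus_params())) {
    for (alpha in c(p$alpha_baseline, p$alpha_infection)) {
      ss <- steady_state(p, alpha)
      long <- reelinsink:::gsk3bp_long_form(alpha, p$tau, p$beta, p$gamma,
                                            p$rho, p$delta, p$eta, p$kappa,
                                            p$g_tot)
      # the long form suffers mild cancellation; agreement to 1e-10 relative
      expect_lt(rel_diff(ss$gsk3b_p, long), 1e-10)
    }
  }
})

test_that("steady-state totals satisfy the flux-balance identities", {
  # alpha = beta A* + delta B*; tau = rho R* + delta B*
  set.seed(7)
  for (i in 1:30) {
    p <- random_params()
    a <- stats::runif(1, 0, 2e5)
    ss <- steady_state(p, a)
    expect_lt(abs(p$beta * ss$a_beta + p$delta * ss$a_beta_reelin - a) /
                max(a, 1), 1e-8)
    expect_lt(abs(p$rho * ss$reelin + p$delta * ss$a_beta_reelin - p$tau) /
                p$tau, 1e-8)
  }
})

test_that("transgenic totals match the oracle at the knockdown study conditions", {
  p <- unclass(replus_params()); p$alpha_baseline <- 2.57 * 7020
  ctrl <- do.call(model_parameters, p)
  tot_c <- steady_state_totals(ctrl)
  expect_equal(unname(tot_c["total_reelin"]), 2.12e6, tolerance = 5e-3)
  expect_equal(unname(tot_c["total_a_beta"]), 9.0e5, tolerance = 5e-3)
  p$tau <- 0.14 * 79000
  expt <- do.call(model_parameters, p)
  tot_e <- steady_state_totals(expt)
  expect_equal(unname(tot_e["total_reelin"]), 5.53e5, tolerance = 5e-3)
  expect_equal(unname(tot_e["total_a_beta"]), 6.2e5, tolerance = 5e-3)
})

test_that("steady-state free reelin decreases and free Abeta increases in alpha", {
  alphas <- seq(0, 2e5, by = 2500)
  for (p in list(lr_params(), replus_params())) {
    ss <- lapply(alphas, function(a) steady_state(p, a))
    reelin <- vapply(ss, `[[`, numeric(1), "reelin")
    abeta <- vapply(ss, `[[`, numeric(1), "a_beta")
    expect_true(all(diff(reelin) <= 0))
    expect_true(all(diff(abeta) >= 0))
  }
})

test_that("analytic Jacobian matches printed structure and finite differences", {
  p <- lr_params()
  # at the origin: diagonal of the four removal rates plus the eta drive
  J0 <- model_jacobian(p, system_state(0, 0, 0, 0))
  expected <- diag(c(-p$beta, -p$rho, -p$delta, -p$kappa))
  expected[4, 2] <- p$eta
  expect_equal(unname(J0), expected)
  # against central differences at the baseline steady state
  ss <- steady_state(p)
  J <- model_jacobian(p, as_system_state(ss))
  Jnum <- oracle_jacobian(p, as_system_state(ss), p$alpha_baseline)
  expect_equal(J, Jnum, tolerance = 1e-6)
})

test_that("Jacobian sign pattern: negative diagonal, positive Abeta-reelin loop", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    s <- system_state(stats::runif(1, 1, 1e6), stats::runif(1, 1, 1e6),
                      stats::runif(1, 0, 1e6), stats::runif(1, 0, p$g_tot))
    J <- model_jacobian(p, s)
    expect_true(all(diag(J) < 0))
    expect_gt(J[1, 2] * J[2, 1], 0)
  }
})

test_that("baseline and infection steady states are locally asymptotically stable", {
  for (p in list(lr_params(), replus_params())) {
    for (alpha in c(p$alpha_baseline, p$alpha_infection)) {
      st <- assess_stability(p, steady_state(p, alpha))
      expect_true(st$stable)
      expect_true(all(Re(st$eigenvalues) < 0))
    }
    # at baseline all four eigenvalues are real and negative
    st <- assess_stability(p, steady_state(p, p$alpha_baseline))
    expect_true(all(abs(Im(st$eigenvalues)) == 0))
    expect_identical(st$classification, "stable node")
  }
})

test_that("assess_stability rejects points that are not steady states", {
  p <- lr_params()
  ss <- steady_state(p)
  ss$reelin <- ss$reelin * 2
  expect_error(assess_stability(p, ss), "not a steady state")
})

test_that("invalid parameters and states are rejected", {
  expect_error(model_parameters(1560, 44000, 0, 0.005, 14500, 0.05, 0.02,
                                12, 0.65, 5e4), "strictly positive")
  expect_error(model_parameters(-1, 44000, 0.1, 0.005, 14500, 0.05, 0.02,
                                12, 0.65, 5e4), "non-negative")
  expect_error(model_parameters(NaN, 44000, 0.1, 0.005, 14500, 0.05, 0.02,
                                12, 0.65, 5e4), "non-finite")
  expect_error(system_state(-1, 0, 0, 0), "non-negative")
  expect_error(model_rhs(system_state(0, 0, 0, 0), lr_params(), -5),
               "non-negative")
  expect_error(steady_state(lr_params(), Inf), "finite")
})
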