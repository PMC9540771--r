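test_that("extinction is absorbing and progeny-free strains die out", {
  p <- baseline_params()
  expect_equal(season_map(0, p), 0)
  expect_equal(season_map(1, baseline_params(beta = 0)), 0)
})

test_that("the between-season map agrees with the numerical oracle", {
  p <- baseline_params()
  m1 <- season_map(1, p)
  expect_gt(m1, 1)  # persistence regime for the baseline parameters
  expect_lt(rel_err(m1, attr(season_oracle(update_params(p, v_init = 1),
                                           2e4), "v2_end")), 1e-6)
  v <- 3e8
  expect_lt(rel_err(season_map(v, p),
                    attr(season_oracle(update_params(p, v_init = v), 2e4),
                         "v2_end")), 1e-6)
})

test_that("persistence requires progeny release within the season", {
  expect_false(persistence_check(baseline_params(beta = 0))$persists)
  pc <- persistence_check(baseline_params(tau = 3.2))  # tau >= T
  expect_equal(pc$growth_factor, 0)
  expect_false(pc$persists)
  base <- persistence_check(baseline_params())
  expect_true(base$persists)
  expect_gt(base$growth_factor, 1)
})

test_that("the map saturates below the identity at high densities", {
  p <- baseline_params()
  v_big <- 1e13
  expect_lt(season_map(v_big, p), v_big)
})

test_that("non-persistent parasites settle at the trivial equilibrium", {
  eq <- resident_equilibrium(baseline_params(beta = 0))
  expect_equal(eq$v_star, 0)
  expect_true(eq$converged)
})

test_that("the resident equilibrium is a self-consistent fixed point", {
  p <- baseline_params(tau = 1.95)  # near the optimum for this environment
  eq <- resident_equilibrium(p)
  expect_true(eq$converged)
  expect_gt(eq$v_star, 1)
  expect_lt(eq$residual, 1e-8)
  expect_lt(abs(season_map(eq$v_star, p) - eq$v_star) / eq$v_star, 1e-8)
  expect_true(eq$stable)
  # warm start converges to the same fixed point
  eq2 <- resident_equilibrium(p, v_guess = eq$v_star * 3)
  expect_lt(rel_err(eq2$v_star, eq$v_star), 1e-8)
})

test_that("fixed points are self-consistent across environments", {
  for (tau in c(1.2, 1.8, 2.4)) {
    p <- baseline_params(tau = tau)
    eq <- resident_equilibrium(p, diagnostics = FALSE)
    if (eq$v_star > 0)
      expect_lt(abs(season_map(eq$v_star, p) - eq$v_star) /
                  eq$v_star, 1e-8)
  }
})
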