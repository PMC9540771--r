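test_that("mutant fitness reduces to the resident formula without a resident", {
  p <- baseline_params(v_init = 5e7)
  m <- mutant_traits(p)
  expect_equal(mutant_v2_end(p, v_star = 0, mutant = m, v1m0 = p$v_init),
               as.numeric(season_v2_end(p)), tolerance = 1e-12)
})

test_that("mutants without progeny or with post-season kills cannot invade", {
  p <- baseline_params()
  expect_equal(mutant_v2_end(p, v_star = 1e9,
                             mutant = mutant_traits(p, beta_m = 0)), 0)
  expect_equal(mutant_v2_end(p, v_star = 1e9,
                             mutant = mutant_traits(p, tau_m = 3.5)), 0)
})

test_that("mutant fitness with self-shading matches the two-strain oracle", {
  p <- baseline_params()
  m <- mutant_traits(p, tau_m = 2.1)
  v_star <- 2e9
  ora <- phenovir:::.mutant_oracle(p, v_star = v_star, mutant = m,
                                   v1m0 = 1, grid_size = 2e4)
  expect_lt(rel_err(mutant_v2_end(p, v_star, m, v1m0 = 1), ora$v2m_end),
            1e-5)
  # the resident strain in the same joint system matches the season map
  expect_lt(rel_err(season_map(v_star, p), ora$v2_end), 1e-5)
})

test_that("a resident-identical rare mutant is selectively neutral", {
  p <- baseline_params(tau = 1.9)
  eq <- resident_equilibrium(p, diagnostics = FALSE)
  g <- selection_gradient(p$tau, p, v_star = eq$v_star)
  expect_equal(attr(g, "w_pc"), 1, tolerance = 1e-6)
})

test_that("the analytic selection gradient matches a finite difference", {
  p <- baseline_params()
  for (tau_r in c(1.2, 1.9, 2.4)) {
    eq <- resident_equilibrium(update_params(p, tau = tau_r),
                               diagnostics = FALSE)
    ga <- selection_gradient(tau_r, p, v_star = eq$v_star)
    gf <- selection_gradient(tau_r, p, v_star = eq$v_star, method = "fd")
    expect_lt(abs(as.numeric(ga) - as.numeric(gf)) /
                max(abs(as.numeric(ga)), 1e-8), 1e-4)
  }
})

test_that("selection pushes the delay towards an interior optimum", {
  p <- baseline_params(T = 4, t_l = 1)
  ss <- find_singular_strategy(p)
  expect_true(ss$found)
  # below the optimum selection favours longer delays, above it shorter
  expect_gt(as.numeric(selection_gradient(ss$tau_star - 0.3, p)), 0)
  expect_lt(as.numeric(selection_gradient(ss$tau_star + 0.3, p)), 0)
  expect_lt(abs(ss$gradient_at_star), 1e-6)
})

test_that("the singular strategy is an interior, classified optimum", {
  ss32 <- find_singular_strategy(baseline_params(T = 3.2))
  expect_true(ss32$found)
  expect_gt(ss32$tau_star, 0)
  expect_lt(ss32$tau_star, 3.2)
  expect_lt(ss32$second_derivative, 0)
  expect_true(ss32$is_ess)
  expect_true(ss32$is_convergence_stable)
  # longer seasons favour longer delays (lower virulence)
  ss40 <- find_singular_strategy(baseline_params(T = 4))
  expect_gt(ss40$tau_star, ss32$tau_star)
})

test_that("degenerate residents yield a boundary diagnosis, not a root", {
  ss <- find_singular_strategy(baseline_params(beta = 0))
  expect_false(ss$found)
  expect_true(is.na(ss$tau_star))
  expect_match(ss$direction, "not persistent")
})

test_that("near-synchronous emergence drives the optimum towards the season end", {
  ss <- find_singular_strategy(baseline_params(t_l = 0.01, T = 3))
  expect_true(ss$found)
  expect_gt(ss$tau_star, 0.9 * 3)
  expect_lt(ss$tau_star, 3)
})

test_that("the pairwise invasibility surface is neutral on the diagonal and closed at the ESS", {
  p <- baseline_params()
  ss <- find_singular_strategy(p)
  taus <- c(1.6, ss$tau_star, 2.3)
  pip <- pip_grid(p, tau_res = taus, tau_mut = taus)
  expect_equal(dim(pip), c(3L, 3L))
  expect_lt(max(abs(diag(pip))), 1e-6)
  # no mutant invades the singular resident
  expect_true(all(pip[, 2] < 1e-6))
  # convergence stability: residents between a mutant and the ESS win;
  # mutants closer to the ESS invade residents further away
  expect_gt(pip[2, 1], 0)   # tau* invades the low-delay resident
  expect_gt(pip[2, 3], 0)   # tau* invades the high-delay resident
  expect_lt(pip[1, 2], 0)
  expect_lt(pip[3, 2], 0)
})
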