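test_that("emergence rate is a uniform density on the emergence window", {
  expect_equal(emergence_rate(0.5, t_l = 1), 1.0)
  expect_equal(emergence_rate(1.5, t_l = 1), 0.0)
  expect_equal(emergence_rate(0, t_l = 2), 0.5)
  # integrates to one over any season containing the window
  for (tl in c(0.3, 1, 2)) {
    igr <- stats::integrate(emergence_rate, 0, tl, t_l = tl)$value +
      stats::integrate(emergence_rate, tl, 5, t_l = tl)$value
    expect_equal(igr, 1, tolerance = 1e-8)
  }
  expect_error(emergence_rate(-0.1, 1))
  expect_error(emergence_rate(0.5, 0))
})

test_that("free parasites decay exponentially from the season start", {
  expect_equal(free_parasite_density(0, v_init = 7.3, delta = 2), 7.3)
  expect_equal(free_parasite_density(1, v_init = 1, delta = 0), 1.0)
  expect_equal(free_parasite_density(0.5, v_init = 1, delta = 2), exp(-1))
})

test_that("host density follows the closed-form linear-ODE solution", {
  # s(0) = 0 always
  expect_equal(susceptible_density(0, baseline_params()), 0)
  # no infection, no mortality: the whole cohort is present after t_l
  p0 <- baseline_params(alpha = 1e-300, mu = 0)
  expect_equal(susceptible_density(c(1, 2, 3), p0),
               rep(1e8, 3), tolerance = 1e-10)
  # no infection, mortality only: integrating-factor closed form
  p1 <- baseline_params(alpha = 1e-300, mu = 0.5)
  expected <- 1e8 * exp(-0.5 * 2) * (exp(0.5 * 1) - 1) / (0.5 * 1)
  expect_equal(susceptible_density(2, p1), expected, tolerance = 1e-9)
  expect_error(susceptible_density(3.5, baseline_params()))
})

test_that("host density agrees with direct numerical integration", {
  p <- baseline_params(v_init = 1e8)  # strong infection pressure
  tr <- season_oracle(p, grid_size = 2e3)
  idx <- seq(1, nrow(tr), by = 97)
  expect_lt(max(rel_err(susceptible_density(tr$t[idx], p), tr$s[idx],
                        floor = 1e-4 * p$s_hat)), 1e-6)
})

test_that("end-of-season progeny density matches the numerical oracle in both regimes", {
  # release window extending past the emergence period (tau < T - t_l)
  p1 <- baseline_params(tau = 1.5)
  expect_lt(rel_err(as.numeric(season_v2_end(p1)),
                    attr(season_oracle(p1, 2e4), "v2_end")), 1e-6)
  # release window inside the emergence period (tau > T - t_l)
  p2 <- baseline_params(tau = 2.5)
  expect_lt(rel_err(as.numeric(season_v2_end(p2)),
                    attr(season_oracle(p2, 2e4), "v2_end")), 1e-6)
  # at high parasite density (host depletion saturating)
  p3 <- baseline_params(v_init = 1e8)
  expect_lt(rel_err(as.numeric(season_v2_end(p3)),
                    attr(season_oracle(p3, 2e4), "v2_end")), 1e-6)
})

test_that("degenerate inputs produce no progeny", {
  expect_equal(as.numeric(season_v2_end(baseline_params(v_init = 0))), 0)
  expect_equal(as.numeric(season_v2_end(baseline_params(alpha = 1e-300))),
               0, tolerance = 1e-250)
  cens <- season_v2_end(baseline_params(tau = 3.5))
  expect_equal(as.numeric(cens), 0)
  expect_true(isTRUE(attr(cens, "censored")))
})

test_that("progeny output increases with progeny number and cohort size", {
  base <- as.numeric(season_v2_end(baseline_params()))
  expect_gt(as.numeric(season_v2_end(baseline_params(beta = 400))), base)
  expect_gt(as.numeric(season_v2_end(baseline_params(s_hat = 2e8))), base)
})

test_that("per-capita dynamics are invariant under the population rescaling", {
  p <- baseline_params(v_init = 1e6)
  ref <- as.numeric(season_v2_end(p)) / p$v_init
  for (cc in c(1e2, 1e4)) {
    ps <- baseline_params(s_hat = p$s_hat / cc, alpha = p$alpha * cc,
                          v_init = p$v_init / cc)
    expect_lt(rel_err(as.numeric(season_v2_end(ps)) / ps$v_init, ref), 1e-10)
  }
})

test_that("season trajectory satisfies its structural invariants", {
  p <- baseline_params(v_init = 1e7)
  tr <- season_trajectory(p, n = 301)
  expect_named(tr, c("t", "s", "v1", "v2"))
  expect_true(all(tr$s >= 0) && all(tr$v1 >= 0) && all(tr$v2 >= 0))
  expect_true(all(diff(tr$v1) <= 0))
  expect_true(all(tr$v2[tr$t < p$tau] == 0))
  expect_equal(attr(tr, "v2_end"), tr$v2[nrow(tr)])
  expect_lt(rel_err(attr(tr, "v2_end"), as.numeric(season_v2_end(p))), 1e-4)
})

test_that("parameter constructors validate their domains", {
  expect_error(host_params(s_hat = -1), "s_hat")
  expect_error(host_params(t_l = 0), "t_l")
  expect_error(parasite_traits(tau = -1), "tau")
  expect_error(model_params(t_l = 4, T = 3), "t_l")
  expect_error(season_config(v_init = -2), "v_init")
  p2 <- update_params(baseline_params(), tau = 2, T = 4)
  expect_equal(p2$tau, 2)
  expect_equal(p2$T, 4)
  expect_error(update_params(baseline_params(), nope = 1), "unknown")
})

test_that("parameter sets round-trip through the config file format", {
  path <- system.file("extdata", "default-config.yaml", package = "phenovir")
  cfg <- read_model_config(path)
  expect_s3_class(cfg$params, "phv_params")
  expect_equal(cfg$params$s_hat, 1e8)
  expect_equal(cfg$params$delta, 2)
  expect_null(cfg$params$tradeoff)
  expect_s3_class(cfg$ibm, "phv_ibm_config")
  expect_equal(cfg$ibm$n_replicates, 50L)
})
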