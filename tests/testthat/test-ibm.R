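test_that("emergence times are uniform, synchronous in the limit, and reproducible", {
  x <- sample_emergence_times(1e4, t_l = 1, seed = 11)
  se <- 1 / sqrt(12 * 1e4)
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  expect_true(all(x >= 0 & x <= 1))
  y <- sample_emergence_times(100, t_l = 1e-9, seed = 3)
  expect_true(all(y < 1e-8))
  expect_identical(sample_emergence_times(50, 1, seed = 5),
                   sample_emergence_times(50, 1, seed = 5))
})

test_that("single realisations honour the event-ordering rules", {
  cfg <- ibm_config(baseline_params(), n_hosts = 2000, seed = 42,
                    n_replicates = 2)
  sim <- simulate_season_ibm(cfg)
  ev <- sim$events
  inf <- ev[!is.na(ev$t_infection), ]
  expect_true(all(inf$t_infection >= inf$emergence))
  rel <- ev[ev$released, ]
  # releases happen exactly tau after infection, before season end, and
  # never from hosts already dead of background causes
  expect_equal(rel$t_release, rel$t_infection + cfg$params$tau)
  expect_true(all(rel$t_release <= cfg$params$T))
  expect_true(all(rel$t_release < rel$t_background))
  expect_equal(sim$v2_end_count, sum(ev$progeny_surviving))
  # hosts killed by background mortality release nothing
  bg_dead <- ev[!is.na(ev$t_infection) & !ev$released &
                  ev$t_background < ev$t_infection + cfg$params$tau, ]
  expect_true(all(bg_dead$progeny_surviving == 0))
  # determinism under the seed
  sim2 <- simulate_season_ibm(cfg)
  expect_identical(sim$events, sim2$events)
})

test_that("degenerate configurations produce no surviving progeny", {
  p0 <- baseline_params(beta = 0)
  expect_equal(simulate_season_ibm(ibm_config(p0, n_hosts = 500,
                                              seed = 1))$v2_end_count, 0)
  p1 <- baseline_params(tau = 3.5)
  expect_equal(simulate_season_ibm(ibm_config(p1, n_hosts = 500,
                                              seed = 1))$v2_end_count, 0)
})

test_that("the stochastic mean converges on the deterministic season output", {
  p <- baseline_params()
  out_small <- ibm_replicates(ibm_config(p, n_hosts = 1e3, seed = 101,
                                         n_replicates = 30))
  out_big <- ibm_replicates(ibm_config(p, n_hosts = 1e4, seed = 202,
                                       n_replicates = 30))
  expect_lt(abs(out_small$z), 3)
  expect_lt(abs(out_big$z), 3)
  # sampling noise around the deterministic limit shrinks with scale
  expect_lt(out_big$se / out_big$deterministic,
            out_small$se / out_small$deterministic)
})
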