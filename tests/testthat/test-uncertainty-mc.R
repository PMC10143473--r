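test_that("distribution specs validate and sample correctly", {
  expect_equal(sample_dist(dist_spec("point", value = 5), 4), rep(5, 4))
  expect_error(dist_spec("normal", mean = 0, sd = -1),
               class = "crsoil_config_error")
  expect_error(dist_spec("uniform", min = 2, max = 1),
               class = "crsoil_config_error")
  expect_error(dist_spec("normal", mean = 0, sd = 1, truncation = c(3, 2)),
               class = "crsoil_config_error")
  expect_error(dist_spec("point", value = 5, truncation = c(0, 1)),
               class = "crsoil_config_error")

  set.seed(1)
  u <- sample_dist(dist_spec("uniform", min = 0, max = 1), 1e5)
  expect_lt(abs(mean(u) - 0.5), 0.01)   # law of large numbers

  # truncation never yields values outside the interval
  z <- sample_dist(dist_spec("normal", mean = 0, sd = 2,
                             truncation = c(0, Inf)), 1e4)
  expect_true(all(z >= 0))
  ln <- sample_dist(dist_spec("lognormal", meanlog = 0, sdlog = 1,
                              truncation = c(0.5, 2)), 1e4)
  expect_true(all(ln >= 0.5 & ln <= 2))

  tri <- sample_dist(dist_spec("triangular", min = 0, mode = 1, max = 5), 1e5)
  expect_true(all(tri >= 0 & tri <= 5))
  expect_lt(abs(mean(tri) - 2), 0.02)   # (min + mode + max) / 3
})

test_that("point-mass Monte Carlo collapses onto the deterministic model", {
  p <- default_receptors()$child
  tox <- toxicity_params()
  det <- hazard_quotients(150, p, tox)$hq_total
  mc <- mc_spec(n_iter = 500, seed = 3,
                params = list(cn = dist_spec("point", value = 150)))
  res <- run_mc(NA, p, tox, mc)
  expect_identical(res$mean, det)
  expect_identical(res$p5, det)
  expect_identical(res$p50, det)
  expect_identical(res$p95, det)
  expect_identical(res$sd, 0)
})

test_that("Monte Carlo runs are reproducible from the seed", {
  p <- default_receptors()$adult_female
  mc <- mc_spec(n_iter = 1000, seed = 17,
                params = list(cn = dist_spec("lognormal", meanlog = 5,
                                             sdlog = 1.2),
                              BW = dist_spec("normal", mean = 57, sd = 5,
                                             truncation = c(30, 100))))
  r1 <- run_mc(NA, p, mc = mc, store_draws = TRUE)
  r2 <- run_mc(NA, p, mc = mc, store_draws = TRUE)
  expect_identical(unclass(r1), unclass(r2))
  r3 <- run_mc(NA, p, mc = mc_spec(1000, 18, mc$params))
  expect_false(identical(r1$mean, r3$mean))
})

test_that("lognormal concentration runs match the closed-form mean", {
  p <- default_receptors()$child
  tox <- toxicity_params()
  mu <- log(700); sigma <- 1
  k <- hazard_quotients(1, p, tox)$hq_total      # HQ per unit concentration
  analytic <- k * exp(mu + sigma^2 / 2)
  mc <- mc_spec(n_iter = 10000, seed = 7,
                params = list(cn = dist_spec("lognormal", meanlog = mu,
                                             sdlog = sigma)))
  res <- run_mc(NA, p, tox, mc)
  se <- res$sd / sqrt(res$n_iter)
  expect_lt(abs(res$mean - analytic), 3 * se)
  expect_true(res$p5 <= res$p50 && res$p50 <= res$p95)
  expect_equal(res$prob_exceed_1,
               mean(run_mc(NA, p, tox, mc, store_draws = TRUE)$draws$hq_total > 1))
})

test_that("rank sensitivity identifies monotone drivers and their signs", {
  p <- default_receptors()$child
  only_cn <- run_mc(NA, p, mc = mc_spec(2000, 5, list(
    cn = dist_spec("lognormal", meanlog = 5, sdlog = 1))),
    store_draws = TRUE)
  rs <- rank_sensitivity(only_cn)
  expect_equal(rs$parameter, "cn")
  expect_equal(abs(rs$rho), 1)

  both <- run_mc(100, p, mc = mc_spec(5000, 5, list(
    BW = dist_spec("lognormal", meanlog = log(15), sdlog = 0.2),
    IngR = dist_spec("lognormal", meanlog = log(200), sdlog = 0.2))),
    store_draws = TRUE)
  rb <- rank_sensitivity(both)
  expect_lt(rb$rho[rb$parameter == "BW"], 0)      # denominator-only: negative
  expect_gt(rb$rho[rb$parameter == "IngR"], 0)
  # equal-variance multiplicative inputs have comparable |rho|
  expect_lt(abs(abs(rb$rho[1]) - abs(rb$rho[2])), 0.15)

  det <- run_mc(100, p, mc = mc_spec(200, 5), store_draws = TRUE)
  expect_warning(out <- rank_sensitivity(det), "no stochastic")
  expect_equal(nrow(out), 0)
})

test_that("degenerate or tiny run specs are flagged", {
  p <- default_receptors()$child
  expect_warning(run_mc(10, p, mc = mc_spec(50, 1)), "unstable")
  expect_error(mc_spec(0), class = "crsoil_config_error")
  expect_error(mc_spec(100, 1, list(cn = 5)), class = "crsoil_config_error")
  expect_error(mc_spec(100, 1, list(foo = dist_spec("point", value = 1))),
               class = "crsoil_config_error")
})
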