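test_that("every forecasting rule fixes a constant history", {
  h <- snapshot_history(z_prev = 0.37)
  for (rule in 1:4)
    expect_equal(forecast_heuristic(rule, h, prev_forecast = 0.37), 0.37)
})

test_that("rules reproduce their printed arithmetic", {
  h <- snapshot_history(z_prev = 0.5, z_prev2 = 0.4, z_ave = 0.6, count = 3)
  p <- hsm_params()
  expect_equal(forecast_heuristic(2, h, 0, p), 0.5 + 0.44 * 0.1)     # 0.544
  expect_equal(forecast_heuristic(3, h, 0, p), 0.5 - 0.44 * 0.1)     # 0.456
  expect_equal(forecast_heuristic(4, h, 0, p), 0.5 * (0.6 + 0.5) + 0.1)
  expect_equal(forecast_heuristic(1, h, 0.8, p), 0.63 * 0.5 + 0.37 * 0.8)
  expect_error(forecast_heuristic(5, h, 0, p), "unknown")
})

test_that("forecasts are clipped into the unit interval on wild histories", {
  p <- hsm_params()
  set.seed(3)
  for (i in 1:200) {
    vals <- runif(3)
    h <- snapshot_history(z_prev = vals[1], z_prev2 = vals[2],
                          z_ave = vals[3], count = sample(1:20, 1))
    f <- forecast_all(h, prev_forecasts = runif(4), params = p)
    expect_true(all(f >= 0 & f <= 1))
  }
  # trend rule exits [0, 1] without clipping: 0.9 + 0.44 * 0.8 > 1
  h <- snapshot_history(z_prev = 0.9, z_prev2 = 0.1)
  expect_equal(forecast_heuristic(2, h, 0, p), 1)
  h2 <- snapshot_history(z_prev = 0.1, z_prev2 = 0.9)
  expect_equal(forecast_heuristic(4, h2, 0, p), 0)
})

test_that("snapshot history maintains an exact running mean", {
  h <- snapshot_history(0.5)
  obs <- c(0.1, 0.9, 0.4, 0.7)
  for (z in obs) h <- push_snapshot(h, z)
  expect_equal(h$z_ave, mean(c(0.5, obs)))
  expect_equal(h$count, 5L)
  expect_equal(h$z_prev, 0.7)
  expect_equal(h$z_prev2, 0.4)
})

test_that("fitness follows the discounted squared-error recursion", {
  st <- heuristic_state(forecasts = rep(0.5, 4))
  # perfect forecast leaves zero fitness
  st1 <- update_fitness(st, 0.5)
  expect_equal(st1$fitness, rep(0, 4))

  # printed example: error 0.1, eta 0.7, prior -0.02
  st$fitness <- rep(-0.02, 4)
  st$forecasts <- rep(0.4, 4)
  st2 <- update_fitness(st, 0.5, hsm_params())
  expect_equal(st2$fitness, rep(-0.01 + 0.7 * (-0.02), 4))

  # memoryless limit
  st3 <- update_fitness(st, 0.5, hsm_params(eta = 0))
  expect_equal(st3$fitness, rep(-0.01, 4))

  # closed-form discounted sum on synthetic error sequences
  set.seed(8)
  for (rep in 1:20) {
    eta <- runif(1)
    errs <- runif(12, -0.3, 0.3)
    st <- heuristic_state(forecasts = rep(0, 4))
    for (e in errs) {
      st$forecasts <- rep(0.5 - e, 4)
      st <- update_fitness(st, 0.5, hsm_params(eta = eta))
    }
    expect_equal(st$fitness[1], discounted_fitness_oracle(errs, eta),
                 tolerance = 1e-12)
  }
})

test_that("selection mixes inertia with a stabilized softmax", {
  st <- heuristic_state(forecasts = rep(0.5, 4), fitness = rep(-0.3, 4),
                        current = 2L)
  pr <- selection_probabilities(st, hsm_params(rho = 0.9))
  expect_equal(sum(pr), 1)
  expect_equal(pr, c(0.025, 0.925, 0.025, 0.025))

  pr0 <- selection_probabilities(st, hsm_params(rho = 0))
  expect_equal(pr0, rep(0.25, 4))

  # phi = 0 ignores fitness entirely
  st$fitness <- c(-5, -1, -9, -2)
  prf <- selection_probabilities(st, hsm_params(rho = 0.4, phi = 0))
  expect_equal(prf, 0.6 * rep(0.25, 4) + 0.4 * c(0, 1, 0, 0))

  # sharp phi concentrates the free mass on the best heuristic
  prs <- selection_probabilities(st, hsm_params(rho = 0, phi = 1e4))
  expect_equal(prs[2], 1, tolerance = 1e-10)

  # large fitness magnitudes do not overflow (max-shift)
  st$fitness <- c(-800, -400, -600, -500)
  prb <- selection_probabilities(st, hsm_params(rho = 0.9, phi = 100))
  expect_true(all(is.finite(prb)))
  expect_equal(sum(prb), 1)

  # the incumbent never drops below rho
  set.seed(12)
  for (i in 1:50) {
    st$fitness <- -runif(4)
    st$current <- sample(1:4, 1)
    pr <- selection_probabilities(st, hsm_params(rho = 0.9))
    expect_gte(pr[st$current], 0.9)
  }
})

test_that("heuristic draws follow the distribution and are reproducible", {
  expect_equal(sample_heuristic(c(1, 0, 0, 0), u = 0.73), 1L)
  expect_equal(sample_heuristic(c(0, 0, 0, 1), u = 0.002), 4L)

  u <- withr::with_seed(42, runif(1e5))
  draws <- vapply(u, function(ui)
    sample_heuristic(rep(0.25, 4), u = ui), integer(1))
  freq <- tabulate(draws, 4) / length(draws)
  se <- sqrt(0.25 * 0.75 / length(draws))
  expect_true(all(abs(freq - 0.25) < 3 * se))

  expect_identical(
    withr::with_seed(5, replicate(20, sample_heuristic(c(0.1, 0.2, 0.3, 0.4)))),
    withr::with_seed(5, replicate(20, sample_heuristic(c(0.1, 0.2, 0.3, 0.4)))))
})
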