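fie_default <- solve_fie(default_payoffs())

test_that("outcome classification compares trailing means to the equilibrium", {
  expect_equal(classify_outcome(rep(0.5, 150), fie_default), "abundant")
  expect_equal(classify_outcome(rep(0.2, 150), fie_default), "scarce")
  # exact tie goes to abundant by convention
  expect_equal(classify_outcome(rep(fie_default$n_star, 100), fie_default),
               "abundant")
  expect_error(classify_outcome(rep(0.5, 100),
                                solve_fie(default_payoffs(as_printed = TRUE))),
               "equilibrium")

  expect_equal(ensemble_split(c("abundant", "abundant")), 0)
  expect_equal(ensemble_split(c("scarce", "abundant", "scarce", "scarce")),
               0.75)
})

test_that("ensembles tabulate per-run outcomes with sequential seeds", {
  cfg <- small_config()
  runs <- run_ensemble(cfg, n_runs = 4, base_seed = 100)
  expect_equal(nrow(runs), 4)
  expect_equal(runs$seed, 100:103)
  expect_true(all(runs$class %in% c("abundant", "scarce")))
  expect_true(all(runs$mean_n_tail >= 0 & runs$mean_n_tail <= 1))
  expect_s3_class(attr(runs, "fie"), "fie_point")
  # rerunning a seed reproduces its trailing mean
  tr <- run_sim(local({ c2 <- cfg; c2$seed <- 101L; c2 }))
  expect_equal(runs$mean_n_tail[2], mean(tr$tail_n))
})

test_that("effort-degree correlation is signed by who holds high effort", {
  # star: hub on high effort, leaves on low -> positive by construction
  st <- star_network(9)
  expect_gt(effort_degree_correlation(c(0L, rep(1L, 9)), st$degrees), 0)
  expect_lt(effort_degree_correlation(c(1L, rep(0L, 9)), st$degrees), 0)
  expect_equal(effort_degree_correlation(rep(1L, 10), st$degrees), 0)
  expect_equal(effort_degree_correlation(c(0L, 1L), c(3, 3)), 0)
})

test_that("majority illusion counts locally inverted majorities", {
  st <- star_network(9)
  # hub extracts high while all nine leaves extract low: every leaf's
  # neighbourhood majority (the hub) contradicts the global majority
  expect_equal(majority_illusion_index(st, c(0L, rep(1L, 9))), 0.9)
  expect_equal(majority_illusion_index(st, rep(1L, 10)), 0)
  expect_equal(majority_illusion_index(st, rep(0L, 10)), 0)
  # complete graphs cannot sustain the illusion
  cn <- complete_network(7)
  for (k in c(2, 5)) {
    S <- c(rep(1L, k), rep(0L, 7 - k))
    expect_equal(majority_illusion_index(cn, S), 0)
  }
})

test_that("advantage binning sorts degrees across the zero line", {
  diag <- data.frame(step = rep(1:100, each = 2),
                     degree = rep(c(900, 50), 100),
                     A_H = rep(c(0.1, -0.1), 100))
  tab <- degree_advantage_table(diag, last_k = 100, breaks = 4)
  expect_equal(sum(tab$count), 200)
  expect_equal(sum(tab$frequency), 1)
  expect_gt(tab$mean_degree[which.max(tab$A_H_mid)],
            tab$mean_degree[which.min(tab$A_H_mid)])

  flat <- data.frame(step = 1:10, degree = 5, A_H = 0.2)
  tabf <- degree_advantage_table(flat, last_k = 10)
  expect_equal(nrow(tabf), 1)
  expect_equal(tabf$frequency, 1)
})

test_that("replicator field vanishes at the equilibrium and the boundary", {
  p <- default_payoffs()
  f <- replicator_field(0.3, 0.3, p)
  expect_equal(f$zdot, 0, tolerance = 1e-12)
  expect_equal(f$ndot, 0, tolerance = 1e-12)
  expect_equal(replicator_field(0, 0.7, p)$zdot, 0)
  expect_equal(replicator_field(1, 0.1, p)$zdot, 0)
  # interior signs: abundant perceptions push low effort down
  expect_lt(replicator_field(0.5, 0.5, p)$zdot, 0)
  expect_gt(replicator_field(0.5, 0.1, p)$zdot, 0)
})

test_that("the replicator flow converges to the stable interior point", {
  p <- default_payoffs()
  path <- integrate_replicator(0.5, 0.5, p, epsilon = 0.25, alpha = 1e-3,
                               horizon = 30000, dt = 2)
  last <- path[nrow(path), ]
  expect_equal(last$z, 0.3, tolerance = 1e-3)
  expect_equal(last$n, 0.3, tolerance = 1e-3)

  # numeric linearization: both eigenvalues in the left half plane
  h <- 1e-6
  J <- matrix(0, 2, 2)
  f0 <- unlist(replicator_field(0.3, 0.3, p, 0.25, 1e-3))
  fz <- unlist(replicator_field(0.3 + h, 0.3, p, 0.25, 1e-3))
  fn <- unlist(replicator_field(0.3, 0.3 + h, p, 0.25, 1e-3))
  J[, 1] <- (fz - f0) / h
  J[, 2] <- (fn - f0) / h
  expect_true(all(Re(eigen(J)$values) < 0))
})

test_that("scaled-down sweeps expose the skewness and impact gradients", {
  cfg <- sim_config(P = 120, T = 3000, lam = 20, seed = 500, tail_window = 100)
  sk <- sweep_skewness(cfg, lam_grid = c(20, 100), runs_per_level = 2)
  expect_named(sk, c("lam", "seed", "skewness", "mean_n_tail", "class"))
  expect_equal(nrow(sk), 4)
  expect_gt(mean(sk$skewness[sk$lam == 100]),
            mean(sk$skewness[sk$lam == 20]))

  im <- sweep_impact(cfg, nu_grid = c(0, 2), runs_per_level = 2)
  expect_named(im, c("nu", "seed", "mean_n_tail", "class"))
  expect_equal(nrow(im), 4)
  expect_true(all(im$mean_n_tail >= 0 & im$mean_n_tail <= 1))
})

test_that("the illusion in a settled run beats degree-preserving chance", {
  # extreme-skew run: leaves observe only hubs, so whichever strategy the
  # hubs carry is locally over-represented across most of the population
  tr <- run_sim(sim_config(lam = 950, T = 20000, seed = 2))
  S <- tr$final$strategy
  obs <- majority_illusion_index(tr$network, S)
  perm <- withr::with_seed(1, vapply(1:99, function(i)
    majority_illusion_index(tr$network, sample(S)), numeric(1)))
  expect_gt(obs, max(perm))
  expect_gt(obs, 0.5)
})
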