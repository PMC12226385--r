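test_that("payoffs are evaluated per the environment-weighted matrix game", {
  # constant matrix: both strategies earn the constant
  m <- corner_payoffs(3, 3, 3, 3, 7, 7, 7, 7)
  pp <- payoffs(m, z = 0.2, n = 0)
  expect_equal(pp$piL, 3)
  expect_equal(pp$piH, 3)

  # default affine parameters at the prosperous all-low corner
  a <- default_payoffs("affine")
  pp <- payoffs(a, 1, 1)
  expect_equal(pp$piL - pp$piH, -0.7, tolerance = 1e-12)

  # interior point, closed form of the default advantage
  pp <- payoffs(a, 0.5, 0.5)
  expect_equal(pp$piL - pp$piH, 0.3 - 0.25 * 0.5 - 0.75 * 0.5,
               tolerance = 1e-12)

  expect_error(payoffs(a, 1.2, 0.5), "0, 1")
  expect_error(payoffs(a, 0.5, -0.1), "0, 1")
})

test_that("advantage_low reproduces the corner incentives with their signs", {
  p <- default_payoffs()
  expect_equal(advantage_low(p, 1, 0), 0.05, tolerance = 1e-12)   # deltaL0
  expect_equal(advantage_low(p, 0, 1), -0.45, tolerance = 1e-12)  # -DeltaH1
  expect_equal(advantage_low(p, 0, 0), 0.3, tolerance = 1e-12)    # deltaH0
  expect_equal(advantage_low(p, 1, 1), -0.7, tolerance = 1e-12)   # -DeltaL1
  expect_equal(advantage_high(p, 1, 0), -0.05, tolerance = 1e-12)
})

test_that("default advantage has the closed form 0.3 - 0.25 z - 0.75 n", {
  p <- default_payoffs()
  grid <- expand.grid(z = seq(0, 1, by = 0.1), n = seq(0, 1, by = 0.1))
  expect_equal(advantage_low(p, grid$z, grid$n),
               0.3 - 0.25 * grid$z - 0.75 * grid$n, tolerance = 1e-12)
  # anti-coordination: d(piH - piL)/dz = +0.25 everywhere
  dz <- advantage_high(p, grid$z, grid$n + 0) -
    advantage_high(p, pmax(grid$z - 0.1, 0), grid$n)
  expect_true(all(abs(dz[grid$z >= 0.1] - 0.025) < 1e-12))
})

test_that("the three parameterizations agree through the mapping tables", {
  a <- default_payoffs("affine")
  m <- corners_from_affine(a)
  p <- incentives_from_affine(a)
  expect_equal(unname(unclass(p)), c(0.3, 0.05, 0.7, 0.45), tolerance = 1e-12)
  expect_equal(unclass(corner_incentives(m)), unclass(p), tolerance = 1e-12)
  # gamma2L = S1 - S0 = 1.5 for the defaults
  expect_equal(unclass(m)[["S1"]] - unclass(m)[["S0"]], 1.5, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:200) {
    m <- random_corners()
    a <- affine_from_corners(m)
    z <- runif(1); n <- runif(1)
    va <- advantage_low(a, z, n)
    vm <- advantage_low(m, z, n)
    vp <- advantage_low(corner_incentives(m), z, n)
    expect_lt(abs(va - vm), 1e-10)
    expect_lt(abs(vp - vm), 1e-10)
  }
})

test_that("affine/corner conversion round-trips losslessly", {
  a0 <- affine_params(0, 0, 0, 0, 0, 0, 0, 0)
  m0 <- corners_from_affine(a0)
  expect_true(all(unclass(m0) == 0))

  set.seed(21)
  for (i in 1:100) {
    a <- do.call(affine_params, as.list(rnorm(8)))
    back <- affine_from_corners(corners_from_affine(a))
    expect_lt(max(abs(unclass(back) - unclass(a))), 1e-12)
    m <- random_corners()
    back_m <- corners_from_affine(affine_from_corners(m))
    expect_lt(max(abs(unclass(back_m) - unclass(m))), 1e-12)
  }

  # identical rows give zero incentives
  m <- corner_payoffs(R0 = 1, S0 = 2, T0 = 1, P0 = 2,
                      R1 = 5, S1 = 4, T1 = 5, P1 = 4)
  expect_true(all(unclass(corner_incentives(m)) == 0))

  # gauge reconstruction from incentives preserves the advantage
  p <- default_payoffs("incentive")
  m <- corners_from_incentives(p)
  expect_equal(unclass(corner_incentives(m)), unclass(p), tolerance = 1e-14)
})

test_that("solve_fie finds the stable interior equilibrium", {
  fie <- solve_fie(default_payoffs())
  expect_true(fie$exists)
  expect_equal(fie$n_star, 0.3, tolerance = 1e-10)
  expect_equal(fie$high_effort_share, 0.7, tolerance = 1e-10)
  expect_true(fie$stable)
  expect_lt(abs(advantage_low(default_payoffs(), fie$n_star, fie$n_star)),
            1e-10)
  # independent bisection oracle
  expect_equal(fie$n_star, fie_bisection_oracle(default_payoffs()),
               tolerance = 1e-9)

  # antisymmetric incentives put the equilibrium at one half
  sym <- incentive_params(deltaH0 = 0.3, deltaL0 = 0.1,
                          DeltaL1 = 0.3, DeltaH1 = 0.1)
  expect_equal(solve_fie(sym)$n_star, 0.5, tolerance = 1e-10)

  # the literal printed sign admits no interior equilibrium
  expect_false(solve_fie(default_payoffs(as_printed = TRUE))$exists)

  # identically zero advantage is flagged degenerate
  deg <- solve_fie(incentive_params(0, 0, 0, 0))
  expect_false(deg$exists)
  expect_true(deg$degenerate)
})

test_that("solve_fie agrees with bisection on random stable games", {
  set.seed(99)
  found <- 0
  while (found < 20) {
    p <- incentive_params(runif(1, 0, 1), runif(1, -0.5, 0.5),
                          runif(1, 0, 1), runif(1, 0, 1))
    nb <- fie_bisection_oracle(p)
    if (is.na(nb)) next
    fie <- solve_fie(p)
    expect_true(fie$exists)
    expect_equal(fie$n_star, nb, tolerance = 1e-8)
    found <- found + 1
  }
})
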