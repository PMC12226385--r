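#' Environment-dependent game: parameterizations of the payoff structure
#'
#' The extraction game is a 2x2 matrix game whose payoffs interpolate linearly
#' between a degraded environment (`n = 0`) and a prosperous one (`n = 1`).
#' Three equivalent parameterizations are supported:
#'
#' * **corner payoffs** `R0, S0, T0, P0, R1, S1, T1, P1` — the eight entries of
#'   the two payoff matrices. Rows: first = low effort, second = high effort;
#'   columns: first = others on low effort, second = others on high effort.
#' * **incentive differences** `deltaH0, deltaL0, DeltaL1, DeltaH1` — the four
#'   payoff differences at the corners of the `(z, n)` state space.
#'   Lower-case deltas are incentives to switch to low effort (depleted
#'   environment), capital Deltas are incentives to switch to high effort
#'   (bountiful environment).
#' * **affine coefficients** `alphaL, alphaH, g1L, g2L, g3L, g1H, g2H, g3H`
#'   of `pi^s(z, n) = alpha^s + g1^s z + g2^s n + g3^s n z`.
#'
#' The incentive form determines decisions completely: absolute payoff levels
#' are gauge freedom. When corners must be reconstructed from incentives alone
#' the baseline entries `T0, P0, R1, S1` are set to zero.
#'
#' @param R0,S0,T0,P0,R1,S1,T1,P1 corner payoffs (finite reals).
#' @return An object of class `corner_payoffs`, `incentive_params` or
#'   `affine_params` (a named numeric vector with a class attribute).
#' @seealso [default_payoffs()], [payoffs()], [advantage_low()], [solve_fie()]
#' @export
corner_payoffs <- function(R0, S0, T0, P0, R1, S1, T1, P1) {
  x <- c(R0 = R0, S0 = S0, T0 = T0, P0 = P0,
         R1 = R1, S1 = S1, T1 = T1, P1 = P1)
  stopifnot(is.numeric(x), length(x) == 8L, all(is.finite(x)))
  structure(x, class = "corner_payoffs")
}

#' @rdname corner_payoffs
#' @param deltaH0 payoff advantage of an early adopter of low effort in a
#'   depleted environment (`S0 - P0`).
#' @param deltaL0 payoff advantage of a late adopter of low effort in a
#'   depleted environment (`R0 - T0`).
#' @param DeltaL1 payoff advantage of an early adopter of high effort in a
#'   bountiful environment (`T1 - R1`).
#' @param DeltaH1 payoff advantage of a late adopter of high effort in a
#'   bountiful environment (`P1 - S1`).
#' @export
incentive_params <- function(deltaH0, deltaL0, DeltaL1, DeltaH1) {
  x <- c(deltaH0 = deltaH0, deltaL0 = deltaL0,
         DeltaL1 = DeltaL1, DeltaH1 = DeltaH1)
  stopifnot(is.numeric(x), length(x) == 4L, all(is.finite(x)))
  structure(x, class = "incentive_params")
}

#' @rdname corner_payoffs
#' @param alphaL,alphaH intercepts of the low/high-effort payoff planes.
#' @param g1L,g1H linear coefficient of the expected low-effort fraction `z`.
#' @param g2L,g2H linear coefficient of the environment `n`.
#' @param g3L,g3H bilinear `n * z` coefficient (0 in the default setting).
#' @export
affine_params <- function(alphaL, alphaH, g1L, g2L, g3L, g1H, g2H, g3H) {
  x <- c(alphaL = alphaL, alphaH = alphaH,
         g1L = g1L, g2L = g2L, g3L = g3L,
         g1H = g1H, g2H = g2H, g3H = g3H)
  stopifnot(is.numeric(x), length(x) == 8L, all(is.finite(x)))
  structure(x, class = "affine_params")
}

#' Default payoff configuration
#'
#' Returns the default anti-coordination payoff configuration in any of the
#' three parameterizations. The default uses the sign-resolved incentive
#' `deltaH0 = alphaL - alphaH = +0.3`: a positive early-adopter advantage of
#' low effort in a depleted environment (`S0 - P0 > 0`) is required for an
#' interior full-information equilibrium to exist, and `+0.3` places it at
#' `n* = 0.3` (70% of users on high effort). `as_printed = TRUE` selects the
#' literal tabulated value `-0.3`, under which no interior equilibrium exists
#' ([solve_fie()] then reports `exists = FALSE`).
#'
#' @param form which parameterization to return.
#' @param as_printed use the literal `-0.3` instead of the sign-resolved
#'   `+0.3` for `deltaH0` / `alphaL - alphaH`.
#' @return a payoff parameter object (see [corner_payoffs()]).
#' @examples
#' advantage_low(default_payoffs(), z = 1, n = 0)  # deltaL0 = 0.05
#' solve_fie(default_payoffs())$n_star             # 0.3
#' @export
default_payoffs <- function(form = c("incentive", "affine", "corner"),
                            as_printed = FALSE) {
  form <- match.arg(form)
  aL <- if (as_printed) -0.3 else 0.3
  a <- affine_params(alphaL = aL, alphaH = 0,
                     g1L = 0.5, g2L = 1.5, g3L = 0,
                     g1H = 0.75, g2H = 2.25, g3H = 0)
  switch(form,
         affine = a,
         incentive = incentives_from_affine(a),
         corner = corners_from_affine(a))
}

.check_zn <- function(z, n) {
  if (!is.numeric(z) || !is.numeric(n) ||
      any(!is.finite(z)) || any(!is.finite(n)) ||
      any(z < 0 | z > 1) || any(n < 0 | n > 1))
    stop("`z` and `n` must lie in [0, 1]", call. = FALSE)
}

# single formula shared with the compiled engine (same operation order)
.adv_low_inc <- function(dH0, dL0, DL1, DH1, z, n) {
  (1 - n) * (dL0 * z + dH0 * (1 - z)) - n * (DL1 * z + DH1 * (1 - z))
}

#' Payoffs of the two strategies at a point of the state space
#'
#' Evaluates the low-effort and high-effort payoffs at expected low-effort
#' fraction `z` and environmental state `n`. Both are affine in `z` and in
#' `n`. For `incentive_params` the gauge corners (baselines zero) are used, so
#' only the difference `piL - piH` is parameterization-independent.
#'
#' @param params a payoff parameter object.
#' @param z expected fraction of the population extracting with low effort,
#'   in `[0, 1]`.
#' @param n environmental state in `[0, 1]` (0 = fully degraded).
#' @return a list with numeric components `piL` and `piH` (vectorized over
#'   `z`/`n`).
#' @export
payoffs <- function(params, z, n) UseMethod("payoffs")

#' @export
payoffs.corner_payoffs <- function(params, z, n) {
  .check_zn(z, n)
  p <- unclass(params)
  piL <- (1 - n) * (p[["R0"]] * z + p[["S0"]] * (1 - z)) +
    n * (p[["R1"]] * z + p[["S1"]] * (1 - z))
  piH <- (1 - n) * (p[["T0"]] * z + p[["P0"]] * (1 - z)) +
    n * (p[["T1"]] * z + p[["P1"]] * (1 - z))
  list(piL = piL, piH = piH)
}

#' @export
payoffs.affine_params <- function(params, z, n) {
  .check_zn(z, n)
  p <- unclass(params)
  list(piL = p[["alphaL"]] + p[["g1L"]] * z + p[["g2L"]] * n + p[["g3L"]] * n * z,
       piH = p[["alphaH"]] + p[["g1H"]] * z + p[["g2H"]] * n + p[["g3H"]] * n * z)
}

#' @export
payoffs.incentive_params <- function(params, z, n) {
  payoffs(corners_from_incentives(params), z, n)
}

#' Payoff advantage of low-effort (and high-effort) extraction
#'
#' `advantage_low()` returns `piL - piH`; `advantage_high()` its negation,
#' the quantity the decision rule consumes. With the default parameters
#' `advantage_low(z, n) = 0.3 - 0.25 z - 0.75 n`: the advantage of high
#' effort grows with the expected low-effort fraction (anti-coordination) and
#' with resource abundance.
#'
#' @inheritParams payoffs
#' @return numeric, vectorized over `z`/`n`.
#' @export
advantage_low <- function(params, z, n) UseMethod("advantage_low")

#' @export
advantage_low.incentive_params <- function(params, z, n) {
  .check_zn(z, n)
  p <- unclass(params)
  .adv_low_inc(p[["deltaH0"]], p[["deltaL0"]], p[["DeltaL1"]], p[["DeltaH1"]], z, n)
}

#' @export
advantage_low.default <- function(params, z, n) {
  pp <- payoffs(params, z, n)
  pp$piL - pp$piH
}

#' @rdname advantage_low
#' @export
advantage_high <- function(params, z, n) -advantage_low(params, z, n)

#' Conversions between payoff parameterizations
#'
#' `corner_incentives()` takes the four corner differences of a payoff matrix
#' pair. `affine_from_corners()` / `corners_from_affine()` are exact inverses.
#' `incentives_from_affine()` applies the difference identities directly.
#' `corners_from_incentives()` reconstructs corner matrices in the zero
#' baseline gauge (`T0 = P0 = R1 = S1 = 0`); absolute payoff levels are not
#' observable in the advantage, so any gauge yields identical dynamics.
#' `as_incentives()` converts any parameter object to `incentive_params`.
#'
#' @param m a `corner_payoffs` object.
#' @param a an `affine_params` object.
#' @param p an `incentive_params` object.
#' @param params any payoff parameter object.
#' @return the converted parameter object.
#' @export
corner_incentives <- function(m) {
  stopifnot(inherits(m, "corner_payoffs"))
  x <- unclass(m)
  incentive_params(deltaH0 = x[["S0"]] - x[["P0"]],
                   deltaL0 = x[["R0"]] - x[["T0"]],
                   DeltaL1 = x[["T1"]] - x[["R1"]],
                   DeltaH1 = x[["P1"]] - x[["S1"]])
}

#' @rdname corner_incentives
#' @export
affine_from_corners <- function(m) {
  stopifnot(inherits(m, "corner_payoffs"))
  x <- unclass(m)
  affine_params(alphaL = x[["S0"]],
                alphaH = x[["P0"]],
                g1L = x[["R0"]] - x[["S0"]],
                g2L = x[["S1"]] - x[["S0"]],
                g3L = x[["R1"]] - x[["R0"]] + x[["S0"]] - x[["S1"]],
                g1H = x[["T0"]] - x[["P0"]],
                g2H = x[["P1"]] - x[["P0"]],
                g3H = x[["P0"]] - x[["P1"]] + x[["T1"]] - x[["T0"]])
}

#' @rdname corner_incentives
#' @export
corners_from_affine <- function(a) {
  stopifnot(inherits(a, "affine_params"))
  x <- unclass(a)
  S0 <- x[["alphaL"]]; P0 <- x[["alphaH"]]
  R0 <- x[["g1L"]] + S0
  S1 <- x[["g2L"]] + S0
  R1 <- x[["g3L"]] + R0 - S0 + S1
  T0 <- x[["g1H"]] + P0
  P1 <- x[["g2H"]] + P0
  T1 <- x[["g3H"]] + P1 - P0 + T0
  corner_payoffs(R0 = R0, S0 = S0, T0 = T0, P0 = P0,
                 R1 = R1, S1 = S1, T1 = T1, P1 = P1)
}

#' @rdname corner_incentives
#' @export
incentives_from_affine <- function(a) {
  stopifnot(inherits(a, "affine_params"))
  x <- unclass(a)
  incentive_params(
    deltaH0 = x[["alphaL"]] - x[["alphaH"]],
    deltaL0 = x[["alphaL"]] - x[["alphaH"]] + x[["g1L"]] - x[["g1H"]],
    DeltaL1 = x[["alphaH"]] - x[["alphaL"]] + x[["g1H"]] - x[["g1L"]] +
      x[["g2H"]] - x[["g2L"]] + x[["g3H"]] - x[["g3L"]],
    DeltaH1 = x[["alphaH"]] - x[["alphaL"]] + x[["g2H"]] - x[["g2L"]])
}

#' @rdname corner_incentives
#' @export
corners_from_incentives <- function(p) {
  stopifnot(inherits(p, "incentive_params"))
  x <- unclass(p)
  corner_payoffs(R0 = x[["deltaL0"]], S0 = x[["deltaH0"]], T0 = 0, P0 = 0,
                 R1 = 0, S1 = 0, T1 = x[["DeltaL1"]], P1 = x[["DeltaH1"]])
}

#' @rdname corner_incentives
#' @export
as_incentives <- function(params) {
  if (inherits(params, "incentive_params")) return(params)
  if (inherits(params, "affine_params")) return(incentives_from_affine(params))
  if (inherits(params, "corner_payoffs")) return(corner_incentives(params))
  stop("not a payoff parameter object", call. = FALSE)
}

#' Full-information equilibrium of the extraction game
#'
#' Under full information and a well-mixed population, the equilibrium is the
#' state where the payoff advantage vanishes while the resource fixed point
#' equals the effective low-effort fraction: `advantage_low(n, n) = 0` with
#' `z* = n*`. This is a quadratic in `n`; roots in `[0, 1]` are found in
#' closed form and, when several exist, the dynamically stable one under the
#' anti-coordination feedback (negative slope of the advantage along the
#' diagonal) is returned.
#'
#' @param params a payoff parameter object.
#' @param tol numeric tolerance for root bracketing and degeneracy checks.
#' @return an object of class `fie_point`: a list with `n_star` (equilibrium
#'   resource state = low-effort fraction, `NA` if none), `exists`, `stable`,
#'   `high_effort_share` (`1 - n_star`), `roots` (all diagonal roots in
#'   `[0, 1]`) and `degenerate` (advantage identically zero).
#' @examples
#' solve_fie(default_payoffs())                      # n* = 0.3
#' solve_fie(default_payoffs(as_printed = TRUE))     # exists = FALSE
#' @export
solve_fie <- function(params, tol = 1e-12) {
  p <- unclass(as_incentives(params))
  dH0 <- p[["deltaH0"]]; dL0 <- p[["deltaL0"]]
  DL1 <- p[["DeltaL1"]]; DH1 <- p[["DeltaH1"]]
  # advantage_low(n, n) = a n^2 + b n + c
  a <- dH0 - dL0 + DH1 - DL1
  b <- dL0 - 2 * dH0 - DH1
  c <- dH0

  out <- structure(list(n_star = NA_real_, exists = FALSE, stable = NA,
                        high_effort_share = NA_real_, roots = numeric(0),
                        degenerate = FALSE, params = as_incentives(params)),
                   class = "fie_point")

  if (abs(a) < tol && abs(b) < tol && abs(c) < tol) {
    out$degenerate <- TRUE
    return(out)
  }
  roots <- if (abs(a) < tol) {
    if (abs(b) < tol) numeric(0) else -c / b
  } else {
    disc <- b * b - 4 * a * c
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- sort(unique(pmin(pmax(roots, -1), 2)))
  inside <- roots[roots >= -tol & roots <= 1 + tol]
  inside <- pmin(pmax(inside, 0), 1)
  out$roots <- inside
  if (length(inside) == 0L) return(out)

  slope <- 2 * a * inside + b            # d/dn advantage_low(n, n)
  stable <- slope < 0
  pick <- if (any(stable)) which(stable)[1L] else 1L
  out$n_star <- inside[pick]
  out$exists <- TRUE
  out$stable <- stable[pick]
  out$high_effort_share <- 1 - out$n_star
  out
}

#' @export
print.fie_point <- function(x, ...) {
  if (!x$exists) {
    cat("Full-information equilibrium: none",
        if (x$degenerate) "(advantage identically zero)" else "", "\n")
  } else {
    cat(sprintf(
      "Full-information equilibrium: n* = %.6g (%s), high-effort share = %.1f%%\n",
      x$n_star, if (isTRUE(x$stable)) "stable" else "unstable",
      100 * x$high_effort_share))
  }
  invisible(x)
}
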