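#' Heuristics switching model parameters
#'
#' Agents forecast the low-effort fraction of their neighbourhood with a menu
#' of four rules and switch between rules according to past forecasting
#' fitness. Defaults are the empirically grounded coefficients used
#' throughout the simulations.
#'
#' @param beta1 adaptive-expectations blend weight on the newest observation
#'   (0.63): the adaptive forecast mixes the last snapshot with the rule's
#'   own previous forecast.
#' @param beta2 trend-chasing extrapolation coefficient (0.44).
#' @param beta3 contrarian extrapolation coefficient (-0.44, must be
#'   negative: contrarians bet against the last observed change).
#' @param rho inertia: probability mass retained by the heuristic currently
#'   in use (0.9).
#' @param eta memory: geometric discount on past squared forecast errors in
#'   the fitness recursion (0.7).
#' @param phi choice intensity of the softmax over fitnesses (100;
#'   computed max-shifted since raw exponentials overflow at this intensity).
#' @return an object of class `hsm_params` (named numeric vector).
#' @export
hsm_params <- function(beta1 = 0.63, beta2 = 0.44, beta3 = -0.44,
                       rho = 0.9, eta = 0.7, phi = 100) {
  x <- c(beta1 = beta1, beta2 = beta2, beta3 = beta3,
         rho = rho, eta = eta, phi = phi)
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (x[["beta3"]] >= 0) stop("beta3 must be negative (contrarian rule)", call. = FALSE)
  if (x[["rho"]] < 0 || x[["rho"]] > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (x[["eta"]] < 0 || x[["eta"]] > 1) stop("eta must be in [0, 1]", call. = FALSE)
  if (x[["phi"]] < 0) stop("phi must be >= 0", call. = FALSE)
  structure(x, class = "hsm_params")
}

#' Snapshot history of an agent's neighbourhood observations
#'
#' Agents snapshot the low-effort fraction of their neighbourhood whenever
#' they act; the two most recent snapshots, the running mean of all
#' snapshots, and the snapshot count feed the forecasting rules. Time
#' subscripts in the rules are event time: an agent's own successive actions,
#' roughly one per `P` global steps.
#'
#' @param z_prev,z_prev2 most recent and second most recent snapshots, in
#'   `[0, 1]`. Before two snapshots exist both equal the agent's initial
#'   observation (cold start).
#' @param z_ave running mean of all snapshots taken so far.
#' @param count number of snapshots taken.
#' @return an object of class `snapshot_history`.
#' @export
snapshot_history <- function(z_prev, z_prev2 = z_prev, z_ave = z_prev,
                             count = 1L) {
  stopifnot(all(c(z_prev, z_prev2, z_ave) >= 0),
            all(c(z_prev, z_prev2, z_ave) <= 1), count >= 1L)
  structure(list(z_prev = z_prev, z_prev2 = z_prev2,
                 z_ave = z_ave, count = as.integer(count)),
            class = "snapshot_history")
}

#' @rdname snapshot_history
#' @param hist a `snapshot_history`.
#' @param z new snapshot in `[0, 1]`.
#' @export
push_snapshot <- function(hist, z) {
  stopifnot(inherits(hist, "snapshot_history"), z >= 0, z <= 1)
  cnt <- hist$count + 1L
  snapshot_history(z_prev = z, z_prev2 = hist$z_prev,
                   z_ave = hist$z_ave + (z - hist$z_ave) / cnt,
                   count = cnt)
}

#' Per-agent heuristic bookkeeping
#'
#' Tracks, for all four heuristics at once, the last forecast each issued and
#' its discounted-forecast-error fitness, plus the index of the heuristic
#' currently in use (1 adaptive, 2 trend-chasing, 3 contrarian, 4
#' anchoring-and-adjustment).
#'
#' @param forecasts length-4 numeric in `[0, 1]`.
#' @param fitness length-4 numeric, `<= 0` when initialized at 0 (discounted
#'   sum of negated squared errors).
#' @param current index in 1..4.
#' @return an object of class `heuristic_state`.
#' @export
heuristic_state <- function(forecasts, fitness = rep(0, 4), current = 1L) {
  stopifnot(length(forecasts) == 4L, length(fitness) == 4L,
            all(forecasts >= 0), all(forecasts <= 1),
            all(is.finite(fitness)), current %in% 1:4)
  structure(list(forecasts = as.numeric(forecasts),
                 fitness = as.numeric(fitness),
                 current = as.integer(current)),
            class = "heuristic_state")
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Forecasting rules
#'
#' `forecast_heuristic()` evaluates one of the four rules on a snapshot
#' history; `forecast_all()` evaluates all four. Writing `z[t-1]`, `z[t-2]`
#' for the last two snapshots, `zbar` for the running mean and `f` for the
#' rule's previous forecast:
#'
#' 1. adaptive: `beta1 * z[t-1] + (1 - beta1) * f`
#' 2. trend-chasing: `z[t-1] + beta2 * (z[t-1] - z[t-2])`
#' 3. contrarian: `z[t-1] + beta3 * (z[t-1] - z[t-2])` with `beta3 < 0`
#' 4. anchoring-and-adjustment: `0.5 * (zbar + z[t-1]) + (z[t-1] - z[t-2])`
#'
#' Forecasts are population fractions, so results are clipped to `[0, 1]`
#' (rules 2-4 can leave the unit interval).
#'
#' @param h heuristic index in 1..4.
#' @param hist a [snapshot_history()].
#' @param prev_forecast the rule's own previous forecast (used by rule 1).
#' @param params an [hsm_params()] object.
#' @return forecast in `[0, 1]`.
#' @examples
#' h <- snapshot_history(z_prev = 0.5, z_prev2 = 0.4)
#' forecast_heuristic(2, h, 0.5, hsm_params())  # 0.5 + 0.44 * 0.1 = 0.544
#' @export
forecast_heuristic <- function(h, hist, prev_forecast, params = hsm_params()) {
  stopifnot(inherits(hist, "snapshot_history"))
  if (!(length(h) == 1L && h %in% 1:4)) stop("unknown heuristic index", call. = FALSE)
  p <- unclass(params)
  s <- hist$z_prev
  d1 <- s - hist$z_prev2
  val <- switch(h,
                p[["beta1"]] * s + (1 - p[["beta1"]]) * prev_forecast,
                s + p[["beta2"]] * d1,
                s + p[["beta3"]] * d1,
                0.5 * (hist$z_ave + s) + d1)
  .clip01(val)
}

#' @rdname forecast_heuristic
#' @param prev_forecasts length-4 vector of each rule's previous forecast.
#' @export
forecast_all <- function(hist, prev_forecasts, params = hsm_params()) {
  # only rule 1 consumes its own previous forecast
  vapply(1:4, forecast_heuristic, numeric(1), hist = hist,
         prev_forecast = prev_forecasts[1L], params = params)
}

#' Fitness update of all heuristics
#'
#' At each of the agent's action events, every heuristic's fitness (not just
#' the one in use) is updated against the newly observed snapshot:
#' `f_h <- -(z_obs - forecast_h)^2 + eta * f_h`, a geometrically discounted
#' sum of negated squared forecast errors.
#'
#' @param state a [heuristic_state()].
#' @param z_observed the new snapshot in `[0, 1]`.
#' @param params an [hsm_params()] object.
#' @return the updated `heuristic_state` (forecasts unchanged; refresh them
#'   with [forecast_all()] after pushing the snapshot).
#' @export
update_fitness <- function(state, z_observed, params = hsm_params()) {
  stopifnot(inherits(state, "heuristic_state"),
            z_observed >= 0, z_observed <= 1)
  e <- z_observed - state$forecasts
  state$fitness <- -(e * e) + unclass(params)[["eta"]] * state$fitness
  state
}

#' Heuristic selection probabilities: inertia plus softmax
#'
#' With probability `rho` the incumbent heuristic is retained; the remaining
#' mass is spread by a softmax over fitnesses with intensity `phi`:
#' `P(h) = rho * [h = current] + (1 - rho) * exp(phi f_h) / sum_j exp(phi f_j)`.
#' The softmax is computed max-shifted for numerical safety.
#'
#' @param state a [heuristic_state()].
#' @param params an [hsm_params()] object.
#' @return probability vector of length 4 summing to 1; the incumbent's
#'   entry is always `>= rho`.
#' @export
selection_probabilities <- function(state, params = hsm_params()) {
  stopifnot(inherits(state, "heuristic_state"))
  p <- unclass(params)
  f <- state$fitness
  w <- exp(p[["phi"]] * (f - max(f)))
  s <- w[1L] + w[2L] + w[3L] + w[4L]
  pr <- (1 - p[["rho"]]) * (w / s)
  pr[state$current] <- pr[state$current] + p[["rho"]]
  pr
}

#' Draw a heuristic by inverse CDF
#'
#' Deterministic given the uniform draw: cumulative probabilities are
#' accumulated in fixed heuristic order 1..4.
#'
#' @param probs probability vector over the four heuristics.
#' @param u uniform(0,1) variate (defaults to a fresh draw).
#' @return heuristic index in 1..4.
#' @export
sample_heuristic <- function(probs, u = stats::runif(1)) {
  stopifnot(length(probs) == 4L, all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8)
  acc <- 0
  for (k in 1:4) {
    acc <- acc + probs[k]
    if (u <= acc) return(k)
  }
  4L
}
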