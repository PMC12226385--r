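#' Local observation of the neighbourhood
#'
#' The fraction of an agent's neighbours currently on the low-effort
#' strategy, read from its memory ledger (the agent itself is excluded;
#' isolated nodes cannot observe and are rejected at simulation setup).
#' When visibility weights are supplied (in simulation, `d_j^nu`, matching
#' the impact weighting of the effective extraction level the agent is
#' trying to estimate), the snapshot is the weighted neighbourhood fraction;
#' with `nu = 0` this reduces exactly to the plain mean.
#'
#' @param strategies integer vector of all agents' strategies (1 = low
#'   effort, 0 = high effort).
#' @param neighbors integer ids of the observing agent's neighbours.
#' @param vis optional positive per-agent visibility weights (full-length
#'   vector, indexed like `strategies`); `NULL` for the unweighted mean.
#' @return fraction in `[0, 1]`.
#' @export
local_snapshot <- function(strategies, neighbors, vis = NULL) {
  if (length(neighbors) == 0L)
    stop("isolated node: no neighbours to observe", call. = FALSE)
  if (is.null(vis))
    return(sum(strategies[neighbors]) / length(neighbors))
  sum(vis[neighbors] * strategies[neighbors]) / sum(vis[neighbors])
}

#' Perception update of the resource state
#'
#' Every global step, every agent nudges its perceived resource state toward
#' its local observation with the resource law of motion applied to local
#' information: `n_hat <- n_hat + (epsilon/P) * (snapshot - n_hat)`. The
#' update is a convex combination, so perceptions never leave `[0, 1]`.
#'
#' @param perceived current perceived resource state(s) in `[0, 1]`
#'   (vectorized).
#' @param snapshot local low-effort fraction(s) in `[0, 1]`.
#' @param epsilon relative speed of environmental vs strategic dynamics.
#' @param P population size (the per-step gap closure is `epsilon / P`).
#' @return updated perception(s).
#' @export
update_perception <- function(perceived, snapshot, epsilon, P) {
  stopifnot(all(perceived >= 0), all(perceived <= 1),
            all(snapshot >= 0), all(snapshot <= 1), epsilon / P > 0,
            epsilon / P < 1)
  perceived + (epsilon / P) * (snapshot - perceived)
}

#' Degree-sharpened logistic choice rule
#'
#' Probability of choosing high-effort extraction given the perceived payoff
#' advantage of high effort `A_H = piH - piL`:
#' `PH = 1 / (1 + exp(-d * sigma * A_H))`. Degree `d` sharpens the response:
#' well-connected agents act near-deterministically on small advantages
#' (their information is richer), low-degree agents remain noisy. The
#' exponent is clipped to +/-500 for numerical safety. Exactly symmetric:
#' `PH(-A) = 1 - PH(A)`.
#'
#' @param d agent degree (>= 1).
#' @param sigma slope of the sigmoid (> 0).
#' @param advantage_high perceived `piH - piL` (vectorized).
#' @return probability in (0, 1).
#' @examples
#' choice_prob_high(10, 0.1, 0.2)  # 1 / (1 + exp(-0.2))
#' @export
choice_prob_high <- function(d, sigma, advantage_high) {
  stopifnot(all(d >= 1), sigma > 0)
  x <- pmin(pmax(d * sigma * advantage_high, -500), 500)
  1 / (1 + exp(-x))
}

#' One agent's full decision event
#'
#' Executes the decision pipeline of the agent scheduled this step:
#' take a snapshot of the ledger, update all heuristic fitnesses against it,
#' push it into the history, select a heuristic (inertia + softmax), refresh
#' all forecasts, evaluate the payoff advantage of high effort at the
#' forecast and the agent's perceived resource state, and draw the strategy
#' from the logistic rule. Deterministic given the two uniforms, which lets
#' the pure-R engine replay the compiled engine draw-for-draw.
#'
#' @param agent list with fields `degree`, `perceived_n`, `hist`
#'   (a [snapshot_history()]) and `hstate` (a [heuristic_state()]).
#' @param snapshot current fraction of the agent's neighbours on low effort.
#' @param payoff an `incentive_params` object.
#' @param sigma logistic slope.
#' @param hsm an [hsm_params()] object.
#' @param u_select,u_act uniform(0,1) draws for heuristic selection and the
#'   action.
#' @return list with the updated `agent`, chosen `strategy` (1 low, 0 high),
#'   realized `A_H`, the `forecast` used, and the `heuristic` index.
#' @export
decide <- function(agent, snapshot, payoff, sigma, hsm,
                   u_select = stats::runif(1), u_act = stats::runif(1)) {
  hstate <- update_fitness(agent$hstate, snapshot, hsm)
  hist <- push_snapshot(agent$hist, snapshot)
  probs <- selection_probabilities(hstate, hsm)
  h <- sample_heuristic(probs, u_select)
  hstate$current <- h
  hstate$forecasts <- forecast_all(hist, hstate$forecasts, hsm)
  ze <- hstate$forecasts[h]

  p <- unclass(as_incentives(payoff))
  A_H <- -.adv_low_inc(p[["deltaH0"]], p[["deltaL0"]],
                       p[["DeltaL1"]], p[["DeltaH1"]], ze, agent$perceived_n)
  PH <- choice_prob_high(agent$degree, sigma, A_H)
  strategy <- if (u_act < PH) 0L else 1L

  agent$hist <- hist
  agent$hstate <- hstate
  list(agent = agent, strategy = strategy, A_H = A_H,
       forecast = ze, heuristic = h)
}
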