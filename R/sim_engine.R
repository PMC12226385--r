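#' Simulation configuration
#'
#' Bundles every parameter of a run. Defaults are the study configuration:
#' 1000 agents on a preferential-attachment network with `lam = 250`,
#' homogeneous impact, 40000 steps (40 generations: one expected action per
#' agent per 1000 steps), environmental speed 0.25, sigmoid slope 0.1, and
#' the standard heuristics-switching coefficients. Initial conditions
#' (`n0 = 0.5`, `p_low0 = 0.5`) are symmetric; long-run outcomes are
#' insensitive to them.
#'
#' @param P number of agents (>= 2).
#' @param T number of global steps (>= 1); one agent acts per step.
#' @param lam attachment count of the network generator (ignored when a
#'   custom network is passed to [run_sim()]).
#' @param nu inequality-of-impact exponent (see [impact_weights()]).
#' @param epsilon relative speed of environmental dynamics.
#' @param sigma slope of the logistic choice rule.
#' @param hsm an [hsm_params()] object.
#' @param payoff a payoff parameter object (any parameterization).
#' @param n0 initial resource state (and every agent's initial perception).
#' @param p_low0 probability each agent starts on low effort.
#' @param seed integer seed; drives network generation and dynamics alike.
#' @param record_stride record `(t, n, z)` every this many steps.
#' @param tail_window length of the un-strided trailing buffer of `n` kept
#'   for outcome classification (the final `tail_window` steps).
#' @param ah_window trailing window (in steps) over which each agent's mean
#'   perceived advantage of high effort is accumulated.
#' @param diagnostics record every decision event (step, id, degree, A_H,
#'   forecast, heuristic, strategy)?
#' @return an object of class `cpr_config` (a list).
#' @export
sim_config <- function(P = 1000, T = 40000, lam = 250, nu = 0,
                       epsilon = 0.25, sigma = 0.1,
                       hsm = hsm_params(), payoff = default_payoffs(),
                       n0 = 0.5, p_low0 = 0.5, seed = 1L,
                       record_stride = 10L, tail_window = 100L,
                       ah_window = 10000L, diagnostics = FALSE) {
  cfg <- structure(list(P = as.integer(P), T = as.integer(T),
                        lam = as.integer(lam), nu = nu,
                        epsilon = epsilon, sigma = sigma,
                        hsm = hsm, payoff = payoff,
                        n0 = n0, p_low0 = p_low0, seed = as.integer(seed),
                        record_stride = as.integer(record_stride),
                        tail_window = as.integer(tail_window),
                        ah_window = as.integer(ah_window),
                        diagnostics = isTRUE(diagnostics)),
                   class = "cpr_config")
  validate_config(cfg)
}

#' @rdname sim_config
#' @param config a `cpr_config` to validate.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "cpr_config"))
  with(config, {
    if (P < 2L) stop("P must be >= 2", call. = FALSE)
    if (T < 1L) stop("T must be >= 1", call. = FALSE)
    if (lam < 1L || lam >= P) stop("need 1 <= lam < P", call. = FALSE)
    if (nu < 0) stop("nu must be >= 0", call. = FALSE)
    if (epsilon / P <= 0 || epsilon / P >= 1)
      stop("need 0 < epsilon/P < 1", call. = FALSE)
    if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
    if (n0 < 0 || n0 > 1) stop("n0 must be in [0, 1]", call. = FALSE)
    if (p_low0 < 0 || p_low0 > 1) stop("p_low0 must be in [0, 1]", call. = FALSE)
    if (record_stride < 1L) stop("record_stride must be >= 1", call. = FALSE)
    if (tail_window < 1L) stop("tail_window must be >= 1", call. = FALSE)
  })
  if (!inherits(config$hsm, "hsm_params"))
    config$hsm <- do.call(hsm_params, as.list(config$hsm))
  as_incentives(config$payoff)  # errors if not a payoff object
  config
}

#' @export
print.cpr_config <- function(x, ...) {
  inc <- unclass(as_incentives(x$payoff))
  cat(sprintf("cpr_config: P = %d, T = %d (%.1f generations), lam = %d, nu = %g\n",
              x$P, x$T, x$T / x$P, x$lam, x$nu))
  cat(sprintf("  epsilon = %g, sigma = %g, seed = %d\n", x$epsilon, x$sigma, x$seed))
  cat(sprintf("  incentives: deltaH0 = %g, deltaL0 = %g, DeltaL1 = %g, DeltaH1 = %g\n",
              inc[["deltaH0"]], inc[["deltaL0"]], inc[["DeltaL1"]], inc[["DeltaH1"]]))
  cat(sprintf("  hsm: beta1 = %g, beta2 = %g, beta3 = %g, rho = %g, eta = %g, phi = %g\n",
              x$hsm[["beta1"]], x$hsm[["beta2"]], x$hsm[["beta3"]],
              x$hsm[["rho"]], x$hsm[["eta"]], x$hsm[["phi"]]))
  invisible(x)
}

#' Initialize a simulation state
#'
#' Seeds the RNG from the config, generates (or adopts) the network, draws
#' initial strategies iid Bernoulli(`p_low0`) and initial heuristics
#' uniformly, and cold-starts every agent's snapshot history and forecasts
#' at its initial local observation with zero fitnesses. Graphs with
#' isolated nodes are rejected (such agents could never observe anyone).
#'
#' The RNG consumption order is fixed (network, then strategies, then
#' heuristics) so the compiled and reference engines continue from an
#' identical stream.
#'
#' @param config a [sim_config()].
#' @param network optional `cpr_network` to use instead of generating one.
#' @return list with `network`, `strategies`, `heuristics`, `weights`, `n`,
#'   `z`, `perceived` and per-agent `hist`/`hstate` builders used by the
#'   reference engine.
#' @export
init_state <- function(config, network = NULL) {
  config <- validate_config(config)
  set.seed(config$seed)
  if (is.null(network)) {
    network <- generate_ba(config$P, config$lam)
  } else {
    stopifnot(inherits(network, "cpr_network"))
    if (network$P != config$P)
      stop("network size does not match config P", call. = FALSE)
  }
  if (any(network$degrees == 0L))
    stop("network has isolated nodes: agents must have someone to observe",
         call. = FALSE)
  P <- config$P
  strategies <- as.integer(stats::runif(P) < config$p_low0)
  heuristics <- as.integer(floor(stats::runif(P) * 4)) + 1L
  weights <- impact_weights(network$degrees, config$nu)
  vis <- if (config$nu == 0) rep(1, P) else as.numeric(network$degrees)^config$nu
  obs0 <- vapply(seq_len(P), function(i)
    local_snapshot(strategies, network$neighbors[[i]], vis), numeric(1))
  list(network = network, strategies = strategies, heuristics = heuristics,
       weights = as.numeric(weights), vis = vis,
       n = config$n0, z = effective_extraction(strategies, weights),
       perceived = rep(config$n0, P), obs0 = obs0)
}

#' Run a full simulation
#'
#' Executes `T` scheduler steps. Each step: (1) one agent is drawn uniformly
#' at random; (2) it runs its decision pipeline ([decide()]); (3) the
#' effective extraction level is updated; (4) the resource state advances by
#' the law of motion; (5) all agents update their perception of the resource
#' from their local observations. Three uniform draws are consumed per step,
#' so a run is exactly reproducible from `(config, seed)` with either
#' engine; `engine = "reference"` is a pure-R implementation used for
#' cross-validation and is practical only for small problems.
#'
#' @param config a [sim_config()].
#' @param network optional custom `cpr_network` (e.g. [complete_network()]
#'   for a full-information control).
#' @param engine `"compiled"` (default) or `"reference"`.
#' @return an object of class `cpr_trajectory`: list with recorded vectors
#'   `t`, `n`, `z`, `cor_dz` (effort-degree correlation at record points),
#'   un-strided trailing buffers `tail_n`, `tail_z`, a per-agent `final`
#'   data.frame (id, degree, is_hub, strategy, heuristic, perceived_n,
#'   mean_AH over the trailing `ah_window`), optional `diagnostics`
#'   data.frame, the `config` echo and `seed`.
#' @examples
#' traj <- run_sim(sim_config(P = 50, T = 500, lam = 10, seed = 7))
#' range(traj$n)
#' @export
run_sim <- function(config, network = NULL,
                    engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  config <- validate_config(config)
  st <- init_state(config, network)
  inc <- unclass(as_incentives(config$payoff))
  h <- config$hsm

  if (engine == "compiled") {
    csr <- .as_csr(st$network)
    res <- run_engine_cpp(csr$offsets, csr$neigh, st$weights, st$vis,
                          st$strategies, st$heuristics,
                          config$n0, config$T, config$epsilon, config$sigma,
                          h[["beta1"]], h[["beta2"]], h[["beta3"]],
                          h[["rho"]], h[["eta"]], h[["phi"]],
                          inc[["deltaH0"]], inc[["deltaL0"]],
                          inc[["DeltaL1"]], inc[["DeltaH1"]],
                          config$record_stride, config$tail_window,
                          config$ah_window, config$diagnostics)
  } else {
    res <- .run_reference(config, st, inc, h)
  }

  diagnostics <- NULL
  if (config$diagnostics && !is.null(res$diagnostics)) {
    diagnostics <- as.data.frame(res$diagnostics)
    names(diagnostics) <- c("step", "id", "degree", "A_H", "forecast",
                            "heuristic", "strategy")
  }
  structure(list(
    t = res$t, n = res$n, z = res$z, cor_dz = res$cor_dz,
    tail_n = res$tail_n, tail_z = res$tail_z,
    final = data.frame(id = seq_len(config$P),
                       degree = st$network$degrees,
                       is_hub = st$network$is_hub,
                       strategy = res$strategy,
                       heuristic = res$heuristic,
                       perceived_n = res$perceived_n,
                       mean_AH = res$mean_AH),
    diagnostics = diagnostics,
    network = st$network, config = config, seed = config$seed),
    class = "cpr_trajectory")
}

#' @export
print.cpr_trajectory <- function(x, ...) {
  cat(sprintf("cpr_trajectory: %d steps, seed %d\n", x$config$T, x$seed))
  cat(sprintf("  final n = %.4f, z = %.4f; trailing mean n (last %d steps) = %.4f\n",
              x$n[length(x$n)], x$z[length(x$z)], length(x$tail_n),
              mean(x$tail_n)))
  cat(sprintf("  effort-degree correlation at end: %.3f\n",
              x$cor_dz[length(x$cor_dz)]))
  invisible(x)
}

# Pure-R engine mirroring run_engine_cpp operation-for-operation (including
# floating-point evaluation order), used as an independent cross-check.
.run_reference <- function(config, st, inc, h) {
  P <- config$P; T <- config$T
  eps_over_P <- config$epsilon / P
  net <- st$network
  deg <- net$degrees
  S <- st$strategies
  W <- st$weights
  vis <- st$vis
  lowW <- vapply(seq_len(P), function(i)
    sum(vis[net$neighbors[[i]]] * S[net$neighbors[[i]]]), numeric(1))
  denomW <- vapply(seq_len(P), function(i) sum(vis[net$neighbors[[i]]]),
                   numeric(1))
  perceived <- st$perceived
  agents <- lapply(seq_len(P), function(i) {
    list(degree = deg[i], perceived_n = perceived[i],
         hist = snapshot_history(st$obs0[i]),
         hstate = heuristic_state(forecasts = rep(st$obs0[i], 4),
                                  current = st$heuristics[i]))
  })
  payoff <- incentive_params(inc[["deltaH0"]], inc[["deltaL0"]],
                             inc[["DeltaL1"]], inc[["DeltaH1"]])

  mean_d <- mean(deg)
  sd_d <- sqrt(mean((deg - mean_d)^2))
  effort_cor <- function() {
    p <- mean(S == 0L)
    if (p <= 0 || p >= 1 || sd_d == 0) return(0)
    cov <- sum(deg[S == 0L]) / P - p * mean_d
    cov / (sqrt(p * (1 - p)) * sd_d)
  }

  z <- st$z; n <- st$n
  n_rec <- T %/% config$record_stride + 1L
  rec <- list(t = numeric(n_rec), n = numeric(n_rec), z = numeric(n_rec),
              cor = numeric(n_rec))
  ir <- 1L
  rec$t[ir] <- 0; rec$n[ir] <- n; rec$z[ir] <- z; rec$cor[ir] <- effort_cor()
  n_tail <- min(T, config$tail_window)
  tail_n <- numeric(n_tail); tail_z <- numeric(n_tail); it <- 0L
  sumAH <- numeric(P); cntAH <- integer(P)
  diag <- if (config$diagnostics) matrix(0, T, 7) else NULL

  for (t in seq_len(T)) {
    u1 <- stats::runif(1)
    a <- min(floor(u1 * P), P - 1) + 1L
    s <- min(max(lowW[a] / denomW[a], 0), 1)
    u2 <- stats::runif(1)
    u3 <- stats::runif(1)
    dec <- decide(agents[[a]], s, payoff, config$sigma, h,
                  u_select = u2, u_act = u3)
    agents[[a]] <- dec$agent
    newS <- dec$strategy
    if (newS != S[a]) {
      z <- z + (newS - S[a]) * W[a]
      nb <- net$neighbors[[a]]
      lowW[nb] <- lowW[nb] + (newS - S[a]) * vis[a]
      S[a] <- newS
    }
    n <- n + eps_over_P * (z - n)
    perceived <- perceived + eps_over_P * (pmin(pmax(lowW / denomW, 0), 1) - perceived)
    for (i in seq_len(P)) agents[[i]]$perceived_n <- perceived[i]

    if (t > T - config$ah_window) {
      sumAH[a] <- sumAH[a] + dec$A_H
      cntAH[a] <- cntAH[a] + 1L
    }
    if (config$diagnostics)
      diag[t, ] <- c(t, a, deg[a], dec$A_H, dec$forecast, dec$heuristic, newS)
    if (t %% config$record_stride == 0L) {
      ir <- ir + 1L
      rec$t[ir] <- t; rec$n[ir] <- n; rec$z[ir] <- z; rec$cor[ir] <- effort_cor()
    }
    if (t > T - n_tail) { it <- it + 1L; tail_n[it] <- n; tail_z[it] <- z }
  }

  list(t = rec$t, n = rec$n, z = rec$z, cor_dz = rec$cor,
       tail_n = tail_n, tail_z = tail_z,
       strategy = S,
       heuristic = vapply(agents, function(a) a$hstate$current, integer(1)),
       perceived_n = perceived,
       mean_AH = ifelse(cntAH > 0, sumAH / cntAH, NA_real_),
       diagnostics = diag)
}
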