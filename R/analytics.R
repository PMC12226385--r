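#' Classify a run's long-run outcome against the full-information equilibrium
#'
#' A run is `"scarce"` when its mean resource state over the trailing window
#' lies strictly below the equilibrium `n*`, `"abundant"` otherwise (exact
#' ties count as abundant by convention).
#'
#' @param traj a `cpr_trajectory` (or a numeric vector of trailing `n`
#'   values).
#' @param fie a [solve_fie()] result for the run's payoff configuration.
#' @param window number of trailing steps averaged (capped at the stored
#'   trailing buffer; default 100).
#' @return `"abundant"` or `"scarce"`.
#' @export
classify_outcome <- function(traj, fie, window = 100L) {
  if (!fie$exists) stop("no full-information equilibrium to compare against",
                        call. = FALSE)
  tail_n <- if (inherits(traj, "cpr_trajectory")) traj$tail_n else traj
  stopifnot(length(tail_n) >= 1L)
  window <- min(window, length(tail_n))
  m <- mean(tail_n[seq(length(tail_n) - window + 1L, length(tail_n))])
  if (m < fie$n_star) "scarce" else "abundant"
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations whose seeds are `base_seed + 0 .. n_runs - 1`;
#' each seed drives both the network realization and the dynamics. Per-run
#' trailing means, outcome classes, final effort-degree correlations and
#' network skewness are tabulated.
#'
#' @param config a [sim_config()]; its `seed` is the default `base_seed`.
#' @param n_runs number of runs.
#' @param base_seed first seed.
#' @param network optional fixed custom network shared by all runs (seeds
#'   then only affect the dynamics).
#' @param window classification window, see [classify_outcome()].
#' @return data.frame with one row per run: `run`, `seed`, `mean_n_tail`,
#'   `class`, `effort_degree_cor`, `skewness`; the [solve_fie()] result is
#'   attached as attribute `"fie"`.
#' @export
run_ensemble <- function(config, n_runs = 100L, base_seed = config$seed,
                         network = NULL, window = 100L) {
  fie <- solve_fie(config$payoff)
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1L)
    traj <- run_sim(cfg, network = network)
    rows[[i]] <- data.frame(
      run = i, seed = cfg$seed,
      mean_n_tail = mean(traj$tail_n[seq(max(1L, length(traj$tail_n) - window + 1L),
                                         length(traj$tail_n))]),
      class = classify_outcome(traj, fie, window),
      effort_degree_cor = traj$cor_dz[length(traj$cor_dz)],
      skewness = degree_skewness(traj$network))
  }
  out <- do.call(rbind, rows)
  attr(out, "fie") <- fie
  out
}

#' Fraction of runs below the full-information equilibrium
#'
#' @param runs a [run_ensemble()] table or a character vector of classes.
#' @return fraction of runs classified `"scarce"`, in `[0, 1]`.
#' @export
ensemble_split <- function(runs) {
  cls <- if (is.data.frame(runs)) runs$class else runs
  stopifnot(length(cls) >= 1L, all(cls %in% c("abundant", "scarce")))
  mean(cls == "scarce")
}

#' Sweep the skewness of the degree distribution
#'
#' Re-runs the ensemble across attachment counts `lam`; higher `lam` yields
#' a more skewed degree distribution and a wider split between the abundant
#' and scarce branches, with bistability vanishing for mild skew.
#'
#' @param config base [sim_config()].
#' @param lam_grid attachment counts to sweep.
#' @param runs_per_level ensemble size per level.
#' @param window classification window.
#' @return data.frame keyed by (`lam`, `seed`) with per-run `skewness`,
#'   `mean_n_tail` and `class`.
#' @export
sweep_skewness <- function(config,
                           lam_grid = seq(50L, 950L, by = 100L),
                           runs_per_level = 30L, window = 100L) {
  out <- lapply(lam_grid, function(lam) {
    cfg <- config
    cfg$lam <- as.integer(lam)
    cfg <- validate_config(cfg)
    runs <- run_ensemble(cfg, n_runs = runs_per_level, window = window)
    cbind(lam = lam, runs[, c("seed", "skewness", "mean_n_tail", "class")])
  })
  do.call(rbind, out)
}

#' Sweep the inequality of environmental impact
#'
#' Re-runs the ensemble across impact exponents `nu`. As `nu` grows, hub
#' agents dominate the effective extraction level, perceptions align with
#' realized extraction, and the two branches collapse onto the
#' full-information equilibrium.
#'
#' @inheritParams sweep_skewness
#' @param nu_grid impact exponents to sweep.
#' @return data.frame keyed by (`nu`, `seed`) with per-run `mean_n_tail` and
#'   `class`.
#' @export
sweep_impact <- function(config, nu_grid = seq(0, 3, by = 0.25),
                         runs_per_level = 30L, window = 100L) {
  out <- lapply(nu_grid, function(nu) {
    cfg <- config
    cfg$nu <- nu
    runs <- run_ensemble(cfg, n_runs = runs_per_level, window = window)
    cbind(nu = nu, runs[, c("seed", "mean_n_tail", "class")])
  })
  do.call(rbind, out)
}

#' Bin decision events by perceived advantage
#'
#' Summarizes per-event diagnostics (from a run with `diagnostics = TRUE`)
#' into bins of the perceived advantage of high effort, reporting the mean
#' degree of the deciding agents and the relative frequency per bin — the
#' degree-sorting picture: within a branch, hubs congregate on one side of
#' zero advantage and leaves on the other.
#'
#' @param diag diagnostics data.frame with columns `step`, `degree`, `A_H`.
#' @param last_k use only events from the final `last_k` steps.
#' @param breaks number of advantage bins (or a vector of cut points).
#' @return data.frame with `bin` (interval label), `A_H_mid`, `mean_degree`,
#'   `count`, `frequency`.
#' @export
degree_advantage_table <- function(diag, last_k = 10000L, breaks = 20L) {
  stopifnot(is.data.frame(diag), all(c("step", "degree", "A_H") %in% names(diag)))
  d <- diag[diag$step > max(diag$step) - last_k, , drop = FALSE]
  if (length(breaks) == 1L && diff(range(d$A_H)) == 0) {
    return(data.frame(bin = sprintf("[%g]", d$A_H[1]), A_H_mid = d$A_H[1],
                      mean_degree = mean(d$degree), count = nrow(d),
                      frequency = 1))
  }
  cuts <- cut(d$A_H, breaks = breaks, include.lowest = TRUE)
  mids <- tapply(d$A_H, cuts, mean)
  degs <- tapply(d$degree, cuts, mean)
  cnts <- tapply(d$A_H, cuts, length)
  keep <- !is.na(cnts) & cnts > 0
  data.frame(bin = names(mids)[keep], A_H_mid = as.numeric(mids[keep]),
             mean_degree = as.numeric(degs[keep]),
             count = as.integer(cnts[keep]),
             frequency = as.integer(cnts[keep]) / nrow(d),
             row.names = NULL)
}

#' Correlation between extraction effort and degree
#'
#' Pearson correlation between the high-effort indicator (`1 - S`) and
#' degree. Positive when hubs extract with high effort (the abundant
#' branch), negative on the scarce branch. Returns 0 by convention when the
#' strategy vector (or the degree sequence) is constant.
#'
#' @param strategies integer strategies (1 low, 0 high).
#' @param degrees node degrees.
#' @return correlation in `[-1, 1]`.
#' @export
effort_degree_correlation <- function(strategies, degrees) {
  stopifnot(length(strategies) == length(degrees), length(strategies) >= 2L)
  high <- 1 - strategies
  if (stats::sd(high) == 0 || stats::sd(degrees) == 0) return(0)
  stats::cor(high, degrees)
}

#' Majority illusion index
#'
#' Fraction of agents whose local (neighbourhood) majority strategy differs
#' from the population majority. Neighbourhood ties are resolved toward the
#' population majority (conservative: a tie is not an illusion); a
#' population tie counts low effort as the majority.
#'
#' @param net a `cpr_network` without isolated nodes.
#' @param strategies integer strategies (1 low, 0 high).
#' @return fraction in `[0, 1]`.
#' @examples
#' # star: hub on high effort, 9 leaves on low -> every leaf is illusioned
#' net <- network_from_edges(cbind(1, 2:10))
#' majority_illusion_index(net, c(0L, rep(1L, 9)))  # 0.9
#' @export
majority_illusion_index <- function(net, strategies) {
  stopifnot(inherits(net, "cpr_network"),
            length(strategies) == net$P, all(net$degrees >= 1L))
  glob_frac <- mean(strategies)
  glob_low <- glob_frac >= 0.5
  illus <- vapply(seq_len(net$P), function(i) {
    f <- mean(strategies[net$neighbors[[i]]])
    local_low <- if (f == 0.5) glob_low else f > 0.5
    local_low != glob_low
  }, logical(1))
  mean(illus)
}

#' Replicator dynamics with environmental feedback
#'
#' The analytically tractable full-information, well-mixed companion of the
#' agent-based model: the low-effort share follows replicator dynamics
#' driven by the payoff advantage while the resource relaxes toward it,
#' `dz/dt = z (1 - z) (piL - piH)`, `dn/dt = epsilon * alpha * (z - n)`.
#' `alpha = 1/P` matches the per-step gap closure of the discrete law of
#' motion. The interior fixed point is the full-information equilibrium.
#'
#' @param z,n state in `[0, 1]`.
#' @param params a payoff parameter object.
#' @param epsilon environmental speed.
#' @param alpha continuous-time rate scale (use `1/P` to compare against the
#'   agent-based model).
#' @return `replicator_field()`: list with `zdot`, `ndot`.
#' @export
replicator_field <- function(z, n, params, epsilon = 0.25, alpha = 1e-3) {
  .check_zn(z, n)
  list(zdot = z * (1 - z) * advantage_low(params, z, n),
       ndot = epsilon * alpha * (z - n))
}

#' @rdname replicator_field
#' @param z0,n0 initial state.
#' @param horizon integration horizon (in continuous time units; one unit
#'   corresponds to one scheduler step when `alpha = 1/P`).
#' @param dt fixed step of the 4th-order Runge-Kutta integrator.
#' @return `integrate_replicator()`: data.frame with columns `time`, `z`,
#'   `n`.
#' @export
integrate_replicator <- function(z0, n0, params, epsilon = 0.25,
                                 alpha = 1e-3, horizon = 40000, dt = 1) {
  .check_zn(z0, n0)
  rhs <- function(t, y, parms) {
    f <- replicator_field(min(max(y[1], 0), 1), min(max(y[2], 0), 1),
                          params, epsilon, alpha)
    list(c(f$zdot, f$ndot))
  }
  out <- deSolve::ode(y = c(z = z0, n = n0), times = seq(0, horizon, by = dt),
                      func = rhs, parms = NULL, method = "rk4")
  data.frame(time = out[, 1], z = out[, 2], n = out[, 3])
}
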