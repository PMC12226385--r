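#' Effective population extraction level
#'
#' Impact-weighted fraction of agents on the low-effort strategy,
#' `z = sum_i S_i W_i`. With homogeneous impact (`nu = 0`) this is exactly
#' the unweighted low-effort fraction; with `nu > 0` the strategies of
#' high-degree agents dominate the effective level.
#'
#' @param strategies integer vector, 1 = low effort, 0 = high effort.
#' @param weights impact weights summing to 1 (see [impact_weights()]).
#' @return effective low-effort fraction in `[0, 1]`.
#' @export
effective_extraction <- function(strategies, weights) {
  if (length(strategies) != length(weights))
    stop("strategies and weights differ in length", call. = FALSE)
  stopifnot(all(strategies %in% c(0L, 1L)))
  sum(strategies * as.numeric(weights))
}

#' Resource law of motion
#'
#' Each period the resource closes a share `epsilon / P` of the gap between
#' its state and the effective low-effort level:
#' `n <- n + (epsilon/P) * (z - n)`. The fixed point is `n = z`; the update
#' is a convex combination, so `n` never leaves `[0, 1]`. `epsilon` sets the
#' relative speed of environmental and strategic dynamics (with one agent
#' acting per step, `epsilon` is the per-generation rate).
#'
#' @param n current resource state in `[0, 1]`.
#' @param z effective low-effort fraction in `[0, 1]`.
#' @param epsilon environmental speed parameter.
#' @param P population size.
#' @return updated resource state.
#' @examples
#' step_environment(0, 1, epsilon = 0.25, P = 1000)  # 2.5e-4
#' @export
step_environment <- function(n, z, epsilon, P) {
  stopifnot(all(n >= 0), all(n <= 1), all(z >= 0), all(z <= 1),
            epsilon / P > 0, epsilon / P < 1)
  n + (epsilon / P) * (z - n)
}
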