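# Independent oracles and small fixtures shared across the suite.

# closed-form geometric relaxation of the resource law of motion
geometric_oracle <- function(n0, z, epsilon, P, k) {
  z + (n0 - z) * (1 - epsilon / P)^k
}

# discounted sum of negated squared errors, the closed form of the fitness
# recursion f <- -(e^2) + eta * f starting from 0
discounted_fitness_oracle <- function(errors, eta) {
  k <- length(errors)
  sum(eta^(k - seq_len(k)) * (-errors^2))
}

# brute-force Fisher-Pearson skewness from raw moment definitions
skewness_oracle <- function(x) {
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  m3 <- sum((x - m)^3) / length(x)
  m3 / m2^1.5
}

# bisection root of advantage_low(n, n) on [0, 1] (assumes one sign change)
fie_bisection_oracle <- function(params, tol = 1e-12) {
  g <- function(n) advantage_low(params, n, n)
  if (sign(g(0)) == sign(g(1))) return(NA_real_)
  stats::uniroot(g, c(0, 1), tol = tol)$root
}

# star graph: node 1 is the centre, nodes 2..(k+1) are leaves
star_network <- function(k) {
  network_from_edges(cbind(1L, seq_len(k) + 1L))
}

# ring lattice: every node linked to its two neighbours (regular graph)
ring_network <- function(P) {
  network_from_edges(cbind(seq_len(P), c(seq_len(P - 1) + 1L, 1L)))
}

small_config <- function(seed = 11, ...) {
  sim_config(P = 30, T = 600, lam = 6, seed = seed, record_stride = 1,
             tail_window = 50, ...)
}

random_corners <- function() {
  do.call(corner_payoffs, as.list(stats::rnorm(8)))
}
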