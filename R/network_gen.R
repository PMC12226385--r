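#' Information networks for the extraction game
#'
#' A `cpr_network` is an undirected simple graph on `P` nodes carrying the
#' visibility structure: agents observe exactly their neighbours. Networks are
#' either generated by [generate_ba()] or supplied as an edge list via
#' [network_from_edges()] / [read_edgelist()].
#'
#' @param edges two-column integer matrix of 1-based node ids, one row per
#'   undirected edge.
#' @param P number of nodes; defaults to the largest id in `edges`.
#' @param lam attachment count used in generation (`NA` for custom graphs).
#' @param initial_nodes ids of the seed nodes present before attachment began.
#' @param seed generator seed recorded for provenance (not used here).
#' @return an object of class `cpr_network`: a list with `P`, `lam`, `edges`,
#'   `neighbors` (sorted adjacency lists), `degrees`, `is_hub`,
#'   `initial_nodes`, `seed`.
#' @export
network_from_edges <- function(edges, P = NULL, lam = NA_integer_,
                               initial_nodes = integer(0), seed = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (is.null(P)) P <- max(edges)
  P <- as.integer(P)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > P)) stop("edge ids out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("parallel edges are not allowed")
  }
  fac <- factor(c(edges[, 1L], edges[, 2L]), levels = seq_len(P))
  neighbors <- unname(lapply(split(c(edges[, 2L], edges[, 1L]), fac), sort))
  degrees <- lengths(neighbors)
  hubs <- if (!is.na(lam)) seq_len(P) > lam else rep(FALSE, P)
  structure(list(P = P, lam = lam, edges = edges, neighbors = neighbors,
                 degrees = degrees, is_hub = hubs,
                 initial_nodes = initial_nodes, seed = seed),
            class = "cpr_network")
}

#' Preferential-attachment network with controllable degree skewness
#'
#' Generates the skew-degree information network: `lam` initially isolated
#' seed nodes, then `P - lam` nodes added sequentially, each attaching to
#' `lam` distinct existing nodes chosen proportionally to current degree.
#' The first added node necessarily connects to all `lam` seed nodes (they
#' carry no degree yet); later attachments are successive degree-proportional
#' draws without replacement, realized via exponential-key weighted sampling.
#' The added nodes (`id > lam`) are the hubs. Large `lam` (e.g. 950 of 1000)
#' produces an extremely skewed degree distribution: 50 hubs of degree at
#' least 950 and 950 peripheral nodes of degree about 48-50.
#'
#' @param P number of nodes at termination (>= 2).
#' @param lam number of existing nodes each new node connects to
#'   (`1 <= lam < P`). Small `lam` relative to `P` gives mild skew, `lam`
#'   close to `P` extreme skew.
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#'   Leave `NULL` to draw from the current RNG stream (as [run_sim()] does).
#' @return a `cpr_network` with edge count exactly `lam * (P - lam)`.
#' @examples
#' net <- generate_ba(100, 25, seed = 1)
#' sum(net$degrees) == 2 * 25 * 75
#' @export
generate_ba <- function(P, lam, seed = NULL) {
  P <- as.integer(P); lam <- as.integer(lam)
  if (is.na(P) || is.na(lam) || P < 2L || lam < 1L || lam >= P)
    stop("need integers with 1 <= lam < P", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_add <- P - lam
  e_from <- integer(lam * n_add)
  e_to <- integer(lam * n_add)
  deg <- integer(P)

  # first added node: all candidates have degree zero, attachment is forced
  first <- lam + 1L
  e_from[seq_len(lam)] <- first
  e_to[seq_len(lam)] <- seq_len(lam)
  deg[seq_len(lam)] <- 1L
  deg[first] <- lam
  pos <- lam

  for (v in seq_len(n_add - 1L) + first) {
    m <- v - 1L
    # successive degree-proportional sampling without replacement
    keys <- runif(m)^(1 / deg[seq_len(m)])
    targets <- order(keys, decreasing = TRUE)[seq_len(lam)]
    e_from[pos + seq_len(lam)] <- v
    e_to[pos + seq_len(lam)] <- targets
    pos <- pos + lam
    deg[targets] <- deg[targets] + 1L
    deg[v] <- lam
  }

  network_from_edges(cbind(e_from, e_to), P = P, lam = lam,
                     initial_nodes = seq_len(lam), seed = seed)
}

#' Complete graph on P nodes
#'
#' Full-visibility control network: every agent observes every other, so no
#' majority illusion can arise.
#'
#' @param P number of nodes (>= 2).
#' @return a `cpr_network`.
#' @export
complete_network <- function(P) {
  P <- as.integer(P)
  stopifnot(P >= 2L)
  idx <- utils::combn(P, 2L)
  network_from_edges(t(idx), P = P)
}

#' @export
print.cpr_network <- function(x, ...) {
  cat(sprintf("cpr_network: %d nodes, %d edges%s\n", x$P, nrow(x$edges),
              if (!is.na(x$lam)) sprintf(" (preferential attachment, lam = %d)", x$lam)
              else " (custom)"))
  cat(sprintf("  degree range [%d, %d], skewness %.3f, hubs: %d\n",
              min(x$degrees), max(x$degrees), degree_skewness(x), sum(x$is_hub)))
  invisible(x)
}

# 0-based CSR view consumed by the compiled engine
.as_csr <- function(net) {
  list(offsets = c(0L, cumsum(net$degrees)),
       neigh = as.integer(unlist(net$neighbors, use.names = FALSE)) - 1L)
}

#' Fisher-Pearson skewness of the degree distribution
#'
#' The sample skewness `g1 = m3 / m2^(3/2)` (third central moment over the
#' 3/2 power of the variance) of the degree sequence; `0` by convention for
#' regular graphs (zero variance).
#'
#' @param x a `cpr_network` or a numeric degree vector (length >= 3).
#' @return numeric scalar.
#' @export
degree_skewness <- function(x) {
  d <- if (inherits(x, "cpr_network")) x$degrees else x
  stopifnot(is.numeric(d), length(d) >= 3L)
  d <- as.numeric(d)
  m <- mean(d)
  m2 <- mean((d - m)^2)
  if (m2 == 0) return(0)
  mean((d - m)^3) / m2^1.5
}

#' Environmental impact weights
#'
#' Weight of each agent in the effective extraction level:
#' `W_i = d_i^nu / sum_j d_j^nu`. With `nu = 0` impact is homogeneous
#' (`1/P` each, taking `0^0 = 1`); with `nu > 0` highly connected agents
#' have disproportionate environmental impact.
#'
#' @param degrees nonnegative integer degrees (or a `cpr_network`).
#' @param nu inequality-of-impact exponent, `>= 0`.
#' @return numeric vector of weights summing to 1, with attribute `nu`.
#' @examples
#' impact_weights(c(1, 3), nu = 1)  # 0.25 0.75
#' @export
impact_weights <- function(degrees, nu) {
  if (inherits(degrees, "cpr_network")) degrees <- degrees$degrees
  stopifnot(is.numeric(degrees), length(degrees) >= 1L,
            all(is.finite(degrees)), all(degrees >= 0),
            is.numeric(nu), length(nu) == 1L, is.finite(nu), nu >= 0)
  w <- if (nu == 0) rep(1, length(degrees)) else as.numeric(degrees)^nu
  s <- sum(w)
  if (s == 0) stop("all degrees zero with nu > 0: weights undefined", call. = FALSE)
  structure(w / s, nu = nu)
}

#' Node attribute table
#'
#' @param net a `cpr_network`.
#' @param nu impact exponent for the `weight` column.
#' @return data.frame with columns `id`, `degree`, `is_hub`, `weight`.
#' @export
node_table <- function(net, nu = 0) {
  stopifnot(inherits(net, "cpr_network"))
  data.frame(id = seq_len(net$P), degree = net$degrees, is_hub = net$is_hub,
             weight = as.numeric(impact_weights(net$degrees, nu)))
}

#' Edge list I/O
#'
#' Edge lists are written as two whitespace-separated columns of 0-based
#' integer node ids, one undirected edge per line.
#'
#' @param net a `cpr_network`.
#' @param path file path.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   returns a `cpr_network`.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "cpr_network"))
  utils::write.table(net$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_edgelist
#' @param P node count; defaults to max id + 1.
#' @export
read_edgelist <- function(path, P = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "integer"))
  network_from_edges(m + 1L, P = if (is.null(P)) max(m) + 1L else P)
}
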