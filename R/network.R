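#' Static social network
#'
#' Lightweight container for an undirected simple graph: `n_nodes` individuals
#' with integer ids `1..n_nodes`, an edge matrix, and an optional per-node
#' attribute `theta` in \[0,1\] (present for networks grown by the fitness
#' model, where it encodes the trait driving homophily).
#'
#' @param n_nodes number of nodes (>= 1).
#' @param edges two-column integer matrix of node ids in `1..n_nodes`; each
#'   row is one undirected social tie. Self-loops and duplicate ties are
#'   rejected.
#' @param theta optional numeric vector of length `n_nodes` with values in
#'   \[0,1\].
#' @return An object of class `static_network`: a list with elements
#'   `n_nodes`, `edges` (canonicalised so the smaller id is first) and
#'   `theta` (or `NULL`).
#' @examples
#' net <- static_network(3, rbind(c(1, 2), c(2, 3)))
#' net$n_nodes
#' @export
static_network <- function(n_nodes, edges, theta = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1)
    stop("n_nodes must be a positive integer")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints must be node ids in 1..n_nodes")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    key <- (edges[, 1] - 1) * as.double(n_nodes) + edges[, 2]
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed")
  }
  if (!is.null(theta)) {
    theta <- as.numeric(theta)
    if (length(theta) != n_nodes || anyNA(theta) ||
        any(theta < 0) || any(theta > 1))
      stop("theta must be a length-n_nodes numeric vector in [0,1]")
  }
  structure(list(n_nodes = n_nodes, edges = edges, theta = theta),
            class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  cat(sprintf("static_network: %d nodes, %d edges, mean degree %.4g%s\n",
              x$n_nodes, nrow(x$edges), 2 * nrow(x$edges) / x$n_nodes,
              if (is.null(x$theta)) "" else ", with node attribute theta"))
  invisible(x)
}

#' Convert a static network to an igraph object
#'
#' @param network a [static_network()].
#' @return An undirected `igraph` graph with the same node ids; `theta` is
#'   attached as a vertex attribute when present.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "static_network"))
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (nrow(network$edges) > 0)
    g <- igraph::add_edges(g, t(network$edges))
  if (!is.null(network$theta))
    igraph::V(g)$theta <- network$theta
  g
}

#' Erdos-Renyi random network
#'
#' Every unordered node pair is linked independently with probability
#' `p = mean_degree / (n_nodes - 1)`, the homogeneous reference substrate.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_degree target average degree, in `[0, n_nodes - 1]`.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @return A [static_network()].
#' @examples
#' net <- generate_er(100, 10, seed = 1)
#' @export
generate_er <- function(n_nodes, mean_degree, seed) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  if (mean_degree < 0 || mean_degree > n_nodes - 1)
    stop("mean_degree must lie in [0, n_nodes - 1]")
  p <- mean_degree / (n_nodes - 1)
  set.seed(seed)
  g <- igraph::sample_gnp(n_nodes, p, directed = FALSE, loops = FALSE)
  static_network(n_nodes, igraph::as_edgelist(g, names = FALSE))
}

#' Watts-Strogatz small-world network
#'
#' Ring lattice in which every node is linked to its `k_nn` nearest
#' neighbours (`k_nn / 2` on each side), then each lattice edge is rewired
#' with probability `rewire_prob` by redrawing its far endpoint uniformly at
#' random (avoiding self-loops and duplicate ties).
#'
#' @param n_nodes number of nodes.
#' @param k_nn even number of nearest neighbours (`k_nn < n_nodes`).
#' @param rewire_prob per-edge rewiring probability `q` in \[0,1\].
#' @param seed integer RNG seed.
#' @return A [static_network()].
#' @examples
#' net <- generate_ws(100, 6, 0.33, seed = 1)
#' @export
generate_ws <- function(n_nodes, k_nn = 6, rewire_prob = 0, seed) {
  if (k_nn %% 2 != 0) stop("k_nn must be even")
  if (k_nn >= n_nodes) stop("k_nn must be smaller than n_nodes")
  if (rewire_prob < 0 || rewire_prob > 1)
    stop("rewire_prob must lie in [0,1]")
  set.seed(seed)
  half <- k_nn / 2
  u <- rep(seq_len(n_nodes), each = half)
  v <- ((u - 1 + rep(seq_len(half), times = n_nodes)) %% n_nodes) + 1
  edges <- cbind(pmin(u, v), pmax(u, v))
  keys <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), ":", max(a, b))
  for (i in seq_len(nrow(edges)))
    assign(ekey(edges[i, 1], edges[i, 2]), TRUE, envir = keys)
  do_rewire <- runif(nrow(edges)) < rewire_prob
  for (i in which(do_rewire)) {
    a <- u[i]
    attempts <- 0
    repeat {
      w <- sample.int(n_nodes, 1)
      attempts <- attempts + 1
      if (w != a && !exists(ekey(a, w), envir = keys, inherits = FALSE))
        break
      if (attempts > 1000) { w <- NA; break }  # node saturated; keep edge
    }
    if (is.na(w)) next
    rm(list = ekey(edges[i, 1], edges[i, 2]), envir = keys)
    assign(ekey(a, w), TRUE, envir = keys)
    edges[i, ] <- c(min(a, w), max(a, w))
  }
  static_network(n_nodes, edges)
}

#' Attribute-fitness preferential-attachment network
#'
#' Growing network in which each new node `J`, carrying a trait
#' `theta_J ~ Uniform(0,1)`, attaches to `m` distinct existing nodes chosen
#' without replacement with probability proportional to the fitness
#' `k_i * exp(-beta * |theta_J - theta_i|)`: degree-driven attachment damped
#' by attribute dissimilarity. `beta = 0` recovers pure preferential
#' attachment (a Barabasi-Albert network with a `k^-3` degree tail); larger
#' `beta` shifts attachment towards similar nodes, raising clustering and
#' modularity. Growth starts from a complete graph on the first `m` nodes.
#'
#' @param n_nodes final number of nodes (`> m`).
#' @param m links added per new node (>= 1).
#' @param beta non-negative homophily strength.
#' @param seed integer RNG seed.
#' @return A [static_network()] with the `theta` attribute set.
#' @examples
#' net <- generate_fitness(200, 3, beta = 100, seed = 1)
#' @export
generate_fitness <- function(n_nodes, m = 3, beta = 0, seed) {
  if (m < 1) stop("m must be at least 1")
  if (n_nodes <= m) stop("n_nodes must exceed m")
  if (beta < 0) stop("beta must be non-negative")
  set.seed(seed)
  theta <- runif(n_nodes)
  n_edges <- m * (m - 1) / 2 + m * (n_nodes - m)
  edges <- matrix(0L, nrow = n_edges, ncol = 2)
  pos <- 0L
  if (m > 1) {
    seed_edges <- t(utils::combn(m, 2))
    edges[seq_len(nrow(seed_edges)), ] <- seed_edges
    pos <- nrow(seed_edges)
  }
  deg <- numeric(n_nodes)
  deg[seq_len(m)] <- m - 1
  for (J in (m + 1):n_nodes) {
    existing <- seq_len(J - 1)
    w <- deg[existing] * exp(-beta * abs(theta[J] - theta[existing]))
    if (sum(w) <= 0) w <- rep(1, length(existing))  # only possible when m = 1
    targets <- sample(existing, m, replace = FALSE, prob = w)
    edges[pos + seq_len(m), ] <- cbind(targets, J)
    pos <- pos + m
    deg[targets] <- deg[targets] + 1
    deg[J] <- m
  }
  static_network(n_nodes, edges, theta = theta)
}

#' Degree-preserving configuration rewiring
#'
#' Randomises a network towards the configuration-model null while keeping
#' every node's degree fixed: two edges `(a,b)` and `(c,d)` are repeatedly
#' chosen at random (with random orientation) and their endpoints swapped to
#' `(a,d)` and `(c,b)`. A proposal that would create a self-loop or a
#' duplicate tie is rejected and redrawn. The default of `10 * |E|` accepted
#' swaps is a standard mixing heuristic.
#'
#' @param network a [static_network()] with at least 2 edges.
#' @param n_swaps number of accepted swaps to perform.
#' @param seed integer RNG seed.
#' @param max_attempts cap on total proposals; if reached before `n_swaps`
#'   acceptances (e.g. on rigid graphs such as a triangle, where every
#'   proposal is rejected) the partial result is returned with a warning.
#' @return A [static_network()] with the same degree sequence; the number of
#'   accepted swaps is attached as attribute `"accepted_swaps"`. The `theta`
#'   attribute, if any, is carried over unchanged.
#' @examples
#' net <- generate_fitness(200, 3, beta = 100, seed = 1)
#' null <- rewire_to_configuration(net, seed = 2)
#' @export
rewire_to_configuration <- function(network, n_swaps = 10 * nrow(network$edges),
                                    seed, max_attempts = 100 * n_swaps) {
  stopifnot(inherits(network, "static_network"))
  edges <- network$edges
  E <- nrow(edges)
  if (E < 2) stop("network must have at least 2 edges to rewire")
  set.seed(seed)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), ":", max(a, b))
  for (i in seq_len(E)) assign(ekey(edges[i, 1], edges[i, 2]), TRUE, envir = keys)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(E, 2)
    e1 <- edges[pick[1], ]
    e2 <- edges[pick[2], ]
    if (runif(1) < 0.5) e1 <- rev(e1)
    if (runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1]; b <- e1[2]; cc <- e2[1]; dd <- e2[2]
    # proposed: (a,dd) and (cc,b)
    if (a == dd || cc == b) next
    if (exists(ekey(a, dd), envir = keys, inherits = FALSE)) next
    if (exists(ekey(cc, b), envir = keys, inherits = FALSE)) next
    rm(list = c(ekey(a, b), ekey(cc, dd)), envir = keys)
    assign(ekey(a, dd), TRUE, envir = keys)
    assign(ekey(cc, b), TRUE, envir = keys)
    edges[pick[1], ] <- c(min(a, dd), max(a, dd))
    edges[pick[2], ] <- c(min(cc, b), max(cc, b))
    accepted <- accepted + 1L
  }
  if (accepted < n_swaps)
    warning(sprintf("only %d of %d swaps accepted within %d proposals",
                    accepted, n_swaps, attempts))
  out <- static_network(network$n_nodes, edges, theta = network$theta)
  attr(out, "accepted_swaps") <- accepted
  out
}
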