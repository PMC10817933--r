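# small graphs built in code

triangle_net <- function() static_network(3, rbind(c(1, 2), c(2, 3), c(1, 3)))

star_net <- function(n_leaves = 10) {
  static_network(n_leaves + 1, cbind(1, 2:(n_leaves + 1)))
}

two_cliques_net <- function(k = 5) {
  e1 <- t(utils::combn(k, 2))
  e2 <- t(utils::combn(k, 2)) + k
  static_network(2 * k, rbind(e1, e2))
}

path_net <- function(n) static_network(n, cbind(1:(n - 1), 2:n))

# independent oracle: connected components of the "pairs closer than eps"
# graph (single-linkage threshold clustering), by union-find over all pairs
brute_force_clusters <- function(x, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(x[i] - x[j]) < eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# reference pure degree-preferential-attachment generator following the
# same growth procedure and RNG stream layout as generate_fitness
reference_ba <- function(n_nodes, m, seed) {
  set.seed(seed)
  theta <- runif(n_nodes)  # drawn but unused: keeps the stream aligned
  edges <- t(utils::combn(m, 2))
  deg <- numeric(n_nodes)
  deg[seq_len(m)] <- m - 1
  for (J in (m + 1):n_nodes) {
    existing <- seq_len(J - 1)
    targets <- sample(existing, m, replace = FALSE, prob = deg[existing])
    edges <- rbind(edges, cbind(targets, J))
    deg[targets] <- deg[targets] + 1
    deg[J] <- m
  }
  static_network(n_nodes, edges, theta = theta)
}

degree_sequence <- function(net) {
  sort(tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = net$n_nodes))
}

edge_key_set <- function(net) {
  sort(paste0(net$edges[, 1], ":", net$edges[, 2]))
}
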