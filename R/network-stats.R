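#' Structural statistics of a social network
#'
#' Computes the summary statistics used to characterise the social
#' substrates: mean degree (exactly `2|E|/N`), mean local clustering
#' coefficient (`cc_i = 2 e_i / (k_i (k_i - 1))`, with `cc_i = 0` when
#' `k_i < 2`), mean shortest-path betweenness (normalised by
#' `(N-1)(N-2)/2`, endpoints excluded), modularity `Q` of the partition
#' found by a modularity-maximisation method, degree assortativity `r`
#' (Pearson correlation of degrees over edge endpoints, both orientations),
#' and the degree distribution.
#'
#' @param network a non-empty [static_network()].
#' @param community_method modularity-maximisation method used for `Q`:
#'   `"louvain"` (default) or `"fast_greedy"`.
#' @param membership optional integer vector of community labels; when given
#'   it overrides community detection and `Q` is evaluated on this partition.
#' @param betweenness if `FALSE`, skip the (comparatively expensive)
#'   betweenness computation and report `NA`.
#' @return An object of class `network_stats`: list with `mean_degree`,
#'   `mean_clustering`, `mean_betweenness`, `modularity`, `assortativity`
#'   (`NA` when undefined, e.g. for regular graphs), `degree_distribution`
#'   (named count vector) and `membership`.
#' @examples
#' net <- generate_er(200, 10, seed = 1)
#' compute_stats(net)
#' @export
compute_stats <- function(network,
                          community_method = c("louvain", "fast_greedy"),
                          membership = NULL, betweenness = TRUE) {
  stopifnot(inherits(network, "static_network"))
  if (network$n_nodes < 1) stop("network must be non-empty")
  community_method <- match.arg(community_method)
  g <- as_igraph(network)
  n <- network$n_nodes
  mean_degree <- 2 * nrow(network$edges) / n
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean_clustering <- mean(cc)
  mean_betweenness <- if (betweenness && n > 2) {
    mean(igraph::betweenness(g, directed = FALSE, normalized = TRUE))
  } else {
    NA_real_
  }
  if (is.null(membership)) {
    comm <- switch(community_method,
                   louvain = igraph::cluster_louvain(g),
                   fast_greedy = igraph::cluster_fast_greedy(g))
    membership <- igraph::membership(comm)
    Q <- igraph::modularity(comm)
  } else {
    Q <- igraph::modularity(g, membership)
  }
  r <- if (nrow(network$edges) > 0) igraph::assortativity_degree(g) else NaN
  if (is.nan(r)) r <- NA_real_
  deg <- igraph::degree(g)
  dd <- table(deg)
  structure(list(mean_degree = mean_degree,
                 mean_clustering = mean_clustering,
                 mean_betweenness = mean_betweenness,
                 modularity = Q,
                 assortativity = r,
                 degree_distribution = dd,
                 membership = as.integer(membership)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("network_stats: <k> = %.4g, <cc> = %.4g, <b> = %.4g, ",
                     "Q = %.4g, r = %s\n"),
              x$mean_degree, x$mean_clustering, x$mean_betweenness,
              x$modularity,
              if (is.na(x$assortativity)) "undefined"
              else sprintf("%.4g", x$assortativity)))
  invisible(x)
}
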