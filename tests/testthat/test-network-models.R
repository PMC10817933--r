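test_that("static_network validates and canonicalises edges", {
  net <- static_network(4, rbind(c(3, 1), c(2, 4)))
  expect_equal(net$edges, cbind(c(1L, 2L), c(3L, 4L)), ignore_attr = TRUE)
  expect_error(static_network(3, rbind(c(1, 1))), "self-loop")
  expect_error(static_network(3, rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(static_network(3, rbind(c(1, 4))), "node ids")
  expect_error(static_network(3, rbind(c(1, 2)), theta = c(0.5, 2, 0.1)),
               "theta")
})

test_that("ER generator hits edge probability and determinism contracts", {
  # p = 1 gives the complete graph
  k4 <- generate_er(4, 3, seed = 1)
  expect_equal(nrow(k4$edges), 6)

  # realised edge count within 4 sigma of the binomial expectation
  net <- generate_er(1000, 20, seed = 5)
  p <- 20 / 999
  npairs <- choose(1000, 2)
  expect_lt(abs(nrow(net$edges) - npairs * p),
            4 * sqrt(npairs * p * (1 - p)))

  expect_identical(generate_er(200, 10, seed = 3)$edges,
                   generate_er(200, 10, seed = 3)$edges)
  expect_error(generate_er(100, 120, seed = 1), "mean_degree")
})

test_that("mean ER clustering approaches the link probability", {
  cc <- vapply(1:40, function(i) {
    compute_stats(generate_er(1000, 20, seed = i), betweenness = FALSE,
                  membership = rep(1L, 1000))$mean_clustering
  }, numeric(1))
  expect_lt(abs(mean(cc) - 0.02) / 0.02, 0.1)
})

test_that("WS lattice has exact degree and closed-form clustering", {
  net <- generate_ws(1000, 6, 0, seed = 1)
  expect_true(all(tabulate(c(net$edges), nbins = 1000) == 6))
  st <- compute_stats(net, betweenness = FALSE,
                      membership = rep(1L, 1000))
  # ring-lattice closed form 3(k-2)/(4(k-1)) = 0.6 at k = 6
  expect_equal(st$mean_clustering, 0.6, tolerance = 1e-12)
  expect_error(generate_ws(100, 5, 0.1, seed = 1), "even")
})

test_that("fully rewired WS reaches the random-graph clustering level", {
  cc <- vapply(1:30, function(i) {
    compute_stats(generate_ws(1000, 6, 1, seed = i), betweenness = FALSE,
                  membership = rep(1L, 1000))$mean_clustering
  }, numeric(1))
  # random-graph limit <cc> ~ k/N = 0.006
  expect_gt(mean(cc), 0.002)
  expect_lt(mean(cc), 0.012)
})

test_that("fitness model has the exact growth-rule edge count for any beta", {
  for (beta in c(0, 100)) {
    net <- generate_fitness(1000, 3, beta, seed = beta + 1)
    expect_equal(nrow(net$edges), 3 + 3 * 997)
    expect_equal(2 * nrow(net$edges) / 1000, 5.988)
    expect_equal(length(net$theta), 1000)
  }
  expect_error(generate_fitness(3, 3, 0, seed = 1), "exceed")
})

test_that("beta = 0 reduces to pure degree-preferential attachment", {
  a <- generate_fitness(300, 3, beta = 0, seed = 17)
  b <- reference_ba(300, 3, seed = 17)
  expect_setequal(edge_key_set(a), edge_key_set(b))
})

test_that("beta = 0 degree distribution has a k^-3 power-law tail", {
  deg <- unlist(lapply(1:20, function(i) {
    net <- generate_fitness(1000, 3, 0, seed = 100 + i)
    tabulate(c(net$edges), nbins = 1000)
  }))
  # CCDF slope on k in [10, 100] should be about -2 for P(k) ~ k^-3
  ks <- 10:100
  ccdf <- vapply(ks, function(k) mean(deg >= k), numeric(1))
  keep <- ccdf > 0
  slope <- stats::coef(stats::lm(log(ccdf[keep]) ~ log(ks[keep])))[2]
  expect_lt(abs(slope - (-2)), 0.3)
})

test_that("clustering and modularity of fitness networks increase with beta", {
  stats_for <- function(beta) {
    res <- vapply(1:6, function(i) {
      st <- compute_stats(generate_fitness(1000, 3, beta, seed = 7 * i),
                          betweenness = FALSE)
      c(st$mean_clustering, st$modularity)
    }, numeric(2))
    rowMeans(res)
  }
  s0 <- stats_for(0)
  s20 <- stats_for(20)
  s100 <- stats_for(100)
  expect_lt(s0[1], s20[1])
  expect_lt(s20[1], s100[1])
  expect_lt(s0[2], s20[2])
  expect_lt(s20[2], s100[2])
})

test_that("configuration rewiring preserves degrees and graph simplicity", {
  net <- generate_fitness(400, 3, 100, seed = 2)
  rew <- rewire_to_configuration(net, n_swaps = 5 * nrow(net$edges), seed = 9)
  expect_equal(degree_sequence(rew), degree_sequence(net))
  expect_equal(nrow(rew$edges), nrow(net$edges))
  # constructor enforces simplicity; also check explicitly
  expect_true(all(rew$edges[, 1] != rew$edges[, 2]))
  expect_false(anyDuplicated(paste(rew$edges[, 1], rew$edges[, 2])) > 0)
  # rewiring really moved edges
  expect_gt(length(setdiff(edge_key_set(rew), edge_key_set(net))), 0)
  expect_error(rewire_to_configuration(static_network(2, rbind(c(1, 2))),
                                       seed = 1), "at least 2")
})

test_that("a triangle admits no valid swaps and passes through unchanged", {
  tri <- triangle_net()
  expect_warning(out <- rewire_to_configuration(tri, n_swaps = 5, seed = 3,
                                                max_attempts = 200),
                 "0 of 5")
  expect_equal(edge_key_set(out), edge_key_set(tri))
})

test_that("configuration rewiring of clustered networks destroys clustering", {
  net <- generate_fitness(1000, 3, 100, seed = 4)
  st0 <- compute_stats(net, betweenness = FALSE)
  rew <- rewire_to_configuration(net, seed = 5)
  st1 <- compute_stats(rew, betweenness = FALSE)
  expect_lt(st1$mean_clustering, st0$mean_clustering / 3)
})

test_that("structural statistics match hand-computable graphs", {
  tri <- compute_stats(triangle_net(), membership = rep(1L, 3))
  expect_equal(tri$mean_clustering, 1)
  expect_equal(tri$mean_degree, 2)

  star <- compute_stats(star_net(10), membership = rep(1L, 11))
  expect_equal(star$assortativity, -1)
  expect_equal(star$mean_clustering, 0)

  # two disjoint 5-cliques with the cliques as the partition: Q = 0.5
  tc <- two_cliques_net(5)
  st <- compute_stats(tc, membership = rep(1:2, each = 5))
  expect_equal(st$modularity, 0.5)

  # mean degree is exactly 2|E|/N for generator output
  net <- generate_er(500, 12, seed = 8)
  st2 <- compute_stats(net, betweenness = FALSE)
  expect_identical(st2$mean_degree, 2 * nrow(net$edges) / 500)

  # regular graph: assortativity undefined, reported as NA
  ring <- generate_ws(50, 4, 0, seed = 1)
  expect_true(is.na(compute_stats(ring, betweenness = FALSE,
                                  membership = rep(1L, 50))$assortativity))
})
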