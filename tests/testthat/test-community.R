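# modularity, Louvain, consensus clustering, stability summaries

test_that("modularity matches hand-worked and trivial cases", {
  tri2 <- matrix(0, 6, 6)
  tri2[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
  tri2 <- tri2 + t(tri2)
  # two disjoint unit triangles split into themselves: Q = 1 - 2 * (1/2)^2
  expect_equal(graph_modularity(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # the all-in-one partition always has Q = 0 at unit resolution
  expect_equal(graph_modularity(tri2, rep(1, 6)), 0)
  set.seed(1)
  for (i in 1:5) {
    w <- random_graph(7)
    expect_equal(graph_modularity(w, rep(1, 7)), 0, tolerance = 1e-12)
  }
  expect_error(graph_modularity(matrix(0, 3, 3), c(1, 1, 2)), "zero total weight")
})

test_that("modularity equals a naive double-loop oracle and respects relabeling", {
  set.seed(31)
  for (i in 1:10) {
    w <- random_graph(6)
    membership <- sample(1:3, 6, replace = TRUE)
    gamma <- sample(c(0.5, 1, 1.7), 1)
    q <- graph_modularity(w, membership, gamma)
    expect_equal(q, modularity_oracle(w, membership, gamma),
                 tolerance = 1e-12)
    # invariance under label permutation
    relabeled <- c(7, 9, 8)[membership]
    expect_equal(graph_modularity(w, relabeled, gamma), q, tolerance = 1e-14)
    expect_true(q >= -1 && q <= 1)
  }
})

test_that("modularity agrees with igraph on weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (i in 1:5) {
    w <- random_graph(10)
    membership <- sample(1:3, 10, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(graph_modularity(w, membership),
                 igraph::modularity(g, membership,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain separates disjoint cliques for any seed", {
  w <- matrix(0, 9, 9)
  w[1:4, 1:4] <- 1
  w[5:9, 5:9] <- 1
  diag(w) <- 0
  for (seed in c(1, 7, 99)) {
    p <- louvain(w, rng_seed = seed)
    expect_identical(p$n_communities, 2L)
    expect_equal(ari(p$assignment, rep(1:2, c(4, 5))), 1)
    # canonical labels: larger community first
    expect_identical(unname(p$assignment[5]), 1L)
  }
})

test_that("louvain attains the exhaustive-partition optimum on most small graphs", {
  set.seed(35)
  hits <- 0
  for (i in 1:20) {
    n <- sample(5:8, 1)
    w <- random_graph(n, density = 0.5)
    if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
    q_best <- best_modularity(w)
    p <- louvain(w, rng_seed = i)
    expect_lte(p$modularity, q_best + 1e-12)    # never above the optimum
    if (abs(p$modularity - q_best) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("louvain's reported Q is consistent and never below the trivial partition", {
  set.seed(37)
  for (i in 1:8) {
    w <- random_graph(12)
    p <- louvain(w, rng_seed = i)
    expect_equal(p$modularity,
                 graph_modularity(w, p$assignment), tolerance = 1e-12)
    expect_gte(p$modularity, 0)     # all-in-one gives exactly 0
  }
})

test_that("louvain is deterministic given the seed", {
  set.seed(39)
  w <- random_graph(30)
  expect_identical(louvain(w, rng_seed = 4), louvain(w, rng_seed = 4))
})

test_that("louvain recovers planted blocks on a group-level matrix", {
  pb <- planted_block_matrix(c(30, 25, 20, 25), seed = 41)
  g <- as_graph_weights(pb$fc)
  p <- louvain(g$weights, rng_seed = 3)
  expect_identical(p$n_communities, 4L)
  expect_equal(ari(p$assignment, pb$labels), 1)
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                            weighted = TRUE)
  ref <- igraph::cluster_louvain(ig)
  expect_equal(ari(p$assignment, igraph::membership(ref)), 1)
})

test_that("negative-weight policies transform the matrix as documented", {
  z <- matrix(c(0, -0.2, 0.5, -0.2, 0, NA, 0.5, NA, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  fc <- hypoparc:::new_connectivity_matrix(letters[1:3], z)
  gz <- as_graph_weights(fc, "zero")
  expect_equal(gz$weights["a", "b"], 0)
  expect_equal(gz$weights["a", "c"], 0.5)
  expect_equal(gz$weights["b", "c"], 0)          # NA treated as no edge
  ga <- as_graph_weights(fc, "abs")
  expect_equal(ga$weights["a", "b"], 0.2)
  # fully missing nodes are dropped
  z2 <- matrix(0.3, 3, 3, dimnames = dimnames(z))
  diag(z2) <- 0
  z2["a", 2:3] <- z2[2:3, "a"] <- NA
  fc2 <- hypoparc:::new_connectivity_matrix(letters[1:3], z2)
  expect_identical(as_graph_weights(fc2)$dropped, "a")
})

test_that("consensus on a noiseless two-block matrix is perfect", {
  pb <- planted_block_matrix(c(8, 6), within = 0.5, between = 0.05,
                             noise = 0, seed = 43)
  cons <- consensus_partition(pb$fc, n_iterations = 10, rng_seed = 2)
  expect_identical(cons$partition$n_communities, 2L)
  expect_equal(ari(cons$partition$assignment, pb$labels), 1)
  within <- outer(pb$labels, pb$labels, "==")
  expect_true(all(cons$coassignment$proportions[within] == 1))
  expect_true(all(diag(cons$coassignment$proportions) == 1))
})

test_that("consensus recovers four planted communities and is deterministic", {
  pb <- planted_block_matrix(c(30, 25, 20, 25), seed = 45)
  a <- consensus_partition(pb$fc, n_iterations = 15, rng_seed = 9)
  b <- consensus_partition(pb$fc, n_iterations = 15, rng_seed = 9)
  expect_identical(a$partition$assignment, b$partition$assignment)
  expect_identical(a$coassignment$proportions, b$coassignment$proportions)
  expect_identical(a$partition$n_communities, 4L)
  expect_equal(ari(a$partition$assignment, pb$labels), 1)
})

test_that("a single consensus iteration reduces to re-clustering one partition", {
  pb <- planted_block_matrix(c(10, 8), seed = 47)
  cons <- consensus_partition(pb$fc, n_iterations = 1, rng_seed = 5)
  single <- louvain(as_graph_weights(pb$fc)$weights,
                    rng_seed = hypoparc:::derive_seed(5, 1))
  binary <- outer(single$assignment, single$assignment, "==") * 1
  expect_identical(unname(cons$coassignment$proportions), unname(binary))
  refit <- louvain({
    w <- binary; diag(w) <- 0; w
  }, rng_seed = hypoparc:::derive_seed(5, 2))
  expect_identical(cons$partition$assignment, refit$assignment)
})

test_that("stability summaries match a loop-based recomputation", {
  pb <- planted_block_matrix(c(12, 9, 7), within = 0.45, between = 0.12,
                             noise = 0.05, seed = 49)
  cons <- consensus_partition(pb$fc, n_iterations = 25, rng_seed = 11)
  tab <- stability_summary(cons$coassignment, cons$partition)
  expect_equal(sum(tab$n_voxels), length(pb$labels))
  for (row in seq_len(nrow(tab))) {
    members <- names(cons$partition$assignment)[
      cons$partition$assignment == tab$community[row]]
    vals <- c()
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (i < j) {
          vals <- c(vals, cons$coassignment$proportions[members[i],
                                                        members[j]])
        }
      }
    }
    expect_equal(tab$mean_coassignment[row], mean(vals))
    expect_equal(tab$p25[row], unname(quantile(vals, 0.25)))
    expect_equal(tab$p75[row], unname(quantile(vals, 0.75)))
  }
})

test_that("singleton communities are flagged with unit stability", {
  co <- structure(list(node_ids = c("a", "b", "c"),
                       proportions = diag(3) * 0 + diag(3) +
                         matrix(c(0, .6, 0, .6, 0, 0, 0, 0, 0), 3, 3),
                       n_iterations = 10),
                  class = "coassignment_matrix")
  dimnames(co$proportions) <- list(co$node_ids, co$node_ids)
  part <- hypoparc:::new_partition(setNames(c(1L, 1L, 2L), c("a", "b", "c")),
                                   modularity = 0)
  tab <- stability_summary(co, part)
  expect_true(tab$singleton[tab$community == 2])
  expect_equal(tab$mean_coassignment[tab$community == 2], 1)
  expect_equal(tab$mean_coassignment[tab$community == 1], 0.6)
})

test_that("hand-built co-assignment proportions average correctly", {
  # 3-node community with pair proportions 0.6, 0.8, 1.0 -> mean 0.8
  p <- matrix(1, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.6
  p[1, 3] <- p[3, 1] <- 0.8
  p[2, 3] <- p[3, 2] <- 1.0
  dimnames(p) <- list(c("a", "b", "c"), c("a", "b", "c"))
  co <- structure(list(node_ids = c("a", "b", "c"), proportions = p,
                       n_iterations = 5), class = "coassignment_matrix")
  part <- hypoparc:::new_partition(setNames(rep(1L, 3), c("a", "b", "c")), 0)
  expect_equal(stability_summary(co, part)$mean_coassignment, 0.8)
})

test_that("graphs with invalid structure are rejected", {
  expect_error(louvain(matrix(1:9, 3, 3)), "symmetric")
  w <- random_graph(4); diag(w) <- 1
  expect_error(louvain(w), "zero diagonal")
  w2 <- matrix(-1, 2, 2); diag(w2) <- 0
  expect_error(louvain(w2), "non-negative")
})
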