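#' Newman-Girvan weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij [w_ij - gamma * k_i * k_j / (2m)] * delta(c_i, c_j)`
#' with `m` the total edge weight, `k` the weighted degrees and `gamma` the
#' resolution parameter.  This is the objective the Louvain algorithm
#' maximises.
#'
#' @param weights symmetric non-negative weight matrix with zero diagonal.
#' @param membership integer community label per node.
#' @param resolution resolution `gamma` (default 1).
#' @return the modularity value.
#' @examples
#' tri2 <- matrix(0, 6, 6)
#' tri2[cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6))] <- 1
#' tri2 <- tri2 + t(tri2)
#' graph_modularity(tri2, c(1, 1, 1, 2, 2, 2))  # 0.5
#' @export
graph_modularity <- function(weights, membership, resolution = 1) {
  check_graph(weights)
  n <- nrow(weights)
  if (length(membership) != n) stop_("membership must cover all nodes")
  two_m <- sum(weights)
  if (two_m <= 0) stop_("graph has zero total weight")
  comm <- factor(membership)
  k <- rowSums(weights)
  within <- rowsum(t(rowsum(weights, comm)), comm)
  tot <- rowsum(k, comm)
  sum(diag(as.matrix(within))) / two_m -
    resolution * sum((tot / two_m)^2)
}

check_graph <- function(weights) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop_("weights must be a square matrix")
  }
  if (any(is.na(weights))) stop_("weights must not contain NA")
  if (max(abs(weights - t(weights))) > 1e-10) stop_("weights must be symmetric")
  if (any(diag(weights) != 0)) stop_("weights must have a zero diagonal")
  if (min(weights) < 0) {
    stop_("weights must be non-negative; apply a negative-weight policy first")
  }
  invisible(TRUE)
}

#' Louvain community detection
#'
#' Greedy two-phase modularity optimisation implemented from scratch:
#' repeated local moves (each pass visits nodes in a seeded uniform random
#' order and accepts only strictly positive modularity gains) followed by
#' graph aggregation, until no further improvement.  Deterministic given
#' `rng_seed`.
#'
#' @param weights symmetric non-negative weight matrix, zero diagonal.
#' @param resolution resolution `gamma` (default 1).
#' @param rng_seed integer seed controlling the node sweep order.
#' @return a `partition`: list with `assignment` (named integer vector of
#'   community labels, canonicalised as 1..K by decreasing community size,
#'   ties broken by the smallest member node), `n_communities`, and
#'   `modularity` (which equals [graph_modularity()] of the assignment).
#' @export
louvain <- function(weights, resolution = 1, rng_seed = 1L) {
  check_graph(weights)
  nodes <- rownames(weights) %||% sprintf("n%d", seq_len(nrow(weights)))
  if (sum(weights) <= 0) stop_("graph has zero total weight")
  membership <- with_seed(rng_seed, louvain_run(weights, resolution))
  labels <- canonicalize_labels(membership)
  new_partition(setNames(labels, nodes),
                modularity = graph_modularity(weights, labels, resolution))
}

new_partition <- function(assignment, modularity) {
  structure(list(assignment = assignment,
                 n_communities = length(unique(assignment)),
                 modularity = modularity),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, Q = %.4f\n",
              length(x$assignment), x$n_communities, x$modularity))
  invisible(x)
}

# full multi-level Louvain; RNG state supplied by the caller
louvain_run <- function(w, resolution) {
  n0 <- nrow(w)
  membership <- seq_len(n0)
  repeat {
    res <- louvain_local(w, resolution)
    if (!res$moved) break
    membership <- res$comm[membership]
    # aggregate: community c becomes a node; internal weight (counted over
    # ordered pairs) lands on the diagonal, preserving degrees and Q
    f <- factor(res$comm, levels = sort(unique(res$comm)))
    w <- rowsum(t(rowsum(w, f)), f)
    w <- as.matrix(w)
    dimnames(w) <- NULL
    membership <- as.integer(factor(membership,
                                    levels = sort(unique(res$comm))))
    if (nrow(w) == 1) break
  }
  membership
}

# one level of local moves; every node starts in its own community.
# Diagonal entries of w are self-loop weights from previous aggregations;
# they never enter the link terms (a self-loop follows its node) but do
# count towards degrees.
louvain_local <- function(w, resolution) {
  n <- nrow(w)
  k <- rowSums(w)
  two_m <- sum(k)
  comm <- seq_len(n)
  tot <- k
  moved_any <- FALSE
  repeat {
    n_moves <- 0L
    for (i in sample.int(n)) {
      ci <- comm[i]
      wi <- w[i, ]
      links <- numeric(n)
      agg <- rowsum(wi, comm)
      links[as.integer(rownames(agg))] <- agg
      links[ci] <- links[ci] - w[i, i]
      tot[ci] <- tot[ci] - k[i]
      gain <- links - resolution * k[i] * tot / two_m
      cand <- which(links > 0)
      cand <- union(cand, ci)
      best <- cand[which.max(gain[cand])]
      # strict improvement required to move (guarantees termination);
      # ties favour staying
      if (best != ci && gain[best] > gain[ci] + 1e-12) {
        comm[i] <- best
        tot[best] <- tot[best] + k[i]
        n_moves <- n_moves + 1L
        moved_any <- TRUE
      } else {
        tot[ci] <- tot[ci] + k[i]
      }
    }
    if (n_moves == 0L) break
  }
  list(comm = comm, moved = moved_any)
}

#' Convert a Fisher-z connectivity matrix to graph weights
#'
#' Applies the configured negative-weight policy (standard modularity is
#' undefined for signed graphs): `"zero"` (default, the dominant convention
#' in functional-connectivity parcellation) sets negative entries to zero;
#' `"abs"` takes absolute values.  Nodes whose off-diagonal entries are all
#' missing are dropped; any remaining `NA` entries are treated as absent
#' edges (zero weight).
#'
#' @param fc a `connectivity_matrix`.
#' @param negative_policy `"zero"` or `"abs"`.
#' @return list with `weights` (matrix) and `dropped` (node ids removed).
#' @export
as_graph_weights <- function(fc, negative_policy = c("zero", "abs")) {
  negative_policy <- match.arg(negative_policy)
  z <- fc$z
  diag(z) <- NA
  drop <- rowSums(!is.na(z)) == 0
  keep <- which(!drop)
  z <- z[keep, keep, drop = FALSE]
  z[is.na(z)] <- 0
  w <- switch(negative_policy, zero = pmax(z, 0), abs = abs(z))
  diag(w) <- 0
  list(weights = w, dropped = fc$node_ids[drop])
}

#' Consensus Louvain partition of a connectivity matrix
#'
#' Runs Louvain `n_iterations` times on the graph built from `fc` (one
#' derived seed per iteration, so only the node sweep order differs),
#' forms the co-assignment matrix -- the proportion of iterations in which
#' each node pair landed in the same community -- and applies Louvain once
#' more to that proportion matrix to obtain the final consensus partition.
#'
#' @param fc a `connectivity_matrix` (group-level Fisher-z).
#' @param n_iterations number of Louvain iterations (the study design uses
#'   100).
#' @param resolution resolution `gamma` (default 1).
#' @param rng_seed base seed; iteration `i` uses seed `rng_seed + i` and
#'   the final clustering of the proportion matrix uses
#'   `rng_seed + n_iterations + 1`.
#' @param negative_policy see [as_graph_weights()].
#' @return list with `partition` (the final `partition`; nodes with no
#'   usable edges are absent from it), `coassignment` (a
#'   `coassignment_matrix`: proportions in `[0, 1]`, unit diagonal), and
#'   `iteration_partitions` (matrix of per-iteration labels, nodes x
#'   iterations).
#' @export
consensus_partition <- function(fc, n_iterations = 100, resolution = 1,
                                rng_seed = 1L,
                                negative_policy = c("zero", "abs")) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  if (!is_count(n_iterations)) stop_("n_iterations must be >= 1")
  g <- as_graph_weights(fc, negative_policy)
  w <- g$weights
  n <- nrow(w)
  nodes <- rownames(w)
  prop <- matrix(0, n, n, dimnames = list(nodes, nodes))
  iters <- matrix(NA_integer_, n, n_iterations,
                  dimnames = list(nodes, NULL))
  for (i in seq_len(n_iterations)) {
    p <- louvain(w, resolution, rng_seed = derive_seed(rng_seed, i))
    lab <- p$assignment
    prop <- prop + outer(lab, lab, "==")
    iters[, i] <- lab
  }
  prop <- prop / n_iterations
  diag(prop) <- 1
  co <- structure(list(node_ids = nodes, proportions = prop,
                       n_iterations = n_iterations),
                  class = "coassignment_matrix")
  w_final <- prop
  diag(w_final) <- 0
  final <- louvain(w_final, resolution,
                   rng_seed = derive_seed(rng_seed, n_iterations + 1))
  if (length(g$dropped) > 0) {
    attr(final, "dropped_nodes") <- g$dropped
  }
  list(partition = final, coassignment = co, iteration_partitions = iters)
}

#' @export
print.coassignment_matrix <- function(x, ...) {
  cat(sprintf("<coassignment_matrix> %d nodes, %d iterations, mean off-diagonal %.3f\n",
              nrow(x$proportions), x$n_iterations,
              mean(x$proportions[row(x$proportions) != col(x$proportions)])))
  invisible(x)
}

#' Per-community co-assignment stability summary
#'
#' For each final community: voxel count, the mean co-assignment
#' proportion over its unordered within-community node pairs, and the 25th
#' and 75th percentiles of those proportions.  A singleton community has no
#' pairs; its mean is reported as 1 with `singleton = TRUE`.
#'
#' @param coassignment a `coassignment_matrix`.
#' @param partition the final consensus `partition` on the same nodes.
#' @return data.frame with columns `community`, `n_voxels`,
#'   `mean_coassignment`, `p25`, `p75`, `singleton`.
#' @export
stability_summary <- function(coassignment, partition) {
  stopifnot(inherits(coassignment, "coassignment_matrix"),
            inherits(partition, "partition"))
  nodes <- coassignment$node_ids
  lab <- partition$assignment[nodes]
  if (anyNA(lab)) stop_("partition does not cover the co-assignment nodes")
  comms <- sort(unique(lab))
  rows <- lapply(comms, function(c) {
    members <- which(lab == c)
    if (length(members) == 1) {
      return(data.frame(community = c, n_voxels = 1L,
                        mean_coassignment = 1, p25 = 1, p75 = 1,
                        singleton = TRUE))
    }
    p <- coassignment$proportions[members, members]
    vals <- p[upper.tri(p)]
    q <- quantile(vals, c(0.25, 0.75), names = FALSE)
    data.frame(community = c, n_voxels = length(members),
               mean_coassignment = mean(vals), p25 = q[1], p75 = q[2],
               singleton = FALSE)
  })
  do.call(rbind, rows)
}
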