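# shared fixtures: all synthetic, built in code at test time

# a small but fully featured study configuration
small_config <- function(rng_seed = 7, n_subjects = 4, tt = 120,
                         community_sizes = c(30, 25, 20, 25),
                         network_sizes = c(15, 15),
                         n_artifact_voxels = 5) {
  runs <- if (n_subjects >= 3) {
    cbind(c(3, 2, 1), c(n_subjects - 2, 1, 1))
  } else {
    cbind(2, n_subjects)
  }
  simulation_config(
    n_subjects = n_subjects,
    runs_per_subject = runs,
    n_timepoints_per_run = tt,
    community_sizes = community_sizes,
    network_sizes = network_sizes,
    network_coupling_z = rbind(rep(0.12, length(community_sizes)),
                               rep(0.03, length(community_sizes)))[
                                 seq_along(network_sizes), , drop = FALSE],
    n_artifact_voxels = n_artifact_voxels,
    rng_seed = rng_seed)
}

# a bare timeseries run from a signal matrix
make_run <- function(signal, run_id = "r1", subject_id = "s1",
                     confounds = NULL, tr = 2) {
  if (is.null(rownames(signal))) {
    rownames(signal) <- sprintf("n%02d", seq_len(nrow(signal)))
  }
  hypoparc:::new_timeseries_run(subject_id, run_id, signal, confounds, tr)
}

random_run <- function(n_nodes, tt, run_id = "r1", subject_id = "s1") {
  make_run(matrix(rnorm(n_nodes * tt), n_nodes, tt), run_id, subject_id)
}

# symmetric non-negative random weight matrix with zero diagonal
random_graph <- function(n, density = 0.7) {
  w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# planted block Fisher-z matrix (group-level style)
planted_block_matrix <- function(sizes, within = 0.42, between = 0.15,
                                 noise = 0.01, seed = 1) {
  lab <- rep(seq_along(sizes), sizes)
  n <- sum(sizes)
  set.seed(seed)
  z <- matrix(between, n, n)
  z[outer(lab, lab, "==")] <- within
  z <- z + matrix(rnorm(n * n, 0, noise), n, n)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  ids <- sprintf("V%03d", seq_len(n))
  dimnames(z) <- list(ids, ids)
  list(z = z, labels = setNames(lab, ids),
       fc = hypoparc:::new_connectivity_matrix(ids, z))
}

# naive double-loop modularity oracle
modularity_oracle <- function(w, membership, resolution = 1) {
  n <- nrow(w)
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + w[i, j] - resolution * k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# all set partitions of n items as a list of membership vectors
# (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      grow(c(prefix, lab), max(maxlab, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

# exhaustive maximum-modularity oracle for small graphs
best_modularity <- function(w, resolution = 1) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(p) modularity_oracle(w, p, resolution),
             numeric(1)))
}

# chance-corrected agreement between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent brute-force sums-of-squares oracle working from raw loops
rm_anova_oracle <- function(tab) {
  subs <- sort(unique(tab$subject)); nets <- sort(unique(tab$network))
  comms <- sort(unique(tab$community))
  n <- length(subs); a <- length(nets); b <- length(comms)
  y <- array(0, c(n, a, b))
  for (r in seq_len(nrow(tab))) {
    y[match(tab$subject[r], subs), match(tab$network[r], nets),
      match(tab$community[r], comms)] <- tab$mean_z[r]
  }
  g <- mean(y)
  ss <- function(idx_fun, div) sum((apply(y, idx_fun, mean) - g)^2) * div
  ss_a <- ss(2, n * b); ss_b <- ss(3, n * a); ss_s <- ss(1, a * b)
  ss_ab <- 0
  for (i in 1:a) for (j in 1:b) {
    ss_ab <- ss_ab + n * (mean(y[, i, j]) - mean(y[, i, ]) -
                            mean(y[, , j]) + g)^2
  }
  ss_as <- 0
  for (s in 1:n) for (i in 1:a) {
    ss_as <- ss_as + b * (mean(y[s, i, ]) - mean(y[s, , ]) -
                            mean(y[, i, ]) + g)^2
  }
  ss_bs <- 0
  for (s in 1:n) for (j in 1:b) {
    ss_bs <- ss_bs + a * (mean(y[s, , j]) - mean(y[s, , ]) -
                            mean(y[, , j]) + g)^2
  }
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  f_a <- (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) /
    (ss_abs / ((a - 1) * (b - 1) * (n - 1)))
  list(F = c(f_a, f_b, f_ab), ss_total = ss_tot,
       parts = c(ss_a, ss_b, ss_ab, ss_s, ss_as, ss_bs, ss_abs))
}
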