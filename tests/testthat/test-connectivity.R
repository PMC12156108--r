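# nuisance regression, Fisher z, subject/group connectivity, ROI extraction

test_that("fisher_z matches the closed form and clips degenerate input", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))        # strictly increasing
  expect_equal(fisher_z(-r), -fisher_z(r))       # odd
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("confound regression is a projection with orthogonal residuals", {
  set.seed(2)
  tt <- 80
  conf <- matrix(rnorm(tt * 3), tt, 3,
                 dimnames = list(NULL, c("trans_x", "trans_y", "rot_z")))
  run <- make_run(matrix(rnorm(5 * tt), 5, tt), confounds = conf)
  run$signal[2, ] <- conf[, 1]                   # a pure confound voxel
  res <- regress_confounds(run, highpass_cutoff = 120)
  x <- cbind(1, conf, hypoparc:::dct_basis(tt, 2, 120))
  expect_lt(max(abs(x %*% t(x) %*% t(res$signal))) /
              max(abs(res$signal)), 1e-8)
  expect_lt(max(abs(t(x) %*% t(res$signal))), 1e-10)
  expect_lt(max(abs(res$signal[2, ])), 1e-10)
  # residuals match an explicit normal-equations oracle
  beta <- solve(t(x) %*% x, t(x) %*% t(run$signal))
  oracle <- t(run$signal) - x %*% beta
  expect_equal(unname(res$signal), unname(t(oracle)), tolerance = 1e-10)
})

test_that("a signal already orthogonal to the design is returned unchanged", {
  tt <- 64
  x <- cbind(1, hypoparc:::dct_basis(tt, 2, 120))
  set.seed(4)
  raw <- matrix(rnorm(3 * tt), 3, tt)
  ortho <- t(qr.resid(qr(x), t(raw)))
  rownames(ortho) <- c("a", "b", "c")
  run <- make_run(ortho)
  res <- regress_confounds(run, highpass_cutoff = 120)
  expect_equal(res$signal, ortho, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  tt <- 40
  conf <- matrix(rnorm(tt * 2), tt, 2, dimnames = list(NULL, c("a", "b")))
  conf <- cbind(conf, dup = conf[, 1])
  run <- make_run(matrix(rnorm(2 * tt), 2, tt), confounds = conf)
  expect_error(regress_confounds(run), "rank deficient")
})

test_that("subject connectivity equals plain Pearson + atanh on complete data", {
  set.seed(6)
  runs <- list(random_run(6, 50, "r1"), random_run(6, 70, "r2"))
  fc <- subject_connectivity(runs)
  concat <- cbind(runs[[1]]$signal, runs[[2]]$signal)
  oracle <- atanh(cor(t(concat)))
  diag(oracle) <- 0
  expect_equal(fc$z, oracle, tolerance = 1e-12)
  expect_true(isSymmetric(fc$z))
  expect_true(all(diag(fc$z) == 0))
  expect_true(all(fc$n_samples == 120))
})

test_that("pairwise availability uses exactly the runs shared by both nodes", {
  set.seed(8)
  runs <- lapply(1:3, function(i) random_run(4, 300, paste0("r", i)))
  av <- matrix(TRUE, 4, 3,
               dimnames = list(rownames(runs[[1]]$signal),
                               c("r1", "r2", "r3")))
  av["n02", "r2"] <- FALSE
  fc <- subject_connectivity(runs, av)
  expect_equal(fc$n_samples["n01", "n02"], 600)
  # two-pass oracle on the 600-point concatenation of runs 1 and 3
  x <- c(runs[[1]]$signal["n01", ], runs[[3]]$signal["n01", ])
  y <- c(runs[[1]]$signal["n02", ], runs[[3]]$signal["n02", ])
  expect_equal(fc$z["n01", "n02"], atanh(cor(x, y)), tolerance = 1e-12)
  # pairs not involving n02 still use all 900 timepoints
  expect_equal(fc$n_samples["n01", "n03"], 900)
})

test_that("identical node signals produce a clipped Fisher z with a warning", {
  sig <- matrix(rnorm(40), 2, 20, byrow = TRUE)
  sig[2, ] <- sig[1, ]
  rownames(sig) <- c("a", "b")
  expect_warning(fc <- subject_connectivity(list(make_run(sig))), "clipped")
  expect_equal(fc$z["a", "b"], atanh(1 - 1e-7))
})

test_that("nodes with no available run are rejected", {
  runs <- list(random_run(3, 20))
  av <- matrix(c(TRUE, TRUE, FALSE), 3, 1,
               dimnames = list(rownames(runs[[1]]$signal), "r1"))
  expect_error(subject_connectivity(runs, av), "at least one run")
})

test_that("group averaging is an entrywise NA-aware mean", {
  set.seed(10)
  mats <- lapply(1:20, function(i) {
    fc <- subject_connectivity(list(random_run(5, 30)))
    if (i <= 3) fc$z[1, 2] <- fc$z[2, 1] <- NA   # missing in a few subjects
    fc
  })
  g <- group_average(mats)
  # independent loop-based oracle
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    vals <- vapply(mats, function(m) m$z[i, j], numeric(1))
    oracle[i, j] <- mean(vals, na.rm = TRUE)
  }
  expect_equal(unname(g$z), oracle, tolerance = 1e-12)
  expect_equal(g$n_subjects[1, 2], 17)
  # idempotence and simple arithmetic
  expect_equal(group_average(list(mats[[4]], mats[[4]]))$z, mats[[4]]$z)
  a <- mats[[4]]; b <- mats[[4]]
  a$z[1, 2] <- a$z[2, 1] <- 0.2
  b$z[1, 2] <- b$z[2, 1] <- 0.4
  expect_equal(group_average(list(a, b))$z[1, 2], 0.3)
  # an entry missing everywhere errors unless explicitly kept
  for (m in seq_along(mats)) mats[[m]]$z[1, 2] <- mats[[m]]$z[2, 1] <- NA
  expect_error(group_average(mats), "missing in every subject")
  kept <- group_average(mats, na_action = "keep")
  expect_true(is.na(kept$z[1, 2]))
})

test_that("group averaging commutes with node reordering", {
  set.seed(12)
  mats <- lapply(1:4, function(i) subject_connectivity(list(random_run(6, 40))))
  g <- group_average(mats)
  perm <- sample(6)
  mats_p <- lapply(mats, function(m) {
    hypoparc:::new_connectivity_matrix(m$node_ids[perm],
                                       m$z[perm, perm])
  })
  gp <- group_average(mats_p)
  expect_equal(gp$z, g$z[perm, perm])
})

test_that("ROI extraction averages available member voxels", {
  set.seed(14)
  run <- random_run(5, 25)
  labels <- setNames(c(1, 1, 2, 3, 3), rownames(run$signal))
  # single-voxel parcel equals that voxel's series
  roi <- extract_roi_timeseries(run, labels)
  expect_equal(roi$signal["2", ], run$signal[3, ], ignore_attr = TRUE)
  # opposite series cancel
  run$signal[5, ] <- -run$signal[4, ]
  roi <- extract_roi_timeseries(run, labels)
  expect_equal(max(abs(roi$signal["3", ])), 0)
  # availability removes a member from the mean
  av <- setNames(c(TRUE, FALSE, TRUE, TRUE, TRUE), names(labels))
  roi_av <- extract_roi_timeseries(run, labels, availability = av)
  expect_equal(roi_av$signal["1", ], run$signal[1, ], ignore_attr = TRUE)
  # empty parcels error
  av2 <- setNames(c(FALSE, FALSE, TRUE, TRUE, TRUE), names(labels))
  expect_error(extract_roi_timeseries(run, labels, availability = av2),
               "no available member")
})

test_that("extracted community series track the generating community means", {
  cfg <- small_config(rng_seed = 25, n_subjects = 1, tt = 200,
                      n_artifact_voxels = 0)
  sim <- simulate_study(cfg, roi_data = FALSE)
  gt <- sim$ground_truth
  run <- sim$voxel_runs[[1]]
  roi <- extract_roi_timeseries(run, gt$voxel_community,
                                parcel_ids = gt$community_ids)
  # compare against the planted block structure: a community's mean signal
  # correlates far better with its own voxels than any other parcel does
  for (c in seq_along(cfg$community_sizes)) {
    members <- names(gt$voxel_community)[gt$voxel_community == c]
    m_true <- colMeans(run$signal[members, ])
    expect_gt(cor(roi$signal[gt$community_ids[c], ], m_true), 0.9)
  }
})
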