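#' Configuration for a synthetic resting-state study
#'
#' Describes a multi-subject, multi-run study with planted structure: voxel
#' communities with exchangeable block covariance, cortical ROIs grouped
#' into networks with controlled Fisher-z coupling to each community's mean
#' signal, high-variance artifact voxels (mimicking third-ventricle
#' pulsation), and a missing-run pattern.
#'
#' The voxel signal model is a one-factor-per-community construction:
#' a voxel in community `c` is
#' `sqrt(b) * g + sqrt(w - b) * f_c + noise_sd * sqrt(1 - w) * e_v`
#' with `g` a global factor, `f_c` a community factor and `e_v`
#' idiosyncratic noise, all standard normal.  At `noise_sd = 1` the
#' population Pearson correlation is exactly `w` within a community and `b`
#' between communities.  Each cortical ROI mixes the (standardised)
#' community mean signals with weights solved from the target Fisher-z
#' coupling matrix, so the expected ROI-community correlation equals the
#' planted value.
#'
#' @param n_subjects number of subjects.
#' @param runs_per_subject two-column matrix or data.frame
#'   (`n_runs`, `n_subjects`) giving how many subjects have each run
#'   count; the subject counts must sum to `n_subjects`.
#' @param n_timepoints_per_run timepoints per run (default 300).
#' @param community_sizes integer vector of planted voxel community sizes
#'   (all positive); their sum is the number of analysed voxels.
#' @param network_sizes integer vector of planted cortical network sizes
#'   (all positive); their sum is the number of cortical ROIs.
#' @param within_community_r target Pearson correlation between voxels of
#'   the same community, in (0, 1).
#' @param between_community_r target correlation between voxels of
#'   different communities, in `[0, within_community_r)`.
#' @param network_coupling_z networks x communities matrix of target mean
#'   Fisher-z coupling between a network's ROIs and each community mean
#'   signal.
#' @param subject_coupling_sd between-subject SD of a subject's true
#'   network coupling (a network-wise random shift of the Fisher-z
#'   targets); models stable individual differences.
#' @param n_artifact_voxels number of voxels whose signal is replaced by
#'   independent high-variance noise.
#' @param artifact_variance_factor variance of an artifact voxel relative
#'   to the median clean voxel variance (> 1).
#' @param noise_sd scale of the idiosyncratic voxel noise; 1 (default)
#'   calibrates the empirical correlations to the targets.
#' @param sampling_interval repetition time in seconds (default 2.34).
#' @param rng_seed integer seed making the whole study reproducible.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [default_study_config()], [simulate_study()]
#' @export
simulation_config <- function(n_subjects,
                              runs_per_subject,
                              n_timepoints_per_run = 300,
                              community_sizes,
                              network_sizes,
                              within_community_r = 0.40,
                              between_community_r = 0.15,
                              network_coupling_z = NULL,
                              subject_coupling_sd = 0.04,
                              n_artifact_voxels = 0,
                              artifact_variance_factor = 20,
                              noise_sd = 1,
                              sampling_interval = 2.34,
                              rng_seed = 1L) {
  if (!is_count(n_subjects)) stop_("n_subjects must be a positive integer")
  runs_per_subject <- as.data.frame(runs_per_subject)
  names(runs_per_subject) <- c("n_runs", "n_subjects")
  if (any(runs_per_subject$n_runs < 1) ||
      sum(runs_per_subject$n_subjects) != n_subjects) {
    stop_("runs_per_subject subject counts must be positive and sum to ",
          "n_subjects")
  }
  if (!is_count(n_timepoints_per_run, min = 3)) {
    stop_("n_timepoints_per_run must be an integer >= 3")
  }
  community_sizes <- as.integer(community_sizes)
  network_sizes <- as.integer(network_sizes)
  if (any(community_sizes < 1)) stop_("every planted community must be non-empty")
  if (any(network_sizes < 1)) stop_("every planted network must be non-empty")
  if (!(within_community_r > 0 && within_community_r < 1)) {
    stop_("within_community_r must lie in (0, 1)")
  }
  if (!(between_community_r >= 0 && between_community_r < within_community_r)) {
    stop_("between_community_r must lie in [0, within_community_r)")
  }
  if (noise_sd < 0) stop_("noise_sd must be non-negative")
  k <- length(community_sizes)
  if (is.null(network_coupling_z)) {
    network_coupling_z <- matrix(0, length(network_sizes), k)
  }
  network_coupling_z <- as.matrix(network_coupling_z)
  if (!all(dim(network_coupling_z) == c(length(network_sizes), k))) {
    stop_("network_coupling_z must be a ", length(network_sizes), " x ", k,
          " matrix (networks x communities)")
  }
  if (n_artifact_voxels < 0 || n_artifact_voxels >= sum(community_sizes)) {
    stop_("n_artifact_voxels must be non-negative and smaller than the ",
          "number of voxels")
  }
  if (artifact_variance_factor <= 1) {
    stop_("artifact_variance_factor must exceed 1")
  }
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects),
         runs_per_subject = runs_per_subject,
         n_timepoints_per_run = as.integer(n_timepoints_per_run),
         community_sizes = community_sizes,
         network_sizes = network_sizes,
         within_community_r = within_community_r,
         between_community_r = between_community_r,
         network_coupling_z = network_coupling_z,
         subject_coupling_sd = subject_coupling_sd,
         n_artifact_voxels = as.integer(n_artifact_voxels),
         artifact_variance_factor = artifact_variance_factor,
         noise_sd = noise_sd,
         sampling_interval = sampling_interval,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config")
  # reject couplings whose implied ROI construction is not positive definite
  coupling_weights(cfg)
  cfg
}

#' Default study configuration
#'
#' The study conditions the generator emulates: 104 subjects of whom 91
#' contribute three runs, nine two runs and four one run (295 runs in
#' total), four planted hypothalamic communities of 295, 234, 291 and 199
#' voxels (1019 voxels), 360 cortical ROIs in two networks of 180, and
#' planted network-level mean Fisher-z coupling of 0.12 (network 1) and
#' 0.03 (network 2), distributed over communities so that the second
#' ("anterior") community couples most strongly with both networks and the
#' first ("anteroventral-tuberal") most weakly.
#'
#' @param rng_seed integer seed.
#' @return a [simulation_config()] object.
#' @examples
#' cfg <- default_study_config()
#' sum(cfg$runs_per_subject$n_runs * cfg$runs_per_subject$n_subjects)  # 295
#' @export
default_study_config <- function(rng_seed = 1L) {
  simulation_config(
    n_subjects = 104L,
    runs_per_subject = data.frame(n_runs = c(3L, 2L, 1L),
                                  n_subjects = c(91L, 9L, 4L)),
    n_timepoints_per_run = 300L,
    community_sizes = c(295L, 234L, 291L, 199L),
    network_sizes = c(180L, 180L),
    within_community_r = 0.40,
    between_community_r = 0.15,
    # rows: cortical networks; columns: hypothalamic communities.
    # Row means are the planted network marginals 0.12 and 0.03.
    network_coupling_z = rbind(c(0.08, 0.16, 0.12, 0.12),
                               c(0.00, 0.07, 0.02, 0.03)),
    subject_coupling_sd = 0.04,
    n_artifact_voxels = 20L,
    artifact_variance_factor = 20,
    noise_sd = 1,
    rng_seed = rng_seed)
}

# solve the ROI mixing weights from the coupling targets.
# S is the population correlation matrix of the community mean signals;
# for each network the weights w satisfy S w = tanh(z), and the residual
# variance 1 - rho' S^-1 rho must be positive (otherwise the requested
# covariance is not positive definite).
coupling_weights <- function(config, coupling_z = config$network_coupling_z) {
  k <- length(config$community_sizes)
  w <- config$within_community_r
  b <- config$between_community_r
  nsd <- config$noise_sd
  n_eff <- community_clean_sizes(config)
  v <- w + nsd^2 * (1 - w) / n_eff          # Var of each community mean
  S <- outer(sqrt(v), sqrt(v), function(a, d) b / (a * d))
  diag(S) <- 1
  rho <- tanh(coupling_z)
  weights <- t(solve(S, t(rho)))
  resid_var <- 1 - rowSums(weights * rho)
  if (any(resid_var <= 0)) {
    stop_("requested network_coupling_z values produce a non-positive-",
          "definite ROI covariance; reduce the coupling targets")
  }
  list(S = S, weights = weights, resid_sd = sqrt(resid_var), var_mean = v)
}

# community sizes after removing artifact voxels (used for the mean-signal
# variance and the ROI construction)
community_clean_sizes <- function(config) {
  gt <- plan_ground_truth(config)
  tab <- table(factor(gt$voxel_community[setdiff(names(gt$voxel_community),
                                                 gt$artifact_voxels)],
                      levels = seq_along(config$community_sizes)))
  pmax(as.integer(tab), 1L)
}

#' Planted ground truth for a configuration
#'
#' Deterministically derives (from `rng_seed`) the quantities that define
#' the study before any signal is drawn: voxel community labels, cortical
#' network labels, the artifact voxel set, per-subject run counts and
#' per-subject RNG seeds.
#'
#' @param config a [simulation_config()].
#' @return a list of class `ground_truth` with elements `voxel_community`
#'   (named integer vector), `cortical_network` (named integer vector),
#'   `artifact_voxels` (character), `subject_runs` (named integer),
#'   `subject_ids`, `voxel_ids`, `roi_ids` and `community_ids`.
#' @export
plan_ground_truth <- function(config) {
  n_vox <- sum(config$community_sizes)
  voxel_ids <- sprintf("V%04d", seq_len(n_vox))
  voxel_community <- setNames(rep(seq_along(config$community_sizes),
                                  config$community_sizes), voxel_ids)
  roi_ids <- sprintf("ROI%03d", seq_len(sum(config$network_sizes)))
  cortical_network <- setNames(rep(seq_along(config$network_sizes),
                                   config$network_sizes), roi_ids)
  subject_ids <- sprintf("sub%03d", seq_len(config$n_subjects))
  subject_runs <- setNames(rep(config$runs_per_subject$n_runs,
                               config$runs_per_subject$n_subjects),
                           subject_ids)
  seeds_and_artifacts <- with_seed(config$rng_seed, {
    art <- if (config$n_artifact_voxels > 0) {
      sort(sample(voxel_ids, config$n_artifact_voxels))
    } else character(0)
    list(artifacts = art,
         subject_seeds = sample.int(2147483646L, config$n_subjects),
         coupling_seed = sample.int(2147483646L, 1))
  })
  structure(
    list(voxel_community = voxel_community,
         cortical_network = cortical_network,
         artifact_voxels = seeds_and_artifacts$artifacts,
         subject_runs = subject_runs,
         subject_ids = subject_ids,
         voxel_ids = voxel_ids,
         roi_ids = roi_ids,
         community_ids = sprintf("HYP%d", seq_along(config$community_sizes)),
         subject_seeds = seeds_and_artifacts$subject_seeds,
         coupling_seed = seeds_and_artifacts$coupling_seed),
    class = "ground_truth")
}

#' Simulate a complete synthetic study
#'
#' Draws every subject's runs under the planted structure of `config`.
#' Voxel signals follow the exchangeable block-covariance model, artifact
#' voxels are replaced by independent high-variance noise, and cortical ROI
#' signals are mixtures of the community mean signals with weights solved
#' from the Fisher-z coupling targets (see [simulation_config()]).  The
#' whole study is reproducible bit for bit given `rng_seed`.
#'
#' Each returned run is a `timeseries_run`: a list with `subject_id`,
#' `run_id`, `signal` (nodes x time matrix with node ids as rownames),
#' `confounds` (time x regressor matrix with fmriprep-style motion column
#' names; pure nuisance plumbing, not mixed into the signal),
#' `sampling_interval`, and for ROI runs `hyp_signal`, the ground-truth
#' community mean signals (communities x time) used to plant the coupling.
#'
#' @param config a [simulation_config()].
#' @param voxel_data generate voxel-level runs? (memory scales with
#'   `sum(community_sizes) * n_timepoints * total runs`).
#' @param roi_data generate cortical ROI runs?
#' @param subjects optional subset of subject indices to generate.
#' @return a list with `voxel_runs`, `roi_runs` (lists of `timeseries_run`,
#'   possibly empty) and `ground_truth`.
#' @examples
#' cfg <- simulation_config(n_subjects = 2,
#'                          runs_per_subject = cbind(2, 2),
#'                          n_timepoints_per_run = 50,
#'                          community_sizes = c(10, 8),
#'                          network_sizes = c(5, 5),
#'                          network_coupling_z = rbind(c(.12, .12), c(.03, .03)))
#' sim <- simulate_study(cfg)
#' dim(sim$voxel_runs[[1]]$signal)  # 18 voxels x 50 timepoints
#' @export
simulate_study <- function(config, voxel_data = TRUE, roi_data = TRUE,
                           subjects = seq_len(config$n_subjects)) {
  stopifnot(inherits(config, "simulation_config"))
  gt <- plan_ground_truth(config)
  voxel_runs <- list()
  roi_runs <- list()
  for (s in subjects) {
    runs <- simulate_subject(config, gt, s, voxel_data = voxel_data,
                             roi_data = roi_data)
    voxel_runs <- c(voxel_runs, runs$voxel_runs)
    roi_runs <- c(roi_runs, runs$roi_runs)
  }
  list(voxel_runs = voxel_runs, roi_runs = roi_runs, ground_truth = gt)
}

#' Simulate one subject's runs
#'
#' @inheritParams simulate_study
#' @param ground_truth the [plan_ground_truth()] of `config` (recomputed if
#'   omitted).
#' @param subject subject index in `1..n_subjects`.
#' @return list with `voxel_runs` and `roi_runs` for that subject.
#' @export
simulate_subject <- function(config, ground_truth = NULL, subject,
                             voxel_data = TRUE, roi_data = TRUE) {
  gt <- ground_truth %||% plan_ground_truth(config)
  k <- length(config$community_sizes)
  n_vox <- length(gt$voxel_ids)
  n_roi <- length(gt$roi_ids)
  tt <- config$n_timepoints_per_run
  w <- config$within_community_r
  b <- config$between_community_r
  wt_g <- sqrt(b)
  wt_f <- sqrt(w - b)
  wt_e <- config$noise_sd * sqrt(1 - w)
  cw <- coupling_weights(config)
  art_idx <- match(gt$artifact_voxels, gt$voxel_ids)
  clean <- lapply(seq_len(k), function(c) {
    setdiff(which(gt$voxel_community == c), art_idx)
  })
  net_of_roi <- gt$cortical_network
  n_runs <- gt$subject_runs[[subject]]
  sid <- gt$subject_ids[[subject]]

  with_seed(gt$subject_seeds[[subject]], {
    # a subject-level shift of the coupling targets (individual differences),
    # constant across that subject's runs
    shift <- rnorm(length(config$network_sizes), 0, config$subject_coupling_sd)
    z_subj <- config$network_coupling_z + shift
    rho_subj <- tanh(z_subj)
    w_subj <- t(solve(cw$S, t(rho_subj)))
    resid_var <- 1 - rowSums(w_subj * rho_subj)
    if (any(resid_var <= 0)) {
      stop_("subject-level coupling shift produced a non-positive-definite ",
            "ROI covariance; reduce subject_coupling_sd")
    }
    cw_subj <- list(weights = w_subj, resid_sd = sqrt(resid_var))
    voxel_runs <- vector("list", n_runs)
    roi_runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      g <- rnorm(tt)
      f <- matrix(rnorm(tt * k), tt, k)
      # time x voxel block-covariance signal
      x <- wt_g * g + wt_f * f[, gt$voxel_community, drop = FALSE] +
        wt_e * matrix(rnorm(tt * n_vox), tt, n_vox)
      if (length(art_idx) > 0) {
        x[, art_idx] <- sqrt(config$artifact_variance_factor) *
          matrix(rnorm(tt * length(art_idx)), tt, length(art_idx))
      }
      # community mean signals (artifact members excluded), standardised by
      # their population SD so the coupling targets are exact
      m <- vapply(seq_len(k), function(c) rowMeans(x[, clean[[c]], drop = FALSE]),
                  numeric(tt))
      u <- sweep(m, 2, sqrt(cw$var_mean), "/")
      run_id <- sprintf("%s_run%d", sid, r)
      confounds <- simulate_confounds(tt)
      if (voxel_data) {
        sig <- t(x)
        rownames(sig) <- gt$voxel_ids
        voxel_runs[[r]] <- new_timeseries_run(sid, run_id, sig, confounds,
                                              config$sampling_interval)
      }
      if (roi_data) {
        eps <- matrix(rnorm(tt * n_roi), tt, n_roi)
        y <- u %*% t(cw_subj$weights[net_of_roi, , drop = FALSE]) +
          sweep(eps, 2, cw_subj$resid_sd[net_of_roi], "*")
        sig <- t(y)
        rownames(sig) <- gt$roi_ids
        hyp <- t(m)
        rownames(hyp) <- gt$community_ids
        run <- new_timeseries_run(sid, run_id, sig, confounds,
                                  config$sampling_interval)
        run$hyp_signal <- hyp
        roi_runs[[r]] <- run
      }
    }
    list(voxel_runs = Filter(Negate(is.null), voxel_runs),
         roi_runs = Filter(Negate(is.null), roi_runs))
  })
}

new_timeseries_run <- function(subject_id, run_id, signal, confounds,
                               sampling_interval) {
  if (!is.null(confounds) && nrow(confounds) != ncol(signal)) {
    stop_("signal and confounds must share the time dimension")
  }
  structure(list(subject_id = subject_id, run_id = run_id, signal = signal,
                 confounds = confounds,
                 sampling_interval = sampling_interval),
            class = "timeseries_run")
}

#' @export
print.timeseries_run <- function(x, ...) {
  cat(sprintf("<timeseries_run> %s: %d nodes x %d timepoints (TR %.3gs, %d confounds)\n",
              x$run_id, nrow(x$signal), ncol(x$signal),
              x$sampling_interval,
              if (is.null(x$confounds)) 0L else ncol(x$confounds)))
  invisible(x)
}

# fmriprep-style motion confounds: smooth random walks plus derivatives.
# These columns are nuisance plumbing for the regression interface; they
# are not mixed into the planted signals.
simulate_confounds <- function(tt) {
  motion <- vapply(seq_len(6), function(i) {
    cumsum(rnorm(tt, sd = 0.02))
  }, numeric(tt))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  deriv <- rbind(0, diff(motion))
  colnames(deriv) <- paste0(colnames(motion), "_derivative1")
  cbind(motion, deriv)
}
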