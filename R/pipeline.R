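#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's parameters with defaults matching the study design:
#' atlas threshold 0.20, kneedle sensitivity 1, 120 s high-pass, 100
#' consensus iterations at resolution 1 with the zero negative-weight
#' policy, k scanned over 2..40, Greenhouse-Geisser correction.
#'
#' @param simulation a [simulation_config()] (simulation mode), or `NULL`
#'   for real-data mode.
#' @param atlas,runs,confounds real-data mode inputs: a probabilistic atlas
#'   NIfTI path, a data.frame of runs (`subject_id`, `run_id`, `path`) and
#'   optionally a parallel vector of confound TSV paths.
#' @param out_dir directory for stage outputs (created if needed).
#' @param atlas_threshold probability threshold for [binarize_atlas()].
#' @param variance_sensitivity kneedle sensitivity for [variance_filter()].
#' @param highpass_cutoff seconds, for [regress_confounds()].
#' @param n_iterations consensus Louvain iterations.
#' @param resolution Louvain resolution.
#' @param negative_policy `"zero"` or `"abs"`.
#' @param k_min,k_max scanned k range for [cluster_cortex()].
#' @param selection `"max"` or `"kneedle"`.
#' @param kmeans_restarts restarts per k.
#' @param correction sphericity correction for [rm_anova()].
#' @param rng_seed master seed for every stage.
#' @param write_volumes also write the simulated runs as NIfTI (off by
#'   default; large).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, atlas = NULL, runs = NULL,
                            confounds = NULL, out_dir = tempfile("hypoparc_"),
                            atlas_threshold = 0.20,
                            variance_sensitivity = 1,
                            highpass_cutoff = 120,
                            n_iterations = 100,
                            resolution = 1,
                            negative_policy = "zero",
                            k_min = 2, k_max = 40,
                            selection = "kneedle",
                            kmeans_restarts = 50,
                            correction = "gg",
                            rng_seed = 1L,
                            write_volumes = FALSE) {
  if (is.null(simulation)) {
    if (is.null(atlas)) stop_("real-data mode requires `atlas` (config field: atlas)")
    if (is.null(runs)) stop_("real-data mode requires `runs` (config field: runs)")
  } else {
    stopifnot(inherits(simulation, "simulation_config"))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full parcellation and coupling pipeline
#'
#' Executes the stages in order -- simulate (or load), variance masking,
#' confound regression, voxel connectivity, group averaging, consensus
#' parcellation, community timeseries extraction, subject 360+K ROI
#' connectivity, profile clustering, coupling table, repeated-measures
#' statistics -- writing every intermediate artifact under
#' `config$out_dir` together with a provenance manifest
#' (`manifest.json`: stage, parameters, seed and md5 per file).  Reruns
#' with an identical config are bitwise-identical for all TSV/JSON outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the key results: the final `partition`,
#'   `stability` table, `networks` assignment, `coupling` table, `anova`,
#'   `posthoc`, `summary`, and `report` (the content of `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, path, params = list()) {
    manifest[[length(manifest) + 1]] <<- manifest_entry(
      stage, path, params, seed = config$rng_seed)
  }

  ## stage 1: data
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    gt <- plan_ground_truth(sim_cfg)
    gt_path <- file.path(config$out_dir, "ground_truth.json")
    write_json(list(voxel_community = as.list(gt$voxel_community),
                    cortical_network = as.list(gt$cortical_network),
                    artifact_voxels = gt$artifact_voxels,
                    subject_runs = as.list(gt$subject_runs)), gt_path)
    note("simulate", gt_path,
         params = list(n_subjects = sim_cfg$n_subjects,
                       rng_seed = sim_cfg$rng_seed))
    mask <- mask_from_ids(gt$voxel_ids)
    subjects <- seq_len(sim_cfg$n_subjects)
    load_subject <- function(s) simulate_subject(sim_cfg, gt, s)
    community_k <- length(sim_cfg$community_sizes)
  } else {
    atlas <- read_volume_nifti(config$atlas)
    mask <- binarize_atlas(atlas, config$atlas_threshold)
    runs_df <- config$runs
    subjects <- unique(runs_df$subject_id)
    load_subject <- function(s) {
      rows <- which(runs_df$subject_id == s)
      list(voxel_runs = lapply(rows, function(i) {
        read_run_nifti(runs_df$path[i], mask, s, runs_df$run_id[i],
                       confounds_path = config$confounds[i])
      }), roi_runs = list())
    }
    gt <- NULL
    community_k <- NA
  }

  ## stages 2-4 per subject: mask, regress, connect
  subject_fcs <- list()
  roi_runs_by_subject <- list()
  for (s in subjects) {
    data_s <- load_subject(s)
    vruns <- lapply(data_s$voxel_runs, regress_confounds,
                    highpass_cutoff = config$highpass_cutoff)
    for (run in vruns) {
      mask <- variance_filter(run, mask,
                              sensitivity = config$variance_sensitivity)
    }
    avail <- availability_matrix(
      mask, vapply(vruns, `[[`, character(1), "run_id"))
    keep <- rowSums(avail) >= 1
    sub_mask_ids <- mask$voxel_ids[keep]
    fc <- subject_connectivity(
      lapply(vruns, function(r) {
        r$signal <- r$signal[sub_mask_ids, , drop = FALSE]; r
      }),
      availability = avail[sub_mask_ids, , drop = FALSE])
    # re-embed on the full voxel set so subjects stay comparable
    full <- matrix(NA_real_, length(mask$voxel_ids), length(mask$voxel_ids),
                   dimnames = list(mask$voxel_ids, mask$voxel_ids))
    full[sub_mask_ids, sub_mask_ids] <- fc$z
    diag(full) <- 0
    subject_fcs[[s]] <- new_connectivity_matrix(mask$voxel_ids, full)
    # keep the confound-regressed voxel runs paired with the ROI runs for
    # community timeseries extraction after the parcellation is known
    roi_runs_by_subject[[s]] <- lapply(seq_along(data_s$roi_runs), function(i) {
      list(roi = data_s$roi_runs[[i]], voxel = vruns[[i]])
    })
  }
  avail_path <- file.path(config$out_dir, "voxel_availability.tsv")
  write_matrix_tsv(mask$availability * 1, avail_path)
  note("mask", avail_path,
       params = list(sensitivity = config$variance_sensitivity))

  ## stage 5: group voxel FC and consensus parcellation
  group_fc <- group_average(subject_fcs, na_action = "keep")
  fc_path <- file.path(config$out_dir, "group_voxel_fc.tsv")
  write_matrix_tsv(group_fc$z, fc_path)
  note("connectome", fc_path,
       params = list(highpass = config$highpass_cutoff))

  cons <- consensus_partition(group_fc, n_iterations = config$n_iterations,
                              resolution = config$resolution,
                              rng_seed = config$rng_seed,
                              negative_policy = config$negative_policy)
  part_path <- file.path(config$out_dir, "voxel_partition.tsv")
  write_partition_tsv(cons$partition, part_path)
  stability <- stability_summary(cons$coassignment, cons$partition)
  stab_path <- file.path(config$out_dir, "stability_table.tsv")
  write_table_tsv(stability, stab_path)
  note("parcellate", part_path,
       params = list(iterations = config$n_iterations,
                     resolution = config$resolution,
                     negative_policy = config$negative_policy))
  note("parcellate", stab_path)

  ## without cortical ROI runs (voxel-only real-data input) the pipeline
  ## ends after the parcellation stage
  if (all(lengths(roi_runs_by_subject) == 0)) {
    report <- list(
      n_voxels = length(mask$voxel_ids),
      n_communities = cons$partition$n_communities,
      community_sizes = as.list(table(cons$partition$assignment)))
    report_path <- file.path(config$out_dir, "report.json")
    write_json(report, report_path)
    note("report", report_path)
    write_json(manifest, file.path(config$out_dir, "manifest.json"))
    return(invisible(list(partition = cons$partition,
                          coassignment = cons$coassignment,
                          stability = stability, report = report,
                          out_dir = config$out_dir, mask = mask,
                          group_fc = group_fc)))
  }

  ## stage 6: subject 360+K ROI connectivity from extracted community series
  n_comm <- cons$partition$n_communities
  comm_ids <- sprintf("HYP%d", seq_len(n_comm))
  labels <- cons$partition$assignment
  roi_fcs <- list()
  for (s in subjects) {
    pairs <- roi_runs_by_subject[[s]]
    if (length(pairs) == 0) next
    runs364 <- lapply(pairs, function(pr) {
      av <- availability_matrix(mask, pr$voxel$run_id)[, 1]
      hyp <- extract_roi_timeseries(pr$voxel, labels,
                                    availability = av[names(labels)],
                                    parcel_ids = comm_ids)
      run <- pr$roi
      run$signal <- rbind(run$signal, hyp$signal)
      run
    })
    roi_fcs[[s]] <- subject_connectivity(runs364)
  }
  group_roi_fc <- group_average(roi_fcs)
  roi_fc_path <- file.path(config$out_dir, "group_roi_fc.tsv")
  write_matrix_tsv(group_roi_fc$z, roi_fc_path)
  note("connectome", roi_fc_path)

  ## stage 7: profile clustering and coupling
  cortical_ids <- setdiff(group_roi_fc$node_ids, comm_ids)
  profiles <- build_profile_matrix(group_roi_fc, cortical_ids, comm_ids)
  networks <- cluster_cortex(profiles, k_min = config$k_min,
                             k_max = min(config$k_max, length(cortical_ids) - 1),
                             selection = config$selection,
                             restarts = config$kmeans_restarts,
                             rng_seed = config$rng_seed)
  net_path <- file.path(config$out_dir, "network_labels.tsv")
  write_table_tsv(data.frame(roi = names(networks$labels),
                             network = unname(networks$labels)), net_path)
  ch_path <- file.path(config$out_dir, "ch_curve.tsv")
  write_table_tsv(data.frame(k = as.integer(names(networks$ch_curve)),
                             calinski_harabasz = unname(networks$ch_curve)),
                  ch_path)
  note("couple", net_path,
       params = list(k_min = config$k_min, k_max = config$k_max,
                     selection = config$selection,
                     restarts = config$kmeans_restarts))
  note("couple", ch_path)

  coupling <- build_coupling_table(roi_fcs, networks, comm_ids)
  coup_path <- file.path(config$out_dir, "coupling_table.tsv")
  write_table_tsv(coupling, coup_path)
  note("couple", coup_path)

  ## stage 8: repeated-measures statistics
  anova <- rm_anova(coupling, correction = config$correction)
  posthoc <- lsd_posthoc(coupling, factor = "cell")
  summary_tab <- cell_summary(coupling)
  write_table_tsv(as.data.frame(anova),
                  file.path(config$out_dir, "anova.tsv"))
  write_table_tsv(posthoc, file.path(config$out_dir, "posthoc_lsd.tsv"))
  write_table_tsv(summary_tab, file.path(config$out_dir, "cell_summary.tsv"))
  note("stats", file.path(config$out_dir, "anova.tsv"),
       params = list(correction = config$correction))
  note("stats", file.path(config$out_dir, "posthoc_lsd.tsv"))
  note("stats", file.path(config$out_dir, "cell_summary.tsv"))

  net_means <- summary_tab[summary_tab$scope == "network", ]
  report <- list(
    n_voxels = length(mask$voxel_ids),
    n_communities = cons$partition$n_communities,
    community_sizes = as.list(table(cons$partition$assignment)),
    n_networks = networks$chosen_k,
    selection_method = networks$selection_method,
    network_mean_z = setNames(as.list(net_means$mean), net_means$network),
    anova = lapply(seq_len(nrow(anova)), function(i) {
      list(effect = anova$effect[i], F = anova$F[i],
           df1 = anova$df1_corr[i], df2 = anova$df2_corr[i],
           epsilon = anova$epsilon[i], p = anova$p[i])
    }))
  report_path <- file.path(config$out_dir, "report.json")
  write_json(report, report_path)
  note("report", report_path)
  write_json(manifest, file.path(config$out_dir, "manifest.json"))

  invisible(list(partition = cons$partition, coassignment = cons$coassignment,
                 stability = stability, networks = networks,
                 coupling = coupling, anova = anova, posthoc = posthoc,
                 summary = summary_tab, report = report,
                 out_dir = config$out_dir, mask = mask,
                 group_fc = group_fc, group_roi_fc = group_roi_fc))
}
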