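#' Binarize a probabilistic atlas into an analysis voxel mask
#'
#' Voxels whose atlas probability is greater than or equal to `threshold`
#' (inclusive) enter the mask.  The canonical use is binarizing a
#' probabilistic hypothalamus atlas at 20% after resampling it to the
#' functional resolution (see [resample_volume()]).
#'
#' @param atlas 3D numeric array (or `RNifti` image) of probabilities in
#'   `[0, 1]`.
#' @param threshold inclusion threshold, strictly between 0 and 1.
#' @return a `voxel_mask`: a list with `voxel_ids` (ordered, of the form
#'   `"v<i>_<j>_<k>"`), `coords` (voxels x 3 integer grid indices,
#'   1-based), and `availability`, a voxels x runs logical matrix that
#'   starts with zero run columns; a voxel is treated as available in any
#'   run that has not been filtered yet.
#' @examples
#' p <- array(seq_len(27) / 27, dim = c(3, 3, 3))
#' length(binarize_atlas(p, 0.5)$voxel_ids)  # 14
#' @export
binarize_atlas <- function(atlas, threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold < 1)) {
    stop_("threshold must lie strictly between 0 and 1")
  }
  arr <- as.array(atlas)
  if (length(dim(arr)) != 3) stop_("atlas must be a 3D volume")
  if (anyNA(arr) || min(arr) < 0 || max(arr) > 1) {
    stop_("atlas probabilities must lie in [0, 1]")
  }
  keep <- which(arr >= threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) stop_("binarized mask is empty at threshold ", threshold)
  ids <- sprintf("v%d_%d_%d", keep[, 1], keep[, 2], keep[, 3])
  new_voxel_mask(ids, coords = keep, dim = dim(arr))
}

new_voxel_mask <- function(voxel_ids, coords = NULL, dim = NULL) {
  if (length(voxel_ids) == 0) stop_("mask must contain at least one voxel")
  if (anyDuplicated(voxel_ids)) stop_("voxel ids must be unique")
  avail <- matrix(logical(0), nrow = length(voxel_ids), ncol = 0,
                  dimnames = list(voxel_ids, NULL))
  structure(list(voxel_ids = voxel_ids, coords = coords, dim = dim,
                 availability = avail),
            class = "voxel_mask")
}

#' Build a voxel mask directly from node ids
#'
#' Convenience constructor for synthetic studies, where the analysis voxel
#' set is the generator's voxel list rather than a thresholded atlas.
#'
#' @param voxel_ids character vector of unique voxel ids.
#' @return a `voxel_mask` (see [binarize_atlas()]).
#' @export
mask_from_ids <- function(voxel_ids) new_voxel_mask(voxel_ids)

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels, availability recorded for %d run(s)\n",
              length(x$voxel_ids), ncol(x$availability)))
  invisible(x)
}

#' Per-run exclusion of high-variance voxels via the kneedle rule
#'
#' Computes the temporal variance of every masked voxel in one run, sorts
#' the variances in decreasing order, locates the knee of the sorted curve
#' with [find_knee()] (decreasing, convex), and marks the voxels whose
#' variance lies strictly above the knee as unavailable *for this run
#' only*.  When no knee is found, no voxel is excluded (conservative
#' default).  This targets ventricle-adjacent voxels whose pulsatile signal
#' dominates their timecourse.
#'
#' @param run a `timeseries_run` covering every masked voxel.
#' @param mask a `voxel_mask`.
#' @param sensitivity kneedle sensitivity (default 1).
#' @param use_confound_residuals compute variances on confound-regressed
#'   signals rather than raw ones (default `FALSE`; exposed because either
#'   convention is defensible).
#' @param highpass_cutoff cutoff (seconds) for the cosine basis when
#'   `use_confound_residuals = TRUE`.
#' @return the mask with an availability column added (or replaced) for
#'   `run$run_id`; other runs' columns are untouched.
#' @export
variance_filter <- function(run, mask, sensitivity = 1,
                            use_confound_residuals = FALSE,
                            highpass_cutoff = 120) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(run, "timeseries_run"))
  missing <- setdiff(mask$voxel_ids, rownames(run$signal))
  if (length(missing) > 0) {
    stop_("run ", run$run_id, " does not cover ", length(missing),
          " masked voxel(s), e.g. ", missing[1])
  }
  if (ncol(run$signal) < 3) stop_("run must have at least 3 timepoints")
  use <- run
  if (use_confound_residuals && !is.null(run$confounds)) {
    use <- regress_confounds(run, highpass_cutoff = highpass_cutoff)
  }
  v <- row_variances(use$signal[mask$voxel_ids, , drop = FALSE])
  ord <- order(v, decreasing = TRUE)
  knee <- find_knee(seq_along(v), v[ord], sensitivity = sensitivity,
                    direction = "decreasing", curvature = "convex")
  available <- rep(TRUE, length(v))
  if (!is.na(knee$knee_index)) {
    available <- v <= v[ord][knee$knee_index]
  }
  set_availability(mask, run$run_id, available)
}

# record one run's availability column in a mask
set_availability <- function(mask, run_id, available) {
  stopifnot(length(available) == length(mask$voxel_ids))
  av <- mask$availability
  if (run_id %in% colnames(av)) {
    av[, run_id] <- available
  } else {
    av <- cbind(av, matrix(available, ncol = 1,
                           dimnames = list(mask$voxel_ids, run_id)))
  }
  mask$availability <- av
  mask
}

#' Availability matrix for a set of runs
#'
#' @param mask a `voxel_mask`.
#' @param run_ids run identifiers; runs never filtered are fully available.
#' @return voxels x runs logical matrix.
#' @export
availability_matrix <- function(mask, run_ids) {
  out <- matrix(TRUE, length(mask$voxel_ids), length(run_ids),
                dimnames = list(mask$voxel_ids, run_ids))
  known <- intersect(run_ids, colnames(mask$availability))
  out[, known] <- mask$availability[, known]
  out
}

#' Resample a 3D volume to a new grid
#'
#' Simple grid-aligned resampling used to bring a probabilistic atlas to
#' the functional voxel size before binarization: `"linear"` (trilinear,
#' for probabilities) or `"nearest"` (for label volumes).  The output grid
#' covers the same field of view; voxel `i` of the new axis is sampled at
#' the continuous input coordinate `(i - 0.5) * old_dim / new_dim + 0.5`.
#'
#' @param vol 3D numeric array.
#' @param new_dim integer triple, the target grid size.
#' @param method `"linear"` or `"nearest"`.
#' @return a 3D array of dimension `new_dim`.
#' @export
resample_volume <- function(vol, new_dim, method = c("linear", "nearest")) {
  method <- match.arg(method)
  vol <- as.array(vol)
  d <- dim(vol)
  if (length(d) != 3 || length(new_dim) != 3) {
    stop_("resample_volume() works on 3D volumes")
  }
  coord <- lapply(1:3, function(a) {
    (seq_len(new_dim[a]) - 0.5) * d[a] / new_dim[a] + 0.5
  })
  grid <- as.matrix(expand.grid(coord[[1]], coord[[2]], coord[[3]]))
  vals <- if (method == "nearest") {
    idx <- pmin(pmax(round(grid), 1), matrix(d, nrow(grid), 3, byrow = TRUE))
    vol[idx]
  } else {
    trilinear_sample(vol, grid)
  }
  array(vals, dim = new_dim)
}

trilinear_sample <- function(vol, grid) {
  d <- dim(vol)
  lo <- pmin(pmax(floor(grid), 1), matrix(d, nrow(grid), 3, byrow = TRUE))
  hi <- pmin(lo + 1, matrix(d, nrow(grid), 3, byrow = TRUE))
  fr <- pmin(pmax(grid - lo, 0), 1)
  out <- numeric(nrow(grid))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) lo[, 1] else hi[, 1]
    iy <- if (cy == 0) lo[, 2] else hi[, 2]
    iz <- if (cz == 0) lo[, 3] else hi[, 3]
    wx <- if (cx == 0) 1 - fr[, 1] else fr[, 1]
    wy <- if (cy == 0) 1 - fr[, 2] else fr[, 2]
    wz <- if (cz == 0) 1 - fr[, 3] else fr[, 3]
    out <- out + wx * wy * wz * vol[cbind(ix, iy, iz)]
  }
  out
}
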