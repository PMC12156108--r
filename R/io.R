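# Readers and writers for the plain-text and NIfTI artifacts the pipeline
# touches.  Matrices and tables travel as TSV, configuration / ground truth
# / manifests as JSON, volumes as NIfTI via RNifti.  Voxel coordinates are
# 0-based grid indices in every writer; world coordinates go through the
# volume's affine.

#' Write / read a numeric matrix as TSV
#'
#' The first column (`node`) carries rownames so round-trips preserve
#' dimnames.
#'
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(node = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a partition as two-column TSV (node_id, community)
#'
#' @param partition a `partition`.
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  write.table(data.frame(node_id = names(partition$assignment),
                         community = unname(partition$assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  setNames(df$community, df$node_id)
}

#' Write a coupling table / confounds / generic data.frame as TSV
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}

#' Write ground truth (or any plain list) as JSON
#' @param x list.
#' @param path file path.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json
#' @export
read_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a 3D or 4D array as NIfTI
#'
#' @param arr numeric array (3D volume or 4D timeseries).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge lengths in mm (default 1.1 isotropic).
#' @export
write_volume_nifti <- function(arr, path, voxel_size = c(1.1, 1.1, 1.1)) {
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[seq_along(voxel_size)] <- voxel_size
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  # plain array out: drop the image attributes RNifti carries along
  structure(as.vector(arr), dim = dim(arr))
}

#' Read a 4D NIfTI run into a `timeseries_run`
#'
#' Extracts the timeseries of the mask's voxels from a 4D volume assumed to
#' be on the same grid as the mask.
#'
#' @param path 4D NIfTI file.
#' @param mask a `voxel_mask` with grid `coords`.
#' @param subject_id,run_id identifiers for the run.
#' @param confounds_path optional TSV of nuisance regressors (time x
#'   regressor, fmriprep-style header).
#' @param sampling_interval repetition time in seconds.
#' @return a `timeseries_run`.
#' @export
read_run_nifti <- function(path, mask, subject_id, run_id,
                           confounds_path = NULL, sampling_interval = 2.34) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4) stop_("expected a 4D NIfTI run: ", path)
  if (is.null(mask$coords)) stop_("mask has no grid coordinates")
  tt <- dim(arr)[4]
  flat <- matrix(arr, prod(dim(arr)[1:3]), tt)
  lin <- mask$coords[, 1] +
    dim(arr)[1] * (mask$coords[, 2] - 1) +
    dim(arr)[1] * dim(arr)[2] * (mask$coords[, 3] - 1)
  sig <- flat[lin, , drop = FALSE]
  rownames(sig) <- mask$voxel_ids
  conf <- if (!is.null(confounds_path)) {
    as.matrix(read_table_tsv(confounds_path))
  } else NULL
  new_timeseries_run(subject_id, run_id, sig, conf, sampling_interval)
}

# one manifest entry per written artifact
manifest_entry <- function(stage, path, params = list(), seed = NULL) {
  list(stage = stage, file = basename(path),
       md5 = unname(tools::md5sum(path)), params = params, seed = seed)
}
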