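#' Regress nuisance confounds and a discrete-cosine high-pass from a run
#'
#' Projects every node's timeseries onto the orthogonal complement of
#' `[intercept | confounds | discrete cosine basis]` and returns the
#' residuals.  The cosine basis contains `floor(2 * T * TR / cutoff)`
#' regressors, i.e. all cosines with period longer than `highpass_cutoff`
#' seconds, emulating a GLM high-pass filter (default cutoff 120 s).
#'
#' @param run a `timeseries_run`.
#' @param highpass_cutoff high-pass cutoff in seconds; `Inf` disables the
#'   cosine basis.
#' @return the run with `signal` replaced by the residuals (orthogonal to
#'   every regressor).
#' @export
regress_confounds <- function(run, highpass_cutoff = 120) {
  stopifnot(inherits(run, "timeseries_run"))
  tt <- ncol(run$signal)
  x <- cbind(intercept = rep(1, tt))
  if (!is.null(run$confounds)) {
    conf <- as.matrix(run$confounds)
    if (nrow(conf) != tt) stop_("signal and confounds must share the time dimension")
    x <- cbind(x, conf)
  }
  if (is.finite(highpass_cutoff)) {
    x <- cbind(x, dct_basis(tt, run$sampling_interval, highpass_cutoff))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[seq.int(qx$rank + 1, ncol(x))]]
    stop_("confound design is rank deficient; collinear column(s): ",
          paste(dropped, collapse = ", "))
  }
  run$signal <- t(qr.resid(qx, t(run$signal)))
  run
}

# discrete cosine high-pass basis: k-th column cos(pi * k * (2t - 1) / (2T)),
# for k = 1 .. floor(2 * T * TR / cutoff)
dct_basis <- function(tt, sampling_interval, cutoff) {
  k_max <- floor(2 * tt * sampling_interval / cutoff)
  if (k_max < 1) return(NULL)
  t_idx <- seq_len(tt)
  basis <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * (2 * t_idx - 1) / (2 * tt))
  }, numeric(tt))
  colnames(basis) <- paste0("cosine", sprintf("%02d", seq_len(k_max)))
  basis
}

#' Fisher z-transform of a correlation coefficient
#'
#' `atanh(r)`, the variance-stabilising transform used before averaging or
#' testing correlations.  Values with `|r| >= 1` (degenerate pairs such as
#' identical timeseries) are clipped to `1 - 1e-7` in magnitude with a
#' warning so downstream matrices stay finite.
#'
#' @param r numeric vector or matrix of correlations.
#' @return `atanh` of the (possibly clipped) input, same shape.
#' @examples
#' fisher_z(0.5)  # 0.549306
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-7
  bad <- is.finite(r) & abs(r) >= 1
  if (any(bad)) {
    warning(sum(bad), " correlation(s) with |r| >= 1 clipped to ", clip,
            call. = FALSE)
    r[bad] <- sign(r[bad]) * clip
  }
  atanh(r)
}

#' Subject-level Fisher-z connectivity under per-run node availability
#'
#' Concatenates a subject's runs and computes, for every node pair, the
#' Pearson correlation over the timepoints of the runs in which *both*
#' nodes are available (pairwise-complete concatenation), then Fisher
#' z-transforms it.  With full availability this equals plain
#' `atanh(cor(t(concatenated signal)))`.
#'
#' @param runs list of `timeseries_run`s for one subject, sharing node ids.
#' @param availability optional nodes x runs logical matrix (columns in run
#'   order or named by `run_id`); defaults to everything available.  Nodes
#'   unavailable in a run contribute nothing for pairs involving them.
#' @return a `connectivity_matrix`: list with `node_ids`, `z` (symmetric
#'   Fisher-z matrix, zero diagonal, `NA` for pairs with no shared
#'   timepoints), and `n_samples` (timepoints used per pair).
#' @export
subject_connectivity <- function(runs, availability = NULL) {
  if (length(runs) < 1) stop_("need at least one run")
  nodes <- rownames(runs[[1]]$signal)
  if (is.null(nodes)) stop_("run signals must have node ids as rownames")
  n <- length(nodes)
  run_ids <- vapply(runs, `[[`, character(1), "run_id")
  if (is.null(availability)) {
    availability <- matrix(TRUE, n, length(runs),
                           dimnames = list(nodes, run_ids))
  } else {
    if (!is.null(colnames(availability))) {
      miss <- setdiff(run_ids, colnames(availability))
      if (length(miss) > 0) {
        extra <- matrix(TRUE, n, length(miss), dimnames = list(NULL, miss))
        availability <- cbind(availability, extra)
      }
      availability <- availability[, run_ids, drop = FALSE]
    }
    availability <- availability[nodes, , drop = FALSE]
  }
  if (!all(rowSums(availability) >= 1)) {
    stop_("every node must be available in at least one run")
  }

  nn <- sxy <- sx <- sxx <- matrix(0, n, n)
  for (r in seq_along(runs)) {
    sig <- runs[[r]]$signal[nodes, , drop = FALSE]
    a <- availability[, r]
    sig[!a, ] <- 0
    tt <- ncol(sig)
    amat <- tcrossprod(a + 0)
    nn <- nn + tt * amat
    sxy <- sxy + tcrossprod(sig)
    sx <- sx + tcrossprod(rowSums(sig), a + 0)
    sxx <- sxx + tcrossprod(rowSums(sig^2), a + 0)
  }
  sy <- t(sx)
  syy <- t(sxx)
  num <- nn * sxy - sx * sy
  den <- sqrt(pmax(nn * sxx - sx^2, 0) * pmax(nn * syy - sy^2, 0))
  rmat <- ifelse(nn > 0 & den > 0, num / den, NA_real_)
  diag(rmat) <- 0
  off <- row(rmat) != col(rmat) & !is.na(rmat)
  z <- rmat
  z[off] <- fisher_z(rmat[off])
  dimnames(z) <- dimnames(nn) <- list(nodes, nodes)
  new_connectivity_matrix(nodes, z, n_samples = nn)
}

new_connectivity_matrix <- function(node_ids, z, n_samples = NULL,
                                    n_subjects = NULL) {
  structure(list(node_ids = node_ids, z = z, n_samples = n_samples,
                 n_subjects = n_subjects),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d Fisher-z (%d missing off-diagonal entries)\n",
              nrow(x$z), ncol(x$z), sum(is.na(x$z))))
  invisible(x)
}

#' Group-average Fisher-z connectivity matrices
#'
#' Entrywise mean of the subject-level Fisher-z values, taken over the
#' subjects in which the entry is non-missing.
#'
#' @param matrices list of `connectivity_matrix` objects sharing node ids.
#' @param na_action `"error"` (default) fails when an off-diagonal entry is
#'   missing in every subject; `"keep"` leaves such entries `NA` (useful
#'   when artifact voxels are excluded from every run).
#' @return a `connectivity_matrix` with an `n_subjects` count matrix.
#' @export
group_average <- function(matrices, na_action = c("error", "keep")) {
  na_action <- match.arg(na_action)
  if (length(matrices) < 1) stop_("need at least one matrix")
  nodes <- matrices[[1]]$node_ids
  for (m in matrices) {
    if (!identical(m$node_ids, nodes)) stop_("matrices must share node_ids")
  }
  total <- count <- matrix(0, length(nodes), length(nodes),
                           dimnames = list(nodes, nodes))
  for (m in matrices) {
    ok <- !is.na(m$z)
    total[ok] <- total[ok] + m$z[ok]
    count <- count + ok
  }
  never <- count == 0 & row(count) != col(count)
  if (any(never) && na_action == "error") {
    stop_(sum(never), " entrie(s) are missing in every subject; ",
          "use na_action = \"keep\" to retain them as NA")
  }
  avg <- ifelse(count > 0, total / pmax(count, 1), NA_real_)
  diag(avg) <- 0
  new_connectivity_matrix(nodes, avg, n_subjects = count)
}

#' Extract parcel-mean timeseries from a run
#'
#' For each parcel, the unweighted mean of its member nodes' signals at
#' every timepoint; member nodes marked unavailable for this run are
#' excluded from the mean (availability-respecting extraction for
#' hypothalamic communities).
#'
#' @param run a `timeseries_run`.
#' @param labels named vector mapping node ids (a subset of the run's
#'   rownames) to parcel labels.
#' @param availability optional named logical vector over the labelled
#'   nodes for this run.
#' @param parcel_ids optional character names for the output parcels (in
#'   `sort(unique(labels))` order); defaults to the label values.
#' @return a `timeseries_run` whose `signal` is parcels x time.
#' @export
extract_roi_timeseries <- function(run, labels, availability = NULL,
                                   parcel_ids = NULL) {
  stopifnot(inherits(run, "timeseries_run"))
  nodes <- names(labels)
  if (is.null(nodes)) stop_("labels must be a named vector of node ids")
  miss <- setdiff(nodes, rownames(run$signal))
  if (length(miss) > 0) stop_("run does not cover labelled node(s): ", miss[1])
  keep <- rep(TRUE, length(nodes))
  if (!is.null(availability)) keep <- availability[nodes]
  levels <- sort(unique(labels))
  if (is.null(parcel_ids)) parcel_ids <- as.character(levels)
  sig <- vapply(seq_along(levels), function(i) {
    members <- nodes[labels == levels[i] & keep]
    if (length(members) == 0) {
      stop_("parcel ", levels[i], " has no available member in run ",
            run$run_id)
    }
    colMeans(run$signal[members, , drop = FALSE])
  }, numeric(ncol(run$signal)))
  out <- run
  out$signal <- t(sig)
  rownames(out$signal) <- parcel_ids
  out
}
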