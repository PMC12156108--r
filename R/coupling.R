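#' Extract the cortical-by-community connectivity profile matrix
#'
#' Pulls the cortical x hypothalamic-community sub-block out of a
#' (typically group-averaged) Fisher-z connectivity matrix; with the study
#' dimensions this is the 360 x 4 profile matrix that cortical ROIs are
#' clustered on.
#'
#' @param fc a `connectivity_matrix` containing both id sets.
#' @param cortical_ids row ids (cortical ROIs).
#' @param community_ids column ids (hypothalamic communities).
#' @return numeric matrix (cortical x community) with dimnames.
#' @export
build_profile_matrix <- function(fc, cortical_ids, community_ids) {
  stopifnot(inherits(fc, "connectivity_matrix"))
  miss <- setdiff(c(cortical_ids, community_ids), fc$node_ids)
  if (length(miss) > 0) stop_("ids absent from the connectivity matrix: ", miss[1])
  profile <- fc$z[cortical_ids, community_ids, drop = FALSE]
  if (anyNA(profile)) {
    stop_("profile matrix has missing entries after group averaging")
  }
  profile
}

#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between- to within-cluster dispersion, each normalised by its
#' degrees of freedom:
#' `CH = [B / (k - 1)] / [W / (n - k)]`, with `B` and `W` the traces of the
#' between- and within-cluster scatter matrices.  Larger favours the
#' clustering.
#'
#' @param x observations x features matrix.
#' @param labels cluster label per row (>= 2 non-empty clusters, `k < n`).
#' @return the index value (`Inf` with a warning if the within-dispersion
#'   is exactly zero).
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' calinski_harabasz(pts, c(1, 1, 2, 2))  # 200
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(labels) != n) stop_("one label per observation required")
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2) stop_("need at least 2 clusters")
  if (k >= n) stop_("need k < n (every cluster with residual df)")
  centroids <- rowsum(x, f) / as.vector(table(f))
  grand <- colMeans(x)
  sizes <- as.vector(table(f))
  between <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
  within <- sum((x - centroids[as.integer(f), , drop = FALSE])^2)
  if (within == 0) {
    warning("zero within-cluster dispersion; index is infinite", call. = FALSE)
    return(Inf)
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Cluster cortical ROIs by their hypothalamic connectivity profiles
#'
#' Runs seeded multi-restart k-means for every `k` in `k_min:k_max` on the
#' profile matrix, records the Calinski-Harabasz index per `k`, and picks
#' the number of clusters either at the kneedle elbow of the
#' index-versus-k curve (`selection = "kneedle"`, the default) or at the
#' maximum of the index (`selection = "max"`).
#'
#' For the elbow rule the curve is treated as decreasing-concave (its
#' direction is auto-detected): a qualifying knee then marks the last `k`
#' before the index starts dropping steeply.  The index of a
#' planted-cluster profile matrix typically peaks at the planted `k` and
#' decays roughly hyperbolically from its first scanned point; such a
#' curve has no concave knee, and the selection falls back to the maximum
#' rule -- so both rules recover the planted count, and the two selection
#' conventions in circulation for this analysis agree.  The fallback is
#' recorded in `selection_method`.
#'
#' @param profiles cortical x community profile matrix (see
#'   [build_profile_matrix()]).
#' @param k_min,k_max scanned range of cluster counts (default 2 to 40;
#'   `k_max` must be smaller than the number of rows).
#' @param selection `"kneedle"` (default) or `"max"`.
#' @param restarts k-means restarts per `k` (default 50; the best
#'   within-cluster sum of squares is kept).
#' @param rng_seed seed for the k-means starts.
#' @param sensitivity kneedle sensitivity when `selection = "kneedle"`.
#' @return a `network_assignment`: list with `labels` (named integer vector
#'   over cortical ROIs, canonicalised by decreasing cluster size),
#'   `chosen_k`, `ch_curve` (named numeric, index per k),
#'   `selection_method`, and `labels_by_k` (matrix of labels for every
#'   scanned k).
#' @export
cluster_cortex <- function(profiles, k_min = 2, k_max = 40,
                           selection = c("kneedle", "max"),
                           restarts = 50, rng_seed = 1L, sensitivity = 1) {
  selection <- match.arg(selection)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (!is_count(k_min, min = 2) || !is_count(k_max, min = k_min)) {
    stop_("need 2 <= k_min <= k_max")
  }
  if (k_max >= n) stop_("k_max must be smaller than the number of ROIs")
  if (all(apply(profiles, 2, function(col) length(unique(col)) == 1))) {
    stop_("degenerate profiles: all rows identical")
  }
  ks <- k_min:k_max
  ch <- setNames(numeric(length(ks)), ks)
  labels_by_k <- matrix(NA_integer_, n, length(ks),
                        dimnames = list(rownames(profiles), ks))
  with_seed(rng_seed, {
    for (i in seq_along(ks)) {
      km <- suppressWarnings(
        kmeans(profiles, centers = ks[i], nstart = restarts, iter.max = 100))
      ch[i] <- calinski_harabasz(profiles, km$cluster)
      labels_by_k[, i] <- km$cluster
    }
  })
  chosen_k <- ks[which.max(ch)]
  used <- "max"
  if (selection == "kneedle") {
    knee <- find_knee(ks, ch, sensitivity = sensitivity,
                      curvature = "concave")
    if (!is.na(knee$knee_index)) {
      chosen_k <- ks[knee$knee_index]
      used <- "kneedle"
    } else {
      used <- "max (no concave knee; fallback)"
    }
  }
  raw <- labels_by_k[, as.character(chosen_k)]
  labels <- setNames(canonicalize_labels(raw), rownames(profiles))
  structure(list(labels = labels, chosen_k = chosen_k, ch_curve = ch,
                 selection_method = used, labels_by_k = labels_by_k),
            class = "network_assignment")
}

#' @export
print.network_assignment <- function(x, ...) {
  cat(sprintf("<network_assignment> %d ROIs in %d networks (selection: %s)\n",
              length(x$labels), x$chosen_k, x$selection_method))
  invisible(x)
}

#' Subject-level network-by-community coupling table
#'
#' For every subject and every (cortical network, hypothalamic community)
#' cell, the mean Fisher-z over the network's cortical ROIs -- the quantity
#' entering the repeated-measures ANOVA.
#'
#' @param subject_fcs named list of subject-level `connectivity_matrix`
#'   objects over the shared 360+K node set (names are subject ids).
#' @param networks a `network_assignment` (or named integer vector) over
#'   the cortical ROIs.
#' @param community_ids ids of the community nodes inside each subject
#'   matrix.
#' @return a `coupling_table`: data.frame with columns `subject`,
#'   `network`, `community`, `mean_z`; every subject contributes every
#'   cell.
#' @export
build_coupling_table <- function(subject_fcs, networks, community_ids) {
  labels <- if (inherits(networks, "network_assignment")) networks$labels
            else networks
  roi_ids <- names(labels)
  if (is.null(names(subject_fcs))) {
    names(subject_fcs) <- sprintf("sub%03d", seq_along(subject_fcs))
  }
  rows <- lapply(names(subject_fcs), function(s) {
    fc <- subject_fcs[[s]]
    block <- build_profile_matrix(fc, roi_ids, community_ids)
    agg <- rowsum(block, labels) / as.vector(table(labels))
    data.frame(subject = s,
               network = rep(rownames(agg), times = ncol(agg)),
               community = rep(colnames(block), each = nrow(agg)),
               mean_z = as.vector(agg))
  })
  out <- do.call(rbind, rows)
  out$network <- paste0("N", out$network)
  class(out) <- c("coupling_table", "data.frame")
  out
}
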