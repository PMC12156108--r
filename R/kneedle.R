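#' Locate the knee/elbow point of a curve (kneedle algorithm)
#'
#' Implements the kneedle knee-point detector: the curve is min-max
#' normalised, transformed to a concave increasing curve according to its
#' direction and curvature, and the knee is declared at the first local
#' maximum of the difference curve `y - x` whose following values drop
#' below a sensitivity-dependent threshold before the next local maximum.
#'
#' The detector is used twice in the parcellation workflow: to threshold
#' sorted voxel temporal variances (excluding ventricle-like artifact
#' voxels run by run, see [variance_filter()]) and to pick the number of
#' cortical clusters from a Calinski-Harabasz curve (see
#' [cluster_cortex()]).
#'
#' @param x numeric vector of strictly ordered x values (length >= 3).
#' @param y numeric vector of curve values, same length as `x`.
#' @param sensitivity positive sensitivity `S`; larger values are more
#'   conservative (fewer knees).  The offline default recommended for the
#'   algorithm is 1.
#' @param direction `"auto"` (default), `"increasing"` or `"decreasing"`.
#'   Auto-detection uses the sign of the endpoint-to-endpoint slope.
#' @param curvature `"auto"` (default), `"concave"` or `"convex"`.
#'   Auto-detection compares the normalised curve with the chord joining
#'   its endpoints.
#' @param smooth_window optional odd integer; if given, `y` is smoothed
#'   with a centred running mean of that width before detection.  No
#'   smoothing is applied by default (sorted variance curves are already
#'   monotone).
#'
#' @return an object of class `knee_result`: a list with `knee_index` and
#'   `knee_x` (`NA` when no knee qualifies), `knee_y`, the sensitivity,
#'   the (possibly auto-detected) `direction` and `curvature`, and
#'   `candidates`, the indices of all qualifying knees in curve order.
#'
#' @examples
#' x <- seq(0.1, 1, length.out = 200)
#' find_knee(x, -1 / x)$knee_x   # about 0.316
#' find_knee(1:10, 1:10)         # straight line: no knee
#' @export
find_knee <- function(x, y, sensitivity = 1,
                      direction = c("auto", "increasing", "decreasing"),
                      curvature = c("auto", "concave", "convex"),
                      smooth_window = NULL) {
  direction <- match.arg(direction)
  curvature <- match.arg(curvature)
  n <- length(x)
  if (n < 3) stop_("find_knee() needs a curve of at least 3 points")
  if (length(y) != n) stop_("x and y must have equal length")
  if (is.unsorted(x, strictly = TRUE)) stop_("x must be strictly increasing")
  if (!is.finite(sensitivity) || sensitivity <= 0) {
    stop_("sensitivity must be a positive number")
  }
  if (!is.null(smooth_window)) {
    y <- running_mean(y, smooth_window)
  }

  no_knee <- structure(
    list(knee_index = NA_integer_, knee_x = NA_real_, knee_y = NA_real_,
         sensitivity = sensitivity, direction = direction,
         curvature = curvature, candidates = integer(0)),
    class = "knee_result")

  if (diff(range(y)) == 0 || diff(range(x)) == 0) return(no_knee)
  xn <- (x - min(x)) / diff(range(x))
  yn <- (y - min(y)) / diff(range(y))

  if (direction == "auto") {
    direction <- if (yn[n] >= yn[1]) "increasing" else "decreasing"
  }
  if (curvature == "auto") {
    # chord from the first to the last normalised point
    chord <- yn[1] + (yn[n] - yn[1]) * (xn - xn[1]) / (xn[n] - xn[1])
    curvature <- if (mean(yn - chord) >= 0) "concave" else "convex"
  }

  # transform to a concave increasing curve; a vertical flip turns convex
  # into concave, and a horizontal flip (index reversal) turns decreasing
  # into increasing
  yt <- if (curvature == "convex") 1 - yn else yn
  # after the vertical flip a convex decreasing curve is already concave
  # increasing; the remaining decreasing cases need the index reversal
  reversed <- (direction == "decreasing" && curvature == "concave") ||
    (direction == "increasing" && curvature == "convex")
  if (reversed) {
    yt <- rev(yt)
    xt <- rev(1 - xn)
  } else {
    xt <- xn
  }

  d <- yt - xt
  # interior local maxima/minima of the difference curve
  rising <- d[-1] > d[-n]
  maxima <- which(c(FALSE, rising) & c(d[-n] >= d[-1], FALSE))
  if (length(maxima) == 0) return(no_knee)

  threshold_drop <- sensitivity * mean(diff(xt))
  winners <- integer(0)
  for (lm in maxima) {
    thr <- d[lm] - threshold_drop
    # scan until the next local maximum (a local minimum resets nothing:
    # the difference values simply have to fall below the threshold first)
    horizon <- min(c(maxima[maxima > lm], n + 1L)) - 1L
    if (horizon <= lm) next
    j <- seq.int(lm + 1L, horizon)
    if (any(d[j] < thr)) winners <- c(winners, lm)
  }
  if (length(winners) == 0) return(no_knee)

  orig <- if (reversed) n + 1L - winners else winners
  knee <- orig[1]
  structure(
    list(knee_index = knee, knee_x = x[knee], knee_y = y[knee],
         sensitivity = sensitivity, direction = direction,
         curvature = curvature, candidates = sort(orig)),
    class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  if (is.na(x$knee_index)) {
    cat("<knee_result> no knee detected (S =", x$sensitivity, ")\n")
  } else {
    cat(sprintf("<knee_result> knee at index %d (x = %.6g, y = %.6g), S = %g, %s/%s\n",
                x$knee_index, x$knee_x, x$knee_y, x$sensitivity,
                x$direction, x$curvature))
  }
  invisible(x)
}

# centred running mean with shrinking windows at the edges
running_mean <- function(y, window) {
  if (!is_count(window, min = 1) || window %% 2 == 0) {
    stop_("smooth_window must be a positive odd integer")
  }
  h <- (window - 1) / 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
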