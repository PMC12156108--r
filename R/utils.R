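# internal helpers shared across modules

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded routines (Louvain sweeps, k-means restarts, simulation) do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# derive a valid 32-bit seed from a base seed and an offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

# fast per-row variance of a matrix (rows = variables, cols = observations)
row_variances <- function(m) {
  n <- ncol(m)
  if (n < 2) stop_("need at least 2 timepoints to compute a variance")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# canonical community labels: 1..K in order of decreasing size, ties broken
# by the smallest member position in `order_by` (defaults to node order)
canonicalize_labels <- function(labels) {
  sizes <- table(labels)
  first_member <- vapply(names(sizes), function(l) min(which(labels == l)),
                         integer(1))
  ord <- order(-as.integer(sizes), first_member)
  remap <- setNames(seq_along(ord), names(sizes)[ord])
  unname(remap[as.character(labels)])
}
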