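#' Two-way repeated-measures ANOVA on the coupling table
#'
#' Standard two-way within-subject decomposition of the network x community
#' coupling means: each effect (network, community, interaction) is tested
#' against its own subject-by-effect error term, and its degrees of freedom
#' are multiplied by a sphericity epsilon -- Greenhouse-Geisser by default,
#' Huynh-Feldt optionally -- computed from the covariance matrix of the
#' effect's orthonormal within-subject contrasts.  A two-level effect has
#' epsilon exactly 1.
#'
#' @param coupling a `coupling_table` (see [build_coupling_table()]); the
#'   design must be complete (every subject in every cell exactly once).
#' @param correction `"gg"` (Greenhouse-Geisser, default), `"hf"`
#'   (Huynh-Feldt) or `"none"`.
#' @return an `rm_anova` object: a data.frame with one row per effect
#'   (`network`, `community`, `network:community`) and columns `SS`,
#'   `SS_error`, `df1`, `df2`, `epsilon`, `df1_corr`, `df2_corr`, `F`, `p`;
#'   the subject-cell array and cell means/SDs are attached as attributes.
#' @export
rm_anova <- function(coupling, correction = c("gg", "hf", "none")) {
  correction <- match.arg(correction)
  y <- coupling_array(coupling)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2) stop_("need at least 2 subjects")
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_subj <- a * b * sum((m_s - grand)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_abs <- ss_total - ss_a - ss_b - ss_ab - ss_subj - ss_as - ss_bs

  effects <- data.frame(
    effect = c("network", "community", "network:community"),
    SS = c(ss_a, ss_b, ss_ab),
    SS_error = c(ss_as, ss_bs, ss_abs),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    stringsAsFactors = FALSE)

  # orthonormal within-subject contrast scores per effect
  ca <- orthonormal_contrasts(a)
  cb <- orthonormal_contrasts(b)
  ones_a <- matrix(1 / a, 1, a)
  ones_b <- matrix(1 / b, 1, b)
  flat <- matrix(y, n, a * b)            # column order: (a, b) pairs, a fastest
  m_eff <- list(kronecker(ones_b, ca),   # network
                kronecker(cb, ones_a),   # community
                kronecker(cb, ca))       # interaction
  eps <- vapply(seq_len(3), function(i) {
    d <- flat %*% t(m_eff[[i]])
    sphericity_epsilon(d, correction)
  }, numeric(1))

  effects$epsilon <- eps
  effects$df1_corr <- effects$df1 * eps
  effects$df2_corr <- effects$df2 * eps
  ms_effect <- effects$SS / effects$df1
  ms_error <- effects$SS_error / effects$df2
  effects$F <- ms_effect / ms_error
  # fully degenerate effects (no effect variance and no error variance,
  # e.g. identical cell values per subject) are reported as F = 0
  tiny <- 1e-12 * (ss_total / (n * a * b) + .Machine$double.eps)
  degenerate <- ms_effect <= tiny & ms_error <= tiny
  effects$F[degenerate] <- 0
  effects$p <- pf(effects$F, effects$df1_corr, effects$df2_corr,
                  lower.tail = FALSE)

  attr(effects, "cells") <- y
  attr(effects, "ss_subject") <- ss_subj
  attr(effects, "ss_total") <- ss_total
  attr(effects, "correction") <- correction
  class(effects) <- c("rm_anova", "data.frame")
  effects
}

# subjects x networks x communities array from the long coupling table
coupling_array <- function(coupling) {
  req <- c("subject", "network", "community", "mean_z")
  if (!all(req %in% names(coupling))) {
    stop_("coupling table needs columns ", paste(req, collapse = ", "))
  }
  subs <- sort(unique(coupling$subject))
  nets <- sort(unique(coupling$network))
  comms <- sort(unique(coupling$community))
  y <- array(NA_real_, dim = c(length(subs), length(nets), length(comms)),
             dimnames = list(subs, nets, comms))
  idx <- cbind(match(coupling$subject, subs),
               match(coupling$network, nets),
               match(coupling$community, comms))
  if (anyDuplicated(idx) > 0) stop_("duplicate (subject, network, community) rows")
  y[idx] <- coupling$mean_z
  if (anyNA(y)) {
    missing <- which(is.na(y), arr.ind = TRUE)
    stop_("incomplete within-subject design; missing cell(s) e.g. subject ",
          subs[missing[1, 1]], ", network ", nets[missing[1, 2]],
          ", community ", comms[missing[1, 3]])
  }
  y
}

# orthonormal contrasts spanning the deviation space of p levels
orthonormal_contrasts <- function(p) {
  if (p == 1) return(matrix(0, 0, 1))
  h <- stats::contr.helmert(p)
  t(sweep(h, 2, sqrt(colSums(h^2)), "/"))
}

# epsilon from the covariance of the orthonormal contrast scores d (n x q):
# GG = tr(S)^2 / (q * tr(S^2)); HF is the usual df-adjusted rescaling of GG
sphericity_epsilon <- function(d, correction) {
  q <- ncol(d)
  if (q <= 1 || correction == "none") return(1)
  s <- cov(d)
  if (sum(diag(s)) <= .Machine$double.eps) return(1)  # no contrast variance
  gg <- sum(diag(s))^2 / (q * sum(s * s))
  if (correction == "gg") return(gg)
  n <- nrow(d)
  hf <- (n * q * gg - 2) / (q * (n - 1 - q * gg))
  min(1, hf)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", attr(x, "correction"),
      " correction)\n", sep = "")
  df <- as.data.frame(x)
  df$F <- round(df$F, 2)
  df$epsilon <- round(df$epsilon, 3)
  df$df1_corr <- round(df$df1_corr, 2)
  df$df2_corr <- round(df$df2_corr, 2)
  df$p <- signif(df$p, 3)
  print(df[, c("effect", "F", "df1_corr", "df2_corr", "epsilon", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Fisher's LSD post-hoc pairwise comparisons
#'
#' Paired t-tests between all level pairs of a within-subject factor on the
#' subject-level cell means, with unadjusted p values (Fisher's LSD applies
#' no multiplicity correction).  `factor = "cell"` compares all
#' network-by-community cells pairwise.
#'
#' @param coupling a `coupling_table`.
#' @param factor `"network"`, `"community"` or `"cell"`.
#' @return a `data.frame` with one row per unordered level pair:
#'   `level1`, `level2`, `mean_diff` (level1 - level2), `t`, `df`, `p`,
#'   `significant` (at .05).  A pair of identical conditions has
#'   `mean_diff = 0`, `t = 0` and `p = 1` (the zero-variance boundary is
#'   treated as "no evidence of a difference").
#' @export
lsd_posthoc <- function(coupling, factor = c("network", "community", "cell")) {
  factor <- match.arg(factor)
  y <- coupling_array(coupling)
  n <- dim(y)[1]
  if (n < 2) stop_("need at least 2 subjects")
  scores <- switch(factor,
    network = apply(y, c(1, 2), mean),
    community = apply(y, c(1, 3), mean),
    cell = {
      m <- matrix(y, n, dim(y)[2] * dim(y)[3])
      colnames(m) <- as.vector(outer(dimnames(y)[[2]], dimnames(y)[[3]],
                                     paste, sep = ":"))
      m
    })
  pairs <- combn(colnames(scores), 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- scores[, pr[1]] - scores[, pr[2]]
    md <- mean(d)
    sdd <- sd(d)
    if (sdd == 0) {
      tval <- if (md == 0) 0 else sign(md) * Inf
    } else {
      tval <- md / (sdd / sqrt(n))
    }
    p <- 2 * pt(-abs(tval), df = n - 1)
    data.frame(level1 = pr[1], level2 = pr[2], mean_diff = md, t = tval,
               df = n - 1, p = p, significant = p < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell and marginal summaries of the coupling table
#'
#' Across-subject mean, SD and t-based 95% confidence interval for every
#' network-by-community cell and for the network and community marginals.
#'
#' @param coupling a `coupling_table`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with columns `scope` (`"cell"`, `"network"`,
#'   `"community"`), `network`, `community`, `n`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`.
#' @export
cell_summary <- function(coupling, conf_level = 0.95) {
  y <- coupling_array(coupling)
  n <- dim(y)[1]
  if (n < 2) stop_("need at least 2 subjects")
  summarize <- function(v) {
    m <- mean(v); s <- sd(v)
    half <- qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
    c(mean = m, sd = s, lo = m - half, hi = m + half)
  }
  rows <- list()
  for (a in dimnames(y)[[2]]) for (b in dimnames(y)[[3]]) {
    s <- summarize(y[, a, b])
    rows[[length(rows) + 1]] <- data.frame(
      scope = "cell", network = a, community = b, n = n,
      mean = s["mean"], sd = s["sd"], ci_lower = s["lo"], ci_upper = s["hi"])
  }
  for (a in dimnames(y)[[2]]) {
    s <- summarize(apply(y[, a, , drop = FALSE], 1, mean))
    rows[[length(rows) + 1]] <- data.frame(
      scope = "network", network = a, community = NA, n = n,
      mean = s["mean"], sd = s["sd"], ci_lower = s["lo"], ci_upper = s["hi"])
  }
  for (b in dimnames(y)[[3]]) {
    s <- summarize(apply(y[, , b, drop = FALSE], 1, mean))
    rows[[length(rows) + 1]] <- data.frame(
      scope = "community", network = NA, community = b, n = n,
      mean = s["mean"], sd = s["sd"], ci_lower = s["lo"], ci_upper = s["hi"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
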