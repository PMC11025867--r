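# Per-contrast differential expression: an empirical-Bayes moderated
# t-statistic with variance shrinkage, an exact rank-sum alternative, a
# Welch t engine, BH adjustment and threshold filtering.
#
# log2FC is always the difference of group means of log2 values (second
# factor level minus first), matching the array-analysis convention.

de_table <- function(feature, log2FC, stat, p, contrast = NA_character_) {
  if (is.null(feature)) feature <- sprintf("feature_%d", seq_along(log2FC))
  data.frame(
    feature = feature,
    log2FC = log2FC,
    stat = stat,
    p = p,
    fdr = bh_adjust(p),
    direction = ifelse(log2FC < 0, "down", "up"),
    contrast = contrast,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

check_two_groups <- function(matrix, groups, min_per_group = 2L) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < min_per_group)) {
    stop("each group needs at least ", min_per_group, " samples")
  }
  if (ncol(matrix) != length(groups)) {
    stop("length(groups) must equal ncol(matrix)")
  }
  groups
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR:
#' `fdr_i = min over j with rank >= rank(i) of m * p_(j) / j`, capped at
#' 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' log2-CPM normalization of a count matrix
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)` with `libsize` the column
#' sum, the standard counts-per-million transform with a 0.5 pseudo-count.
#'
#' @param counts Non-negative integer matrix (features x samples).
#' @return Matrix of log2-CPM values with the same dimnames.
#' @export
normalize_counts <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("column sums must be > 0")
  log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
}

# Inverse of the trigamma function by Newton iteration (monotone,
# convex in 1/x; standard closed-form start).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:100) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# Moment-matching fit of a scaled-F prior to observed residual variances:
# log s^2 follows (log-scale) a shifted log-F; matching mean and variance
# of log s^2 gives the prior df d0 and prior variance s0^2 via
# digamma/trigamma identities.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) return(NULL)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # variances more concentrated than chi-square sampling noise alone:
    # infinite prior df, all features share s0^2
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  }
  df_prior <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Per-feature two-group comparison on log2-scale data.  The residual
#' variance of each feature (pooled, `n - 2` df) is shrunk towards a
#' prior fitted to all features by moment matching of `log s^2` to a
#' scaled-F distribution: `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`.
#' The moderated t `log2FC / (s_tilde * sqrt(1/n1 + 1/n2))` is referred
#' to a t distribution with `d0 + d` degrees of freedom.
#'
#' @param matrix Numeric matrix (features x samples) on log2 scale.
#' @param groups Two-level factor (or coercible); `log2FC` is the mean of
#'   the second level minus the mean of the first.
#' @param contrast Optional contrast label stored in the result.
#' @param shrink If `FALSE`, skip shrinkage (prior df forced to 0): the
#'   statistic reduces to the ordinary pooled-variance two-sample t.
#' @return A `DETable` data.frame: `feature`, `log2FC`, `stat`, `p`,
#'   `fdr` (BH), `direction` (`up`/`down`; zero log2FC is `up` by
#'   convention), `contrast`.
#' @export
moderated_t <- function(matrix, groups, contrast = NA_character_,
                        shrink = TRUE) {
  groups <- check_two_groups(matrix, groups)
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  x1 <- matrix[, groups == g1, drop = FALSE]
  x2 <- matrix[, groups == g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m2 - m1
  df <- n1 + n2 - 2
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / df

  prior <- if (shrink) fit_variance_prior(s2, df) else list(df_prior = 0,
                                                           s2_prior = 0)
  if (is.null(prior)) {
    warning("variance prior fit degenerate (constant matrix?); ",
            "falling back to ordinary t")
    prior <- list(df_prior = 0, s2_prior = 0)
  }
  if (is.infinite(prior$df_prior)) {
    s2_tilde <- rep(prior$s2_prior, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (prior$df_prior * prior$s2_prior + df * s2) /
      (prior$df_prior + df)
    df_total <- prior$df_prior + df
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_stat <- lfc / se
  t_stat[lfc == 0] <- 0              # 0/0 for exactly equal groups
  t_stat[lfc != 0 & se == 0] <- sign(lfc[lfc != 0 & se == 0]) * Inf
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  de_table(rownames(matrix), lfc, t_stat, p, contrast)
}

#' Two-group rank-sum (Mann-Whitney) test per feature
#'
#' Exact two-sided p for `min(n1, n2) <= 8` without ties; otherwise the
#' normal approximation with continuity correction and tie-corrected
#' variance (midranks).  `log2FC` remains the difference of group means.
#'
#' @inheritParams moderated_t
#' @return A `DETable` data.frame (statistic is the Mann-Whitney W of the
#'   second group versus the first).
#' @export
rank_sum_test <- function(matrix, groups, contrast = NA_character_) {
  groups <- check_two_groups(matrix, groups, min_per_group = 1L)
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  res <- apply(matrix, 1L, function(x) {
    exact <- min(sum(i1), sum(i2)) <= 8L && !anyDuplicated(x)
    wt <- suppressWarnings(
      stats::wilcox.test(x[i2], x[i1], exact = exact, correct = TRUE)
    )
    c(stat = unname(wt$statistic), p = wt$p.value)
  })
  lfc <- rowMeans(matrix[, i2, drop = FALSE]) -
    rowMeans(matrix[, i1, drop = FALSE])
  p <- pmin(res["p", ], 1)
  de_table(rownames(matrix), lfc, res["stat", ], p, contrast)
}

#' Welch two-sample t-test per feature
#'
#' Unequal-variance t with Satterthwaite degrees of freedom; `log2FC` is
#' the difference of group means as elsewhere.
#'
#' @inheritParams moderated_t
#' @return A `DETable` data.frame.
#' @export
welch_t_test <- function(matrix, groups, contrast = NA_character_) {
  groups <- check_two_groups(matrix, groups)
  g1 <- levels(groups)[1]
  g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  res <- apply(matrix, 1L, function(x) {
    if (stats::sd(x[i1]) == 0 && stats::sd(x[i2]) == 0) {
      # degenerate: no within-group variance
      d <- mean(x[i2]) - mean(x[i1])
      return(c(stat = if (d == 0) 0 else sign(d) * Inf,
               p = if (d == 0) 1 else 0))
    }
    tt <- stats::t.test(x[i2], x[i1], var.equal = FALSE)
    c(stat = unname(tt$statistic), p = tt$p.value)
  })
  lfc <- rowMeans(matrix[, i2, drop = FALSE]) -
    rowMeans(matrix[, i1, drop = FALSE])
  de_table(rownames(matrix), lfc, res["stat", ], res["p", ], contrast)
}

#' Differential-expression thresholds
#'
#' @param lfc_min Minimum absolute log2 fold change (non-strict: features
#'   with `|log2FC| >= lfc_min` pass).
#' @param alpha Significance cut-off (strict: `p < alpha` or
#'   `fdr < alpha`).
#' @param use_fdr If `TRUE` the BH-adjusted values are thresholded,
#'   otherwise the raw p-values.
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(lfc_min = 1, alpha = 0.05, use_fdr = TRUE) {
  stopifnot(lfc_min >= 0, alpha > 0, alpha < 1)
  structure(list(lfc_min = lfc_min, alpha = alpha, use_fdr = isTRUE(use_fdr)),
            class = "de_thresholds")
}

#' Filter a DE table and split into up- and down-regulated sets
#'
#' Keeps features with `|log2FC| >= lfc_min` and `p < alpha` (or
#' `fdr < alpha` when `use_fdr`); the fold-change bound is non-strict,
#' the significance bound strict.
#'
#' @param table A `DETable` data.frame from one of the DE engines.
#' @param thr A [de_thresholds()].
#' @return List with elements `kept`, `up`, `down` (disjoint `DETable`
#'   subsets; `up` and `down` partition `kept`).
#' @export
filter_de <- function(table, thr) {
  stopifnot(inherits(thr, "de_thresholds"))
  crit <- if (thr$use_fdr) table$fdr < thr$alpha else table$p < thr$alpha
  keep <- abs(table$log2FC) >= thr$lfc_min & crit
  kept <- table[keep, , drop = FALSE]
  list(kept = kept,
       up = kept[kept$direction == "up", , drop = FALSE],
       down = kept[kept$direction == "down", , drop = FALSE])
}
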