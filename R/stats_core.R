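#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of sorted columns. Ties within a sample receive
#' the mean of the reference quantiles they span. Each omics layer is
#' normalized separately by calling this once per layer.
#'
#' @param x Expression matrix (features x samples), linear scale.
#' @return Normalized matrix of the same shape; the `omics_kind` attribute
#'   is preserved. A single-sample matrix is returned unchanged with a
#'   warning.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(x)
  }
  if (any(!is.finite(x))) stop("values must be finite")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attr(out, "omics_kind") <- attr(x, "omics_kind")
  out
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni: `min(1, m * p)`. Benjamini-Hochberg: step-up with a running
#' minimum from the largest rank. Input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"bonferroni"` (case-insensitive).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH")
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(tolower(method[1]), c("bh", "bonferroni"))
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

# Rank-sum U statistic and tie-share AUC for tumor vs control values.
rank_sum_auc <- function(tumor, control) {
  n1 <- length(tumor); n2 <- length(control)
  r <- rank(c(tumor, control))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  c(U = u, auc = u / (n1 * n2))
}

#' Paired differential statistics for every feature
#'
#' For each feature, computes on `log2(value + pseudocount)`: the paired
#' t-test on per-patient (tumor - control) differences, the two-sample
#' Wilcoxon-Mann-Whitney test (tie-corrected normal approximation), the AUC
#' (probability that a random tumor value exceeds a random control value,
#' ties counted 1/2), the mean paired log2 fold change, the effect size
#' t / sqrt(n pairs), and a Shapiro-Wilk normality p-value for the paired
#' differences. Raw t-test p-values are adjusted by both Benjamini-Hochberg
#' and Bonferroni. Features with any missing value are excluded and listed
#' in the `"excluded"` attribute.
#'
#' @param x Expression matrix (normalized, linear scale).
#' @param design Paired sample design covering all columns of `x`.
#' @param pseudocount Added before the log2 transform (default 1).
#' @return Data frame (one row per feature) with columns `feature_id`,
#'   `mean_tumor`, `mean_control`, `log2_fold_change`, `t_statistic`,
#'   `p_t_raw`, `p_wmw_raw`, `auc`, `effect_size`, `shapiro_p`, `p_bh`,
#'   `p_bonferroni`, `direction`, `zero_variance`. Attributes: `n_pairs`,
#'   `excluded`, `omics_kind`.
#' @export
test_differential <- function(x, design, pseudocount = 1) {
  idx <- paired_indices(x, design)
  n <- length(idx$patients)
  if (n < 3) stop("need at least 3 matched pairs")

  has_na <- apply(x, 1, anyNA)
  excluded <- rownames(x)[has_na]
  if (length(excluded) > 0) {
    sm_log("differential: excluded ", length(excluded),
           " feature(s) with missing values")
    x <- x[!has_na, , drop = FALSE]
  }

  lx <- log2(x + pseudocount)
  tum <- lx[, idx$tumor, drop = FALSE]
  ctl <- lx[, idx$control, drop = FALSE]
  d <- tum - ctl

  lfc <- rowMeans(d)
  sd_d <- apply(d, 1, sd)
  zero_var <- sd_d == 0
  t_stat <- ifelse(zero_var, NA_real_, lfc / (sd_d / sqrt(n)))
  p_t <- ifelse(zero_var, 1, 2 * pt(-abs(t_stat), df = n - 1))

  wmw <- t(vapply(seq_len(nrow(lx)), function(i) {
    tv <- tum[i, ]; cv <- ctl[i, ]
    ua <- rank_sum_auc(tv, cv)
    p <- if (all(tv == tv[1]) && all(cv == cv[1]) && tv[1] == cv[1]) 1
         else wilcox.test(tv, cv, exact = FALSE, correct = FALSE)$p.value
    c(ua, p_wmw = p)
  }, c(U = 0, auc = 0, p_wmw = 0)))

  shapiro_p <- vapply(seq_len(nrow(d)), function(i) {
    if (zero_var[i]) return(NA_real_)
    shapiro.test(d[i, ])$p.value
  }, 0)

  res <- data.frame(
    feature_id = rownames(x),
    mean_tumor = rowMeans(x[, idx$tumor, drop = FALSE]),
    mean_control = rowMeans(x[, idx$control, drop = FALSE]),
    log2_fold_change = lfc,
    t_statistic = t_stat,
    p_t_raw = p_t,
    p_wmw_raw = wmw[, "p_wmw"],
    auc = wmw[, "auc"],
    effect_size = t_stat / sqrt(n),
    shapiro_p = shapiro_p,
    p_bh = adjust_pvalues(p_t, "BH"),
    p_bonferroni = adjust_pvalues(p_t, "bonferroni"),
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA_character_)),
    zero_variance = zero_var,
    row.names = NULL
  )
  attr(res, "n_pairs") <- n
  attr(res, "excluded") <- excluded
  attr(res, "omics_kind") <- attr(x, "omics_kind")
  res
}

# Column of adjusted (or raw) p-values to use for a significance call.
p_column <- function(method = c("bonferroni", "BH", "raw")) {
  method <- match.arg(tolower(method[1]), c("bonferroni", "bh", "raw"))
  switch(method, bonferroni = "p_bonferroni", bh = "p_bh", raw = "p_t_raw")
}

#' Summarize up/down direction among significant features
#'
#' @param results A differential result table from [test_differential()].
#' @param alpha Significance level (default 0.05).
#' @param method Which p-value to threshold: `"bonferroni"` (default),
#'   `"BH"` or `"raw"`.
#' @return List with `n_significant`, `n_up`, `n_down`, and `pct_down` /
#'   `pct_up` (percentages rounded to one decimal; `NA` when nothing is
#'   significant).
#' @export
summarize_directions <- function(results, alpha = 0.05,
                                 method = "bonferroni") {
  p <- results[[p_column(method)]]
  sig <- !is.na(p) & p < alpha & !is.na(results$direction)
  n_sig <- sum(sig)
  n_down <- sum(results$direction[sig] == "down")
  n_up <- sum(results$direction[sig] == "up")
  list(
    n_significant = n_sig,
    n_up = n_up,
    n_down = n_down,
    pct_down = if (n_sig > 0) round(100 * n_down / n_sig, 1) else NA_real_,
    pct_up = if (n_sig > 0) round(100 * n_up / n_sig, 1) else NA_real_
  )
}

#' Principal component scores for samples
#'
#' PCA on log2-transformed, feature-centered values. Components are ordered
#' by decreasing variance; each component's sign is fixed so that its
#' largest-magnitude feature loading is positive.
#'
#' @param x Expression matrix (linear scale).
#' @param pseudocount Added before the log2 transform.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components) and `var_explained` (fractions summing to 1).
#' @export
pca_scores <- function(x, pseudocount = 1) {
  if (ncol(x) < 2) stop("PCA needs >= 2 samples")
  lx <- log2(x + pseudocount)
  if (all(apply(lx, 1, sd) == 0)) stop("matrix is constant; PCA undefined")
  fit <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  list(scores = fit$x,
       loadings = fit$rotation,
       var_explained = fit$sdev^2 / sum(fit$sdev^2))
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering with Euclidean distance on log2 values and
#' average linkage. Samples are ordered by identifier beforehand so tie
#' resolution is deterministic.
#'
#' @param x Expression matrix (linear scale).
#' @param pseudocount Added before the log2 transform.
#' @return List with `tree` (an [stats::hclust] object) and `leaf_order`
#'   (sample ids in dendrogram order).
#' @export
hierarchical_clustering <- function(x, pseudocount = 1) {
  if (ncol(x) < 2) stop("clustering needs >= 2 samples")
  x <- x[, order(colnames(x)), drop = FALSE]
  lx <- log2(x + pseudocount)
  hc <- hclust(dist(t(lx)), method = "average")
  list(tree = hc, leaf_order = hc$labels[hc$order])
}
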