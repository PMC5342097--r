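#' Per-test alpha under Bonferroni control of all feature pairs
#'
#' Divides the family-wise alpha by the number of unordered feature pairs
#' `choose(n_features, 2)`.
#'
#' @param n_features Number of features tested pairwise (>= 2).
#' @param family_alpha_level Family-wise significance level (default 0.05).
#' @return The per-test threshold.
#' @export
#' @examples
#' signif(family_alpha(43419), 1) # 5e-11
family_alpha <- function(n_features, family_alpha_level = 0.05) {
  if (n_features < 2) stop("need at least 2 features")
  family_alpha_level / choose(n_features, 2)
}

# Canonical unordered pair-type label, e.g. "miRNA-mRNA".
pair_type_label <- function(kind_a, kind_b) {
  ka <- match(kind_a, OMICS_KINDS)
  kb <- match(kind_b, OMICS_KINDS)
  paste(OMICS_KINDS[pmin(ka, kb)], OMICS_KINDS[pmax(ka, kb)], sep = "-")
}

PAIR_TYPES <- c("miRNA-miRNA", "miRNA-mRNA", "miRNA-protein",
                "mRNA-mRNA", "mRNA-protein", "protein-protein")

# Two-sided p-value for a Pearson correlation via the t transform with
# n - 2 degrees of freedom; |r| = 1 maps to p = 0.
cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tt <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-tt, df = n - 2)
  p
}

#' Significant all-pairs correlation edges across omics layers
#'
#' Concatenates the layers (on the log2 scale), computes Pearson
#' correlations between every unordered pair of features over all samples,
#' and keeps pairs whose two-sided p-value (t transform, n - 2 df) falls
#' below the per-test threshold. Correlations are evaluated blockwise so the
#' full pairs matrix is never materialized. Constant features are excluded
#' up front (their correlation is undefined) and the exclusion count logged;
#' the default threshold is the Bonferroni family alpha over the pairs of
#' features actually tested.
#'
#' @param matrices Named list of expression matrices sharing one sample set.
#' @param threshold Per-test p-value threshold; defaults to
#'   [family_alpha()] over the tested features.
#' @param family_alpha_level Family-wise alpha used when `threshold` is not
#'   supplied.
#' @param block_size Features per block (default 500).
#' @param pseudocount Added before the log2 transform.
#' @return Data frame of significant edges: `feature_a`, `feature_b`,
#'   `omics_a`, `omics_b`, `pair_type`, `r`, `p_raw`; attributes
#'   `threshold`, `n_features_tested`, `n_constant_excluded`,
#'   `n_per_omics`.
#' @export
correlation_edges <- function(matrices, threshold = NULL,
                              family_alpha_level = 0.05,
                              block_size = 500, pseudocount = 1) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  samples <- colnames(matrices[[1]])
  for (m in matrices) {
    if (!setequal(colnames(m), samples))
      stop("all matrices must share the same sample set")
  }
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples")

  lx <- do.call(rbind, lapply(matrices, function(m)
    log2(m[, samples, drop = FALSE] + pseudocount)))
  kinds <- unlist(lapply(matrices, function(m)
    rep(attr(m, "omics_kind"), nrow(m))))
  if (anyDuplicated(rownames(lx)) > 0)
    stop("feature ids collide across layers")

  mu <- rowMeans(lx)
  ss <- sqrt(rowSums((lx - mu)^2))
  constant <- ss == 0
  if (any(constant))
    sm_log("correlation: excluded ", sum(constant), " constant feature(s)")
  z <- (lx[!constant, , drop = FALSE] - mu[!constant]) / ss[!constant]
  kinds <- kinds[!constant]
  nf <- nrow(z)
  if (is.null(threshold)) threshold <- family_alpha(nf, family_alpha_level)

  blocks <- split(seq_len(nf), ceiling(seq_len(nf) / block_size))
  hits <- list()
  for (bi in seq_along(blocks)) {
    for (bj in bi:length(blocks)) {
      ii <- blocks[[bi]]; jj <- blocks[[bj]]
      r <- tcrossprod(z[ii, , drop = FALSE], z[jj, , drop = FALSE])
      p <- matrix(cor_pvalue(as.vector(r), n), nrow = nrow(r))
      keep <- which(p < threshold, arr.ind = TRUE)
      if (bi == bj) keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]
      if (nrow(keep) > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          i = ii[keep[, 1]], j = jj[keep[, 2]],
          r = r[keep], p_raw = p[keep])
      }
    }
  }
  ids <- rownames(z)
  if (length(hits) == 0) {
    edges <- data.frame(feature_a = character(0), feature_b = character(0),
                        omics_a = character(0), omics_b = character(0),
                        pair_type = character(0), r = numeric(0),
                        p_raw = numeric(0))
  } else {
    h <- do.call(rbind, hits)
    edges <- data.frame(
      feature_a = ids[h$i], feature_b = ids[h$j],
      omics_a = kinds[h$i], omics_b = kinds[h$j],
      pair_type = pair_type_label(kinds[h$i], kinds[h$j]),
      r = pmin(1, pmax(-1, h$r)), p_raw = h$p_raw,
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$feature_a, edges$feature_b), ]
    rownames(edges) <- NULL
  }
  attr(edges, "threshold") <- threshold
  attr(edges, "n_features_tested") <- nf
  attr(edges, "n_constant_excluded") <- sum(constant)
  attr(edges, "n_per_omics") <-
    table(factor(kinds, levels = OMICS_KINDS))
  edges
}

#' Observed vs expected correlation counts per pair type
#'
#' Under random pairing, the expected fraction of pairs of type (A, B) is
#' `n_A * n_B / choose(N, 2)` for distinct layers and
#' `choose(n_A, 2) / choose(N, 2)` within a layer. Observed counts come
#' from a significant-edge list.
#'
#' @param edges Edge table from [correlation_edges()].
#' @param n_per_omics Named counts of features per omics kind (defaults to
#'   the attribute carried by `edges`).
#' @return Data frame over the six pair types with observed counts and
#'   fractions and expected fractions (each fraction set sums to 1).
#' @export
pair_type_summary <- function(edges, n_per_omics = NULL) {
  if (is.null(n_per_omics)) n_per_omics <- attr(edges, "n_per_omics")
  n_per_omics <- n_per_omics[OMICS_KINDS]
  n_total <- sum(n_per_omics)
  total_pairs <- choose(n_total, 2)
  expected_pairs <- vapply(PAIR_TYPES, function(ptype) {
    kinds <- strsplit(ptype, "-", fixed = TRUE)[[1]]
    if (kinds[1] == kinds[2]) choose(n_per_omics[[kinds[1]]], 2)
    else n_per_omics[[kinds[1]]] * n_per_omics[[kinds[2]]]
  }, 0)
  obs <- table(factor(edges$pair_type, levels = PAIR_TYPES))
  n_edges <- sum(obs)
  data.frame(
    pair_type = PAIR_TYPES,
    observed = as.integer(obs),
    observed_fraction = if (n_edges > 0) as.numeric(obs) / n_edges
                        else rep(0, length(PAIR_TYPES)),
    expected_fraction = expected_pairs / total_pairs,
    row.names = NULL
  )
}
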