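#' Build gene-protein pairs with differential signal on both layers
#'
#' Expands the protein-to-gene mapping into pairs and keeps those where
#' both the gene and the protein have a raw paired t-test p-value below the
#' threshold. Proteins without a mapping (or without measurements) are
#' dropped with a logged count; a protein mapping to several genes yields
#' several pairs.
#'
#' @param map Protein-gene mapping (`protein_id`, `gene_id`).
#' @param gene_results,protein_results Differential result tables for the
#'   two layers.
#' @param p_threshold Raw p-value cutoff applied to both members
#'   (default 0.05).
#' @return Data frame of pairs: `gene_id`, `protein_id`, `gene_auc`,
#'   `protein_auc`, `gene_p_raw`, `protein_p_raw`, `concordant` (`TRUE`
#'   when both AUCs sit on the same side of 0.5; `NA` when either is
#'   exactly 0.5).
#' @export
build_concordance_pairs <- function(map, gene_results, protein_results,
                                    p_threshold = 0.05) {
  if (is.null(map) || nrow(map) == 0)
    stop("protein-gene mapping is empty")
  n_prot <- length(unique(protein_results$feature_id))
  m <- merge(map, gene_results[, c("feature_id", "auc", "p_t_raw")],
             by.x = "gene_id", by.y = "feature_id")
  names(m)[names(m) == "auc"] <- "gene_auc"
  names(m)[names(m) == "p_t_raw"] <- "gene_p_raw"
  m <- merge(m, protein_results[, c("feature_id", "auc", "p_t_raw")],
             by.x = "protein_id", by.y = "feature_id")
  names(m)[names(m) == "auc"] <- "protein_auc"
  names(m)[names(m) == "p_t_raw"] <- "protein_p_raw"
  dropped <- n_prot - length(unique(m$protein_id))
  if (dropped > 0)
    sm_log("concordance: ", dropped,
           " measured protein(s) without mapped measured gene")
  pairs <- m[m$gene_p_raw < p_threshold & m$protein_p_raw < p_threshold, ,
             drop = FALSE]
  gs <- sign(pairs$gene_auc - 0.5)
  ps <- sign(pairs$protein_auc - 0.5)
  pairs$concordant <- ifelse(gs == 0 | ps == 0, NA, gs == ps)
  pairs <- pairs[order(pairs$gene_id, pairs$protein_id),
                 c("gene_id", "protein_id", "gene_auc", "protein_auc",
                   "gene_p_raw", "protein_p_raw", "concordant")]
  rownames(pairs) <- NULL
  pairs
}

#' Correlation and concordance of gene vs protein differential signals
#'
#' Pearson correlation between gene and protein AUC values over the
#' retained pairs, and the percentage of pairs where gene and protein are
#' deregulated in the same direction (both AUCs on the same side of 0.5).
#' Pairs with an AUC of exactly 0.5 carry no direction and are excluded
#' from the concordance denominator.
#'
#' @param pairs Pair table from [build_concordance_pairs()].
#' @return List with `n_pairs`, `auc_correlation` (`NA` with fewer than 3
#'   pairs), `pct_concordant` and `n_direction_pairs` (the concordance
#'   denominator).
#' @export
concordance_stats <- function(pairs) {
  n <- nrow(pairs)
  r <- if (n >= 3) cor(pairs$gene_auc, pairs$protein_auc) else NA_real_
  usable <- !is.na(pairs$concordant)
  n_dir <- sum(usable)
  pct <- if (n_dir > 0) 100 * sum(pairs$concordant[usable]) / n_dir
         else NA_real_
  list(n_pairs = n, auc_correlation = r,
       pct_concordant = pct, n_direction_pairs = n_dir)
}
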