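#' Filter a miRNA-gene interaction table
#'
#' Restricts edges to a support level (`"all"` keeps everything,
#' `"functional_strong"` keeps only interactions validated by functional
#' assays) and to miRNAs and genes actually measured; dropped-edge counts
#' are logged.
#'
#' @param interactions Interaction table (`mirna_id`, `gene_id`,
#'   `support`).
#' @param support `"all"` or `"functional_strong"`.
#' @param measured_mirnas,measured_genes Character vectors of measured
#'   feature ids (`NULL` keeps all).
#' @return The filtered interaction table; errors if nothing remains.
#' @export
filter_network <- function(interactions,
                           support = c("all", "functional_strong"),
                           measured_mirnas = NULL, measured_genes = NULL) {
  support <- match.arg(support)
  n0 <- nrow(interactions)
  keep <- rep(TRUE, n0)
  if (support == "functional_strong")
    keep <- interactions$support == "functional_strong"
  if (!is.null(measured_mirnas))
    keep <- keep & interactions$mirna_id %in% measured_mirnas
  if (!is.null(measured_genes))
    keep <- keep & interactions$gene_id %in% measured_genes
  out <- interactions[keep, , drop = FALSE]
  sm_log("network filter: kept ", nrow(out), " of ", n0, " edge(s)")
  if (nrow(out) == 0) stop("no interactions left after filtering")
  rownames(out) <- NULL
  out
}

#' Stoichiometric edge weights from control gene expression
#'
#' For each miRNA `m_i` targeting genes `g_1..g_l`, the weight of the edge
#' to `g_j` is the share of that gene in the total expression of the
#' miRNA's targets: `w_ij = e(g_j) / sum_k e(g_k)`, with `e` the mean
#' control-sample expression on the linear scale. A highly expressed target
#' thus absorbs more of the miRNA's influence than its lowly expressed
#' competitors. If all of a miRNA's targets have zero mean expression the
#' weights fall back to uniform `1/l` with a warning.
#'
#' @param interactions Filtered interaction table.
#' @param control_gene_means Named nonnegative vector of mean control
#'   expression per gene (linear scale); must cover every gene in the
#'   table.
#' @return An `influence_network`: list with `edges` (edge table plus
#'   `weight`), `mirna_targets` (targets per miRNA, `l`) and `gene_degree`
#'   (targeting miRNAs per gene, `z`).
#' @export
compute_edge_weights <- function(interactions, control_gene_means) {
  missing <- setdiff(unique(interactions$gene_id),
                     names(control_gene_means))
  if (length(missing) > 0)
    stop("no control expression for gene(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  if (any(control_gene_means < 0))
    stop("control gene means must be nonnegative")
  e_g <- unname(control_gene_means[interactions$gene_id])
  denom <- tapply(e_g, interactions$mirna_id, sum)
  denom_per_edge <- unname(denom[interactions$mirna_id])
  l_per_edge <- unname(table(interactions$mirna_id)[interactions$mirna_id])
  zero <- denom_per_edge == 0
  if (any(zero))
    warning("all-zero target expression for ",
            length(unique(interactions$mirna_id[zero])),
            " miRNA(s); using uniform weights")
  w <- ifelse(zero, 1 / l_per_edge, e_g / denom_per_edge)
  edges <- interactions
  edges$weight <- as.numeric(w)
  structure(list(
    edges = edges,
    mirna_targets = table(interactions$mirna_id),
    gene_degree = table(interactions$gene_id)
  ), class = "influence_network")
}

#' Joint influence scores of miRNAs on target genes
#'
#' For each gene `g_j`, the joint influence score is the weighted sum of
#' the abundances of all miRNAs targeting it:
#' `s(g_j) = sum_k w_kj * e(m_k)`. Edge weights are fixed (inferred from
#' control gene expression via [compute_edge_weights()]) and the score is
#' evaluated twice: with control miRNA means (`s_control`, the normal-state
#' score) and with cancer miRNA means (`s_cancer`), giving the per-gene
#' change `delta = s_cancer - s_control`.
#'
#' @param network An `influence_network` from [compute_edge_weights()].
#' @param mirna_means_control,mirna_means_cancer Named vectors of mean
#'   miRNA expression per condition (linear scale).
#' @param genes Optional gene ids to include; genes with no targeting
#'   miRNA get scores of 0. Defaults to the genes in the network.
#' @return Data frame with `gene_id`, `degree`, `s_control`, `s_cancer`,
#'   `delta`.
#' @export
joint_influence_scores <- function(network, mirna_means_control,
                                   mirna_means_cancer, genes = NULL) {
  edges <- network$edges
  missing <- setdiff(unique(edges$mirna_id),
                     intersect(names(mirna_means_control),
                               names(mirna_means_cancer)))
  if (length(missing) > 0)
    stop("no expression for miRNA(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "")
  if (is.null(genes)) genes <- sort(unique(edges$gene_id))
  gfac <- factor(edges$gene_id, levels = genes)
  s_n <- tapply(edges$weight * mirna_means_control[edges$mirna_id],
                gfac, sum, default = 0)
  s_c <- tapply(edges$weight * mirna_means_cancer[edges$mirna_id],
                gfac, sum, default = 0)
  deg <- table(gfac)
  data.frame(
    gene_id = genes,
    degree = as.integer(deg[genes]),
    s_control = as.numeric(s_n[genes]),
    s_cancer = as.numeric(s_c[genes]),
    delta = as.numeric(s_c[genes]) - as.numeric(s_n[genes]),
    row.names = NULL
  )
}

#' Predict the direction of gene deregulation from influence changes
#'
#' A gene whose joint influence score increases in cancer
#' (`delta > 0`) is under stronger miRNA repression there and is expected
#' to have lower expression in cancer (`"down"`); a decreased score
#' predicts higher expression (`"up"`). An exactly unchanged score yields
#' `"no_call"` and is excluded from accuracy evaluation.
#'
#' @param scores Score table from [joint_influence_scores()].
#' @return The table with a `predicted_direction` column added.
#' @export
predict_directions <- function(scores) {
  scores$predicted_direction <-
    ifelse(scores$delta > 0, "down",
           ifelse(scores$delta < 0, "up", "no_call"))
  scores
}

#' One-sided exact binomial p-value for a prediction accuracy
#'
#' Probability of at least `n_correct` successes out of `n_evaluated`
#' under a null success probability (coin-flip direction calls by
#' default).
#'
#' @param n_correct,n_evaluated Correct and total evaluated predictions.
#' @param null_prob Null success probability (default 0.5).
#' @return The upper-tail p-value, or `NA` when nothing was evaluated.
#' @export
#' @examples
#' accuracy_pvalue(12, 13) # ~0.0017
accuracy_pvalue <- function(n_correct, n_evaluated, null_prob = 0.5) {
  if (n_evaluated == 0) return(NA_real_)
  stopifnot(n_correct >= 0, n_correct <= n_evaluated)
  pbinom(n_correct - 1, n_evaluated, null_prob, lower.tail = FALSE)
}

#' Degree-stratified accuracy of direction predictions
#'
#' Compares predicted directions against measured ones (sign of the paired
#' log2 fold change) for the significantly deregulated genes, stratified by
#' the number of miRNAs targeting each gene. Genes enter the evaluation
#' when their adjusted p-value falls below `alpha`, their measured fold
#' change is nonzero and the model made a call.
#'
#' @param predictions Score table with predictions from
#'   [predict_directions()].
#' @param gene_results Differential result table for the gene layer.
#' @param min_degrees Integer vector of minimum-degree thresholds
#'   (default 1:6).
#' @param alpha Significance level for the evaluation set (default 0.05).
#' @param adjust `"bonferroni"` (default), `"BH"` or `"raw"`.
#' @return Data frame with one row per threshold: `min_degree`,
#'   `n_evaluated`, `n_correct`, `accuracy_pct`, `p_value`; the per-gene
#'   evaluation table is attached as attribute `"genes"`.
#' @export
evaluate_by_degree <- function(predictions, gene_results,
                               min_degrees = 1:6, alpha = 0.05,
                               adjust = "bonferroni") {
  p <- gene_results[[p_column(adjust)]]
  sig <- gene_results[!is.na(p) & p < alpha &
                        !is.na(gene_results$direction), , drop = FALSE]
  ev <- merge(predictions, sig[, c("feature_id", "direction")],
              by.x = "gene_id", by.y = "feature_id")
  ev <- ev[ev$predicted_direction != "no_call", , drop = FALSE]
  ev$correct <- ev$predicted_direction == ev$direction
  out <- do.call(rbind, lapply(min_degrees, function(d) {
    sub <- ev[ev$degree >= d, , drop = FALSE]
    n <- nrow(sub)
    nc <- sum(sub$correct)
    data.frame(min_degree = d, n_evaluated = n, n_correct = nc,
               accuracy_pct = if (n > 0) 100 * nc / n else NA_real_,
               p_value = accuracy_pvalue(nc, n))
  }))
  attr(out, "genes") <- ev[order(ev$gene_id), ]
  out
}

#' Export an influence network with expression attributes
#'
#' Builds an undirected bipartite igraph with edge weights and, when
#' differential results are supplied, per-node log2 fold changes, for SIF /
#' GraphML export in the style of a regulator-target network diagram.
#'
#' @param network An `influence_network`.
#' @param mirna_results,gene_results Optional differential result tables
#'   used to annotate nodes with `log2_fold_change`.
#' @return An igraph object (miRNA nodes flagged `type = FALSE`, gene
#'   nodes `type = TRUE`).
#' @export
influence_graph <- function(network, mirna_results = NULL,
                            gene_results = NULL) {
  edges <- network$edges[, c("mirna_id", "gene_id", "weight")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- igraph::V(g)$name %in% network$edges$gene_id
  lfc <- c()
  for (res in list(mirna_results, gene_results)) {
    if (!is.null(res))
      lfc <- c(lfc, setNames(res$log2_fold_change, res$feature_id))
  }
  if (length(lfc) > 0)
    igraph::V(g)$log2_fold_change <-
      unname(lfc[igraph::V(g)$name])
  g
}
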