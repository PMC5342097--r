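options(stoichmir.verbose = FALSE)

# A valid paired design with n patients (samples P01_T, P01_C, ...).
toy_design <- function(n = 4) {
  data.frame(
    sample_id = c(sprintf("P%02d_T", seq_len(n)),
                  sprintf("P%02d_C", seq_len(n))),
    patient_id = rep(sprintf("P%02d", seq_len(n)), 2),
    condition = rep(c("tumor", "control"), each = n)
  )
}

# Expression matrix from per-feature tumor and control value rows.
paired_matrix <- function(tumor, control, omics = "mRNA",
                          ids = paste0("f", seq_len(nrow(tumor)))) {
  n <- ncol(tumor)
  m <- cbind(tumor, control)
  dimnames(m) <- list(ids, c(sprintf("P%02d_T", seq_len(n)),
                             sprintf("P%02d_C", seq_len(n))))
  expression_matrix(m, omics)
}

# Random strictly positive expression matrix.
random_matrix <- function(n_feat, n_pat, omics = "mRNA",
                          prefix = "f") {
  m <- matrix(exp(rnorm(n_feat * 2 * n_pat, 5, 1)), n_feat)
  dimnames(m) <- list(paste0(prefix, seq_len(n_feat)),
                      c(sprintf("P%02d_T", seq_len(n_pat)),
                        sprintf("P%02d_C", seq_len(n_pat))))
  expression_matrix(m, omics)
}

# Brute-force Benjamini-Hochberg step-up from its definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m / i * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Brute-force AUC: share of tumor-control pairs with tumor higher,
# ties counted one half.
auc_brute <- function(tumor, control) {
  mean(outer(tumor, control, ">") + 0.5 * outer(tumor, control, "=="))
}

# Minimal differential-result-like table for direction/accuracy helpers.
fake_results <- function(ids, direction, p, col = "p_bonferroni") {
  df <- data.frame(feature_id = ids, direction = direction,
                   stringsAsFactors = FALSE)
  df[[col]] <- p
  for (other in setdiff(c("p_bonferroni", "p_bh", "p_t_raw"), col))
    df[[other]] <- p
  df
}

# Toy annotation on a two-chromosome genome.
toy_genome <- function() c("1" = 1e7, "2" = 1e7)
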