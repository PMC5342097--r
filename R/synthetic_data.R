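#' Configuration for a synthetic paired cohort
#'
#' Defines the generative conditions for a matched tumor/control multi-omics
#' cohort: 18 patients by default, with three layers whose sizes are
#' scaled-down counterparts of a genome-wide screen (100 miRNAs, 800 genes,
#' 300 proteins). Expression is log-normal: per-feature baseline plus a
#' shared per-patient offset plus feature noise, all on the natural-log
#' scale. Intrinsically deregulated features receive a tumor shift of
#' `effect_size_log2 * ln 2` with sign drawn 50/50; genes targeted by
#' miRNAs additionally respond to the change in their joint influence score
#' with strength `coupling_strength` (see [generate_cohort()]).
#'
#' @param n_patients Number of matched pairs (default 18).
#' @param n_mirna,n_gene,n_protein Features per layer (proteins must not
#'   exceed genes; each protein maps to one distinct gene).
#' @param mean_targets_per_mirna Mean out-degree of the simulated
#'   interaction network (shifted Poisson, >= 1 target each).
#' @param frac_functional Fraction of interactions flagged
#'   `functional_strong`.
#' @param fraction_deregulated Named fractions of intrinsically deregulated
#'   features per layer (`miRNA`, `mRNA`, `protein`); the mRNA fraction
#'   applies to genes not targeted in the network, so intrinsic and
#'   coupling-driven gene sets are disjoint.
#' @param effect_size_log2 Mean tumor shift of intrinsically deregulated
#'   features, in log2 units.
#' @param coupling_strength Nonnegative response of targeted genes to the
#'   relative change in joint miRNA influence (kappa; 0 decouples layers).
#' @param protein_noise_sd,feature_noise_sd,patient_baseline_sd Natural-log
#'   standard deviations of protein-specific noise, per-measurement feature
#'   noise, and the shared per-patient baseline.
#' @param hotspot If `TRUE`, a set of deregulated features of all three
#'   layers is placed into one shared genomic window.
#' @param hotspot_n_per_layer Deregulated features per layer placed in the
#'   hotspot.
#' @param hotspot_width Width of the hotspot window in bases (default 1e6);
#'   features are packed into its central 40% so a sliding window of this
#'   size is guaranteed to cover all of them.
#' @param chrom_lengths Chromosome lengths used to lay out feature
#'   coordinates.
#' @param seed Integer seed making the cohort reproducible (`NULL` uses the
#'   current RNG stream).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 18, n_mirna = 100, n_gene = 800,
                       n_protein = 300, mean_targets_per_mirna = 4,
                       frac_functional = 0.3,
                       fraction_deregulated = c(miRNA = 0.2, mRNA = 0.05,
                                                protein = 0),
                       effect_size_log2 = 1, coupling_strength = 1,
                       protein_noise_sd = 0.5, feature_noise_sd = 0.3,
                       patient_baseline_sd = 0.3,
                       hotspot = FALSE, hotspot_n_per_layer = 4,
                       hotspot_width = 1e6,
                       chrom_lengths = hs_chromosome_lengths(),
                       seed = NULL) {
  fraction_deregulated <- fraction_deregulated[OMICS_KINDS]
  names(fraction_deregulated) <- OMICS_KINDS
  fraction_deregulated[is.na(fraction_deregulated)] <- 0
  cfg <- list(n_patients = n_patients, n_mirna = n_mirna, n_gene = n_gene,
              n_protein = n_protein,
              mean_targets_per_mirna = mean_targets_per_mirna,
              frac_functional = frac_functional,
              fraction_deregulated = fraction_deregulated,
              effect_size_log2 = effect_size_log2,
              coupling_strength = coupling_strength,
              protein_noise_sd = protein_noise_sd,
              feature_noise_sd = feature_noise_sd,
              patient_baseline_sd = patient_baseline_sd,
              hotspot = hotspot,
              hotspot_n_per_layer = hotspot_n_per_layer,
              hotspot_width = hotspot_width,
              chrom_lengths = chrom_lengths, seed = seed)
  counts <- c(cfg$n_patients, cfg$n_mirna, cfg$n_gene, cfg$n_protein)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$n_protein > cfg$n_gene)
    stop("n_protein must not exceed n_gene")
  if (any(fraction_deregulated < 0 | fraction_deregulated > 1))
    stop("deregulated fractions must lie in [0, 1]")
  sds <- c(cfg$protein_noise_sd, cfg$feature_noise_sd,
           cfg$patient_baseline_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$coupling_strength < 0) stop("coupling_strength must be >= 0")
  structure(cfg, class = "sim_config")
}

mirna_ids <- function(n) sprintf("mir%04d", seq_len(n))
gene_ids_ <- function(n) sprintf("gene%05d", seq_len(n))
protein_ids <- function(n) sprintf("prot%04d", seq_len(n))

#' Generate a random miRNA-gene interaction network
#'
#' Each miRNA's target count is drawn from a Poisson distribution shifted
#' to be at least 1 (so the mean equals `mean_targets_per_mirna`), capped
#' at the number of genes; targets are sampled without replacement and a
#' configurable fraction of edges is flagged as functionally validated.
#'
#' @param n_mirna,n_gene Node counts per side.
#' @param mean_targets_per_mirna Requested mean out-degree (>= 1, and at
#'   most `n_gene`).
#' @param frac_functional Probability that an edge is `functional_strong`.
#' @param seed Optional integer seed.
#' @return An interaction table (`mirna_id`, `gene_id`, `support`).
#' @export
generate_interaction_network <- function(n_mirna, n_gene,
                                         mean_targets_per_mirna,
                                         frac_functional = 0.3,
                                         seed = NULL) {
  if (n_mirna < 1 || n_gene < 1) stop("counts must be >= 1")
  if (mean_targets_per_mirna < 1)
    stop("mean_targets_per_mirna must be >= 1")
  if (mean_targets_per_mirna > n_gene)
    stop("mean_targets_per_mirna cannot exceed n_gene")
  with_seed_if(seed, {
    mirnas <- mirna_ids(n_mirna)
    genes <- gene_ids_(n_gene)
    l <- pmin(1 + rpois(n_mirna, mean_targets_per_mirna - 1), n_gene)
    edges <- do.call(rbind, lapply(seq_len(n_mirna), function(i) {
      data.frame(mirna_id = mirnas[i],
                 gene_id = genes[sample.int(n_gene, l[i])],
                 stringsAsFactors = FALSE)
    }))
    edges$support <- ifelse(runif(nrow(edges)) < frac_functional,
                            "functional_strong", "other")
    interaction_table(edges)
  })
}

# Log-scale layer matrix: baseline + patient offset + tumor shift + noise.
# Columns are ordered tumor samples then control samples.
layer_log_matrix <- function(mu, delta, beta, noise_sd, feature_names,
                             tumor_names, control_names) {
  n_f <- length(mu); n_p <- length(beta)
  base <- matrix(mu, n_f, 2 * n_p) +
    matrix(rep(beta, 2), n_f, 2 * n_p, byrow = TRUE)
  base[, seq_len(n_p)] <- base[, seq_len(n_p)] + delta
  base <- base + matrix(rnorm(n_f * 2 * n_p, 0, noise_sd), n_f)
  dimnames(base) <- list(feature_names, c(tumor_names, control_names))
  base
}

# Direction label from a signed tumor shift (natural-log units).
shift_direction <- function(shift, eps = 1e-12) {
  ifelse(shift > eps, "up", ifelse(shift < -eps, "down", "none"))
}

#' Generate a synthetic paired tumor/control multi-omics cohort
#'
#' Simulates, in order: (1) miRNA abundances from a log-normal model with a
#' shared per-patient baseline and 50/50 up/down tumor shifts for the
#' intrinsically deregulated fraction; (2) gene abundances from the same
#' scheme, where genes targeted in the interaction network carry no
#' intrinsic shift but respond to miRNA deregulation: edge weights and
#' per-condition joint influence scores are computed from the true
#' (noise-free) condition means with [compute_edge_weights()] and
#' [joint_influence_scores()], and tumor gene abundance is multiplied by
#' `exp(-kappa * (s_cancer - s_control) / max(s_control, 1e-6))` — an
#' increased joint influence represses the gene; (3) protein abundances as
#' the mapped gene's log-abundance plus a protein-specific offset and
#' noise; (4) genomic coordinates by tiling the chromosomes evenly (proteins
#' inherit their gene's interval), optionally packing deregulated features
#' of all three layers into one hotspot window. Every injected direction is
#' recorded in the ground-truth table.
#'
#' @param config A [sim_config()].
#' @param network Optional interaction table; generated from the config
#'   when `NULL`. Its features must be a subset of the configured ids.
#' @return A `sim_cohort` list: `layers` (named expression matrices
#'   `miRNA`, `mRNA`, `protein`), `design`, `annotation`, `truth` (columns
#'   `feature_id`, `omics_kind`, `true_direction`, `true_shift_ln`,
#'   `delta_s`), `network`, `protein_gene_map`, `chrom_lengths`, `config`.
#' @export
generate_cohort <- function(config = sim_config(), network = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    mirnas <- mirna_ids(config$n_mirna)
    genes <- gene_ids_(config$n_gene)
    prots <- protein_ids(config$n_protein)
    if (is.null(network)) {
      network <- generate_interaction_network(
        config$n_mirna, config$n_gene, config$mean_targets_per_mirna,
        config$frac_functional)
    }
    if (!all(network$mirna_id %in% mirnas) ||
        !all(network$gene_id %in% genes))
      stop("network features are not a subset of the configured features")

    patients <- sprintf("P%02d", seq_len(config$n_patients))
    tumor_s <- paste0(patients, "_T")
    control_s <- paste0(patients, "_C")
    design <- sample_design(data.frame(
      sample_id = c(tumor_s, control_s),
      patient_id = rep(patients, 2),
      condition = rep(c("tumor", "control"), each = config$n_patients)))

    ln2 <- log(2)
    eff <- config$effect_size_log2 * ln2
    beta <- rnorm(config$n_patients, 0, config$patient_baseline_sd)

    # --- miRNA layer ---------------------------------------------------
    mu_m <- rnorm(config$n_mirna, log(200), 1)
    n_dm <- round(config$fraction_deregulated[["miRNA"]] * config$n_mirna)
    dereg_m <- if (n_dm > 0) sample(mirnas, n_dm) else character(0)
    delta_m <- setNames(rep(0, config$n_mirna), mirnas)
    if (n_dm > 0)
      delta_m[dereg_m] <- sample(c(-eff, eff), n_dm, replace = TRUE)
    log_m <- layer_log_matrix(mu_m, unname(delta_m), beta,
                              config$feature_noise_sd, mirnas,
                              tumor_s, control_s)

    # --- gene layer ----------------------------------------------------
    mu_g <- rnorm(config$n_gene, log(500), 1)
    targeted <- unique(network$gene_id)
    free_genes <- setdiff(genes, targeted)
    n_ig <- min(round(config$fraction_deregulated[["mRNA"]] * config$n_gene),
                length(free_genes))
    intrinsic_g <- if (n_ig > 0) sample(free_genes, n_ig) else character(0)
    delta_g <- setNames(rep(0, config$n_gene), genes)
    if (n_ig > 0)
      delta_g[intrinsic_g] <- sample(c(-eff, eff), n_ig, replace = TRUE)
    log_g <- layer_log_matrix(mu_g, unname(delta_g), beta,
                              config$feature_noise_sd, genes,
                              tumor_s, control_s)

    # coupling: joint influence from true (noise-free) condition means
    true_gene_ctrl <- setNames(exp(mu_g), genes)
    true_m_ctrl <- setNames(exp(mu_m), mirnas)
    true_m_tum <- setNames(exp(mu_m + unname(delta_m)), mirnas)
    wnet <- compute_edge_weights(network, true_gene_ctrl)
    sc <- joint_influence_scores(wnet, true_m_ctrl, true_m_tum)
    rel <- setNames(rep(0, config$n_gene), genes)
    rel[sc$gene_id] <- sc$delta / pmax(sc$s_control, 1e-6)
    coupling_shift <- -config$coupling_strength * rel
    log_g[, tumor_s] <- log_g[, tumor_s] + unname(coupling_shift)
    delta_s <- setNames(rep(NA_real_, config$n_gene), genes)
    delta_s[sc$gene_id] <- sc$delta

    # --- protein layer -------------------------------------------------
    mapped_genes <- sample(genes, config$n_protein)
    n_dp <- round(config$fraction_deregulated[["protein"]] *
                    config$n_protein)
    delta_p <- setNames(rep(0, config$n_protein), prots)
    offset_p <- rnorm(config$n_protein, 0, 0.5)

    # --- genomic layout -------------------------------------------------
    hot <- NULL
    if (config$hotspot) {
      k <- config$hotspot_n_per_layer
      if (length(dereg_m) < k || length(intrinsic_g) < k)
        stop("hotspot needs at least hotspot_n_per_layer deregulated ",
             "miRNAs and intrinsic genes")
      hot_m <- sample(dereg_m, k)
      hot_g <- sample(intrinsic_g, k)
      # make sure the hotspot genes carry mapped proteins
      for (g in setdiff(hot_g, mapped_genes)) {
        replace_at <- which(!(mapped_genes %in% c(hot_g, targeted)))[1]
        mapped_genes[replace_at] <- g
      }
      hot <- list(mirnas = hot_m, genes = hot_g)
    }
    if (n_dp > 0) {
      dereg_p <- sample(prots, n_dp)
      delta_p[dereg_p] <- sample(c(-eff, eff), n_dp, replace = TRUE)
    }
    pg_map <- data.frame(protein_id = prots, gene_id = mapped_genes,
                         stringsAsFactors = FALSE)

    log_p <- log_g[mapped_genes, , drop = FALSE] + offset_p +
      matrix(rnorm(config$n_protein * 2 * config$n_patients, 0,
                   config$protein_noise_sd), config$n_protein)
    log_p[, tumor_s] <- log_p[, tumor_s] + unname(delta_p)
    rownames(log_p) <- prots

    annotation <- tile_annotation(mirnas, genes, pg_map,
                                  config$chrom_lengths, hot,
                                  config$hotspot_width)

    # --- ground truth ---------------------------------------------------
    gene_shift <- unname(delta_g) + unname(coupling_shift)
    prot_shift <- gene_shift[match(mapped_genes, genes)] + unname(delta_p)
    truth <- data.frame(
      feature_id = c(mirnas, genes, prots),
      omics_kind = rep(OMICS_KINDS, c(config$n_mirna, config$n_gene,
                                      config$n_protein)),
      true_direction = c(shift_direction(unname(delta_m)),
                         shift_direction(gene_shift),
                         shift_direction(prot_shift)),
      true_shift_ln = c(unname(delta_m), gene_shift, prot_shift),
      delta_s = c(rep(NA_real_, config$n_mirna), unname(delta_s),
                  rep(NA_real_, config$n_protein)),
      stringsAsFactors = FALSE
    )

    structure(list(
      layers = list(miRNA = expression_matrix(exp(log_m), "miRNA"),
                    mRNA = expression_matrix(exp(log_g), "mRNA"),
                    protein = expression_matrix(exp(log_p), "protein")),
      design = design,
      annotation = annotation,
      truth = truth,
      network = network,
      protein_gene_map = pg_map,
      chrom_lengths = config$chrom_lengths,
      config = config
    ), class = "sim_cohort")
  })
}

# Tile miRNA and gene features evenly over the genome (random order);
# proteins inherit the interval of their mapped gene. An optional hotspot
# packs the given features into the central 40% of one window on the
# longest chromosome.
tile_annotation <- function(mirnas, genes, pg_map, chrom_lengths, hot,
                            hotspot_width) {
  widths <- c(setNames(rep(200, length(mirnas)), mirnas),
              setNames(rep(5000, length(genes)), genes))
  feats <- sample(c(mirnas, genes))
  total <- sum(chrom_lengths)
  offsets <- chromosome_offsets(chrom_lengths)
  gap <- floor(total / (length(feats) + 1))
  global_mid <- gap * seq_along(feats)
  chrom_idx <- findInterval(global_mid, unname(offsets))
  chrom <- names(offsets)[chrom_idx]
  local_mid <- global_mid - unname(offsets)[chrom_idx]
  w <- unname(widths[feats])
  start <- pmax(1, local_mid - floor(w / 2))
  end <- start + w - 1
  over <- end > chrom_lengths[chrom]
  start[over] <- chrom_lengths[chrom][over] - w[over] + 1
  end[over] <- chrom_lengths[chrom][over]
  ann <- data.frame(
    feature_id = feats,
    omics_kind = ifelse(feats %in% mirnas, "miRNA", "mRNA"),
    chromosome = chrom, start = start, end = end,
    stringsAsFactors = FALSE)

  if (!is.null(hot)) {
    target_chrom <- names(chrom_lengths)[which.max(chrom_lengths)]
    span <- floor(0.4 * hotspot_width)
    h_start <- floor(chrom_lengths[[target_chrom]] / 2)
    members <- c(hot$mirnas, hot$genes)
    pos <- h_start + floor(span * seq_along(members) / (length(members) + 1))
    idx <- match(members, ann$feature_id)
    ann$chromosome[idx] <- target_chrom
    ann$start[idx] <- pos
    ann$end[idx] <- pos + unname(widths[members]) - 1
  }

  prot_ann <- ann[match(pg_map$gene_id, ann$feature_id), ]
  prot_ann$feature_id <- pg_map$protein_id
  prot_ann$omics_kind <- "protein"
  out <- rbind(ann, prot_ann)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort as a full pipeline input bundle
#'
#' Emits the three expression TSVs, the design TSV, per-layer BED
#' annotation files, the interaction TSV, the protein-gene map TSV and the
#' ground-truth TSV, all readable by the package's readers.
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of paths written, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'")
  paths <- c(
    mirna = file.path(out_dir, "expression_mirna.tsv"),
    mrna = file.path(out_dir, "expression_mrna.tsv"),
    protein = file.path(out_dir, "expression_protein.tsv"),
    design = file.path(out_dir, "design.tsv"),
    bed_mirna = file.path(out_dir, "features_mirna.bed"),
    bed_mrna = file.path(out_dir, "features_mrna.bed"),
    bed_protein = file.path(out_dir, "features_protein.bed"),
    interactions = file.path(out_dir, "interactions.tsv"),
    protein_gene_map = file.path(out_dir, "protein_gene_map.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_expression_matrix(cohort$layers$miRNA, paths[["mirna"]])
  write_expression_matrix(cohort$layers$mRNA, paths[["mrna"]])
  write_expression_matrix(cohort$layers$protein, paths[["protein"]])
  write_sample_design(cohort$design, paths[["design"]])
  ann <- cohort$annotation
  write_feature_annotation(ann[ann$omics_kind == "miRNA", ],
                           paths[["bed_mirna"]])
  write_feature_annotation(ann[ann$omics_kind == "mRNA", ],
                           paths[["bed_mrna"]])
  write_feature_annotation(ann[ann$omics_kind == "protein", ],
                           paths[["bed_protein"]])
  write_interaction_table(cohort$network, paths[["interactions"]])
  write_tsv(cohort$protein_gene_map[
    order(cohort$protein_gene_map$protein_id), ],
    paths[["protein_gene_map"]])
  write_tsv(cohort$truth[order(cohort$truth$feature_id), ],
            paths[["truth"]])
  invisible(paths)
}
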