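#' Read an expression matrix from TSV
#'
#' The file must have a header row whose first column holds feature
#' identifiers and whose remaining columns are sample identifiers; the body
#' must be numeric and nonnegative.
#'
#' @param path Path to a tab-separated file.
#' @param omics_kind One of `"miRNA"`, `"mRNA"`, `"protein"`.
#' @return A validated expression matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path, omics_kind) {
  df <- tryCatch(
    read.delim(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse expression TSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("expression file '", path, "' has no data")
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  not_numeric <- is.na(vals) & !is.na(body)
  if (any(not_numeric)) {
    bad <- which(not_numeric, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value for feature '%s', sample '%s'",
                 ids[bad[1]], colnames(body)[bad[2]]))
  }
  dimnames(vals) <- list(ids, colnames(body))
  expression_matrix(vals, omics_kind)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; rows are written sorted by feature
#' id so repeated runs are byte-identical.
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- x[order(rownames(x)), , drop = FALSE]
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a paired sample design from TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `condition`.
#' @return A validated design data frame (see [sample_design()]).
#' @export
read_sample_design <- function(path) {
  df <- read.delim(path, colClasses = "character")
  sample_design(df)
}

#' Write a sample design to TSV
#' @param design Validated design data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_design <- function(design, path) {
  design <- sample_design(design)
  write_tsv(design[order(design$sample_id), ], path)
}

# Strip an optional "chr" prefix and return labels in the canonical set,
# or NA for chromosomes outside 1..22/X/Y.
normalize_chromosome <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  ifelse(chrom %in% CHROMOSOMES, chrom, NA_character_)
}

#' Read a feature genomic annotation from BED
#'
#' Standard BED (0-based, half-open) is converted once at this boundary to
#' internal 1-based inclusive coordinates (`start = BED start + 1`,
#' `end = BED end`). The BED name field supplies the feature id. Records on
#' chromosomes outside 1..22/X/Y are skipped with a warning (an error in
#' strict mode).
#'
#' @param path Path to a BED file.
#' @param omics_kind One of `"miRNA"`, `"mRNA"`, `"protein"`.
#' @param strict If `TRUE`, unknown chromosomes are an error.
#' @return Data frame with columns `feature_id`, `omics_kind`, `chromosome`,
#'   `start`, `end`.
#' @export
read_feature_annotation <- function(path, omics_kind, strict = FALSE) {
  omics_kind <- match.arg(omics_kind, OMICS_KINDS)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1)) {
    bad <- gr$name[GenomicRanges::width(gr) < 1][1]
    stop("empty interval (BED start >= end) for feature '", bad, "'")
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    stop("BED name field (column 4) must supply feature ids")
  chrom <- normalize_chromosome(as.character(GenomicRanges::seqnames(gr)))
  if (anyNA(chrom)) {
    dropped <- nm[is.na(chrom)]
    if (strict)
      stop("chromosome outside 1..22/X/Y for: ",
           paste(dropped, collapse = ", "))
    sm_log("annotation: skipped ", length(dropped),
           " record(s) on non-canonical chromosomes")
  }
  keep <- !is.na(chrom)
  ann <- data.frame(
    feature_id = nm[keep],
    omics_kind = omics_kind,
    chromosome = chrom[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$feature_id) > 0)
    stop("duplicate feature id(s) in annotation: ",
         paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
               collapse = ", "))
  ann
}

#' Write a feature annotation to BED
#'
#' Converts internal 1-based inclusive coordinates back to BED's 0-based
#' half-open convention.
#'
#' @param annotation Annotation data frame (`feature_id`, `chromosome`,
#'   `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_annotation <- function(annotation, path) {
  ann <- annotation[order(annotation$feature_id), ]
  bed <- data.frame(chrom = paste0("chr", ann$chromosome),
                    start = ann$start - 1L,
                    end = ann$end,
                    name = ann$feature_id)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

SUPPORT_LEVELS <- c("functional_strong", "other")

#' Read a miRNA-to-gene interaction table from TSV
#'
#' Expects columns `mirna_id`, `gene_id`, `support` (values
#' `functional_strong` for interactions validated by functional assays, else
#' `other`), in the style of a curated target database export. Duplicate
#' (miRNA, gene) pairs are collapsed keeping the strongest support level.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame of unique edges with columns `mirna_id`, `gene_id`,
#'   `support`.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  req <- c("mirna_id", "gene_id", "support")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("interaction table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("interaction table is empty")
  bad <- setdiff(unique(df$support), SUPPORT_LEVELS)
  if (length(bad) > 0)
    stop("unknown support level(s): ", paste(bad, collapse = ", "))
  interaction_table(df[, req])
}

# Collapse duplicate edges to the strongest support level and fix ordering.
interaction_table <- function(edges) {
  edges$support <- factor(edges$support, levels = SUPPORT_LEVELS)
  o <- order(edges$mirna_id, edges$gene_id, edges$support)
  edges <- edges[o, ]
  dup <- duplicated(edges[, c("mirna_id", "gene_id")])
  if (any(dup)) {
    sm_log("interactions: collapsed ", sum(dup),
           " duplicate pair(s) to strongest support")
    edges <- edges[!dup, ]
  }
  edges$support <- as.character(edges$support)
  rownames(edges) <- NULL
  edges
}

#' Write an interaction table to TSV
#' @param edges Interaction table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(edges, path) {
  write_tsv(edges[order(edges$mirna_id, edges$gene_id), ], path)
}

#' Read a protein-to-gene mapping from TSV
#'
#' @param path TSV with columns `protein_id`, `gene_id`. A protein may map
#'   to several genes and vice versa; exact duplicate pairs are dropped.
#' @return Data frame of unique (`protein_id`, `gene_id`) pairs.
#' @export
read_protein_gene_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  req <- c("protein_id", "gene_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("protein-gene map is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("protein-gene map is empty")
  df <- df[, req]
  dup <- duplicated(df)
  if (any(dup)) {
    sm_log("protein-gene map: dropped ", sum(dup), " duplicate pair(s)")
    df <- df[!dup, ]
  }
  df[order(df$protein_id, df$gene_id), ]
}

# Deterministic TSV writer used by all table outputs.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as SIF and GraphML
#'
#' Writes an edge table as a Cytoscape-compatible SIF file and as GraphML
#' (via igraph), with edges sorted by identifier so output is reproducible
#' byte-for-byte. Additional edge columns become edge attributes in the
#' GraphML export.
#'
#' @param edges Data frame whose first two columns are node identifiers;
#'   an optional `interaction` column sets the SIF relation type.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.sif` and `<prefix>.graphml`.
#' @param interaction Default relation label when no `interaction` column
#'   is present.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_network <- function(edges, path_prefix, interaction = "interacts") {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    edges <- edges[order(edges[[1]], edges[[2]]), , drop = FALSE]
  }
  rel <- if ("interaction" %in% names(edges)) edges$interaction
         else rep(interaction, nrow(edges))
  sif <- file.path(paste0(path_prefix, ".sif"))
  writeLines(if (nrow(edges) > 0)
               paste(edges[[1]], rel, edges[[2]], sep = "\t")
             else character(0), sif)
  gml <- file.path(paste0(path_prefix, ".graphml"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(sif, gml))
}

#' Read a SIF network back as an edge table
#' @param path Path to a SIF file.
#' @return Data frame with columns `from`, `interaction`, `to` (zero rows
#'   for an empty network).
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(from = character(0), interaction = character(0),
                      to = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             interaction = vapply(parts, `[`, "", 2),
             to = vapply(parts, `[`, "", 3))
}

#' Write result tables and networks to a directory
#'
#' @param tables Named list of data frames; each is written as
#'   `<name>.tsv` with rows sorted by the first column.
#' @param networks Named list of edge tables; each is written as
#'   `<name>.sif` + `<name>.graphml` via [write_network()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(tables = list(), networks = list(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'")
  written <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    if (nrow(df) > 0) df <- df[order(df[[1]]), , drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(df, p)
    written <- c(written, p)
  }
  for (nm in names(networks)) {
    written <- c(written,
                 write_network(networks[[nm]], file.path(out_dir, nm)))
  }
  invisible(written)
}
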