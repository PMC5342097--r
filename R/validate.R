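#' Construct and validate an expression matrix
#'
#' An expression matrix holds nonnegative, finite abundance values on the
#' linear scale for one omics layer, with unique feature identifiers as row
#' names and unique sample identifiers as column names. The layer is carried
#' in the `omics_kind` attribute.
#'
#' @param values Numeric matrix (features x samples) with dimnames.
#' @param omics_kind One of `"miRNA"`, `"mRNA"`, `"protein"`.
#' @return The validated matrix with its `omics_kind` attribute set.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), "mRNA")
#' omics_kind(m)
expression_matrix <- function(values, omics_kind) {
  omics_kind <- match.arg(omics_kind, OMICS_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0)
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)) > 0)
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value for feature '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  attr(values, "omics_kind") <- omics_kind
  values
}

#' Omics layer of an expression matrix
#' @param x An expression matrix created by [expression_matrix()] or a reader.
#' @return `"miRNA"`, `"mRNA"` or `"protein"` (or `NULL` if unset).
#' @export
omics_kind <- function(x) attr(x, "omics_kind")

#' Construct and validate a paired sample design
#'
#' Enforces the matched-pairs structure of the cohort: every patient
#' contributes exactly one tumor and one matched control sample.
#'
#' @param design Data frame with columns `sample_id`, `patient_id`,
#'   `condition` (values `"tumor"` / `"control"`).
#' @return The validated design data frame.
#' @export
sample_design <- function(design) {
  req <- c("sample_id", "patient_id", "condition")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design)[, req]
  design[] <- lapply(design, as.character)
  if (anyDuplicated(design$sample_id) > 0)
    stop("duplicate sample_id in design")
  bad <- setdiff(unique(design$condition), c("tumor", "control"))
  if (length(bad) > 0)
    stop("condition labels must be 'tumor' or 'control'; found: ",
         paste(bad, collapse = ", "))
  tab <- table(design$patient_id, design$condition)
  if (!all(dim(tab) == c(nrow(tab), 2)) || any(tab != 1)) {
    offender <- rownames(tab)[apply(tab != 1, 1, any)][1]
    stop(sprintf(
      "patient '%s' does not have exactly one tumor and one control sample",
      offender))
  }
  design
}

# Check that all matrix samples appear in the design; returns the design
# rows matching the matrix columns.
match_design <- function(x, design) {
  design <- sample_design(design)
  missing <- setdiff(colnames(x), design$sample_id)
  if (length(missing) > 0)
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design[match(colnames(x), design$sample_id), , drop = FALSE]
}

# Tumor/control column indices ordered by patient, for paired statistics.
paired_indices <- function(x, design) {
  d <- match_design(x, design)
  patients <- sort(unique(d$patient_id))
  tum <- match(paste0(patients, ".tumor"),
               paste0(d$patient_id, ".", d$condition))
  ctl <- match(paste0(patients, ".control"),
               paste0(d$patient_id, ".", d$condition))
  if (anyNA(tum) || anyNA(ctl))
    stop("design pairs not fully represented in the matrix columns")
  list(patients = patients, tumor = tum, control = ctl)
}
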