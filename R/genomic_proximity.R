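# Cumulative chromosome offsets (bases preceding each chromosome) in the
# canonical order 1..22, X, Y.
chromosome_offsets <- function(chrom_lengths) {
  chrom_lengths <- chrom_lengths[CHROMOSOMES[CHROMOSOMES %in%
                                               names(chrom_lengths)]]
  setNames(cumsum(c(0, unname(chrom_lengths)))[seq_along(chrom_lengths)],
           names(chrom_lengths))
}

#' Linearize genomic coordinates
#'
#' Maps every annotated feature onto a single global axis running 1..~3e9:
#' chromosomes are concatenated in the order 1..22, X, Y and each feature
#' is placed at its interval midpoint (`floor((start + end) / 2)`) plus the
#' cumulative length of the preceding chromosomes.
#'
#' @param annotation Annotation data frame (`feature_id`, `omics_kind`,
#'   `chromosome`, `start`, `end`; 1-based inclusive).
#' @param chrom_lengths Named chromosome lengths; defaults to
#'   [hs_chromosome_lengths()].
#' @return Data frame with columns `feature_id`, `omics_kind`,
#'   `chromosome`, `midpoint`, `global_position`; chromosome lengths and
#'   offsets are carried in attributes.
#' @export
linearize <- function(annotation, chrom_lengths = hs_chromosome_lengths()) {
  chrom <- normalize_chromosome(annotation$chromosome)
  if (anyNA(chrom))
    stop("non-canonical chromosome for: ",
         paste(annotation$feature_id[is.na(chrom)], collapse = ", "))
  missing_len <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(missing_len) > 0)
    stop("no length known for chromosome(s): ",
         paste(missing_len, collapse = ", "))
  midpoint <- floor((annotation$start + annotation$end) / 2)
  beyond <- annotation$end > chrom_lengths[chrom]
  if (any(beyond))
    stop("feature(s) beyond chromosome length: ",
         paste(annotation$feature_id[beyond], collapse = ", "))
  offsets <- chromosome_offsets(chrom_lengths)
  pos <- data.frame(
    feature_id = annotation$feature_id,
    omics_kind = annotation$omics_kind,
    chromosome = chrom,
    midpoint = midpoint,
    global_position = unname(offsets[chrom]) + midpoint,
    stringsAsFactors = FALSE
  )
  attr(pos, "chrom_lengths") <- chrom_lengths
  attr(pos, "offsets") <- offsets
  pos
}

#' Scan the linearized genome with a sliding window
#'
#' Shifts a window of `window_size` bases along the global axis in steps of
#' `step` bases and counts, for each window position, the significant
#' features of each omics kind whose midpoint falls inside the half-open
#' window `[w, w + window_size)`.
#'
#' @param positions Linearized positions from [linearize()].
#' @param significant Character vector of significant feature ids, or a
#'   logical vector aligned with `positions`.
#' @param window_size Window width in bases (default 1e6).
#' @param step Shift between consecutive windows (default 5e5; set equal to
#'   `window_size` for non-overlapping tiling).
#' @return A `window_scan` object: list with `windows` (data frame of
#'   window start/end and per-kind counts), the significant positions, and
#'   the scan geometry.
#' @export
scan_windows <- function(positions, significant, window_size = 1e6,
                         step = 5e5) {
  if (window_size <= 0 || step <= 0)
    stop("window_size and step must be positive")
  if (is.logical(significant)) {
    stopifnot(length(significant) == nrow(positions))
    sig <- positions[significant, , drop = FALSE]
  } else {
    sig <- positions[positions$feature_id %in% significant, , drop = FALSE]
  }
  chrom_lengths <- attr(positions, "chrom_lengths")
  genome_length <- sum(chrom_lengths)
  starts <- seq(1, genome_length, by = step)
  counts <- sapply(OMICS_KINDS, function(kind) {
    sp <- sort(sig$global_position[sig$omics_kind == kind])
    findInterval(starts + window_size - 0.5, sp) -
      findInterval(starts - 0.5, sp)
  })
  if (length(starts) == 1) counts <- matrix(counts, nrow = 1,
                                            dimnames = list(NULL, OMICS_KINDS))
  windows <- data.frame(start = starts,
                        end = pmin(starts + window_size, genome_length + 1))
  windows$n_miRNA <- counts[, "miRNA"]
  windows$n_mRNA <- counts[, "mRNA"]
  windows$n_protein <- counts[, "protein"]
  windows$n_total <- rowSums(counts)
  structure(list(windows = windows, significant = sig,
                 window_size = window_size, step = step,
                 chrom_lengths = chrom_lengths,
                 offsets = chromosome_offsets(chrom_lengths)),
            class = "window_scan")
}

# Count significant features of the scan inside a half-open global span.
count_span <- function(scan, start, end) {
  inside <- scan$significant$global_position >= start &
    scan$significant$global_position < end
  members <- scan$significant[inside, , drop = FALSE]
  list(members = members,
       n = table(factor(members$omics_kind, levels = OMICS_KINDS)))
}

#' Select co-enriched genomic regions from a window scan
#'
#' A window qualifies when it holds at least one significant miRNA, one
#' significant mRNA and one significant protein, and at least `min_total`
#' significant features overall. Overlapping or adjacent qualifying windows
#' are merged into maximal regions; merged spans are split at chromosome
#' boundaries and each piece is kept only if it still meets both criteria.
#'
#' @param scan A `window_scan` object from [scan_windows()].
#' @param min_total Minimum total number of significant features in a
#'   window (default 11, i.e. more than 10).
#' @return Data frame of regions: `chromosome`, `start`, `end` (1-based
#'   inclusive, chromosome-local), per-kind counts, `n_total`, and a
#'   semicolon-joined `members` column of feature ids.
#' @export
select_regions <- function(scan, min_total = 11) {
  w <- scan$windows
  qual <- w$n_miRNA >= 1 & w$n_mRNA >= 1 & w$n_protein >= 1 &
    w$n_total >= min_total
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), n_miRNA = integer(0),
                      n_mRNA = integer(0), n_protein = integer(0),
                      n_total = integer(0), members = character(0))
  if (!any(qual)) return(empty)
  q <- w[qual, , drop = FALSE]
  q <- q[order(q$start), ]
  # merge overlapping/adjacent half-open windows into maximal spans
  spans <- list(c(q$start[1], q$end[1]))
  for (i in seq_len(nrow(q))[-1]) {
    last <- spans[[length(spans)]]
    if (q$start[i] <= last[2]) {
      spans[[length(spans)]][2] <- max(last[2], q$end[i])
    } else {
      spans[[length(spans) + 1]] <- c(q$start[i], q$end[i])
    }
  }
  offsets <- scan$offsets
  bounds <- data.frame(chrom = names(offsets),
                       g_start = unname(offsets) + 1,
                       g_end = unname(offsets) +
                         unname(scan$chrom_lengths[names(offsets)]))
  out <- list()
  for (span in spans) {
    hit <- bounds[bounds$g_end >= span[1] & bounds$g_start < span[2], ,
                  drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      s <- max(span[1], hit$g_start[k])
      e <- min(span[2], hit$g_end[k] + 1) # half-open
      cs <- count_span(scan, s, e)
      if (all(cs$n >= 1) && sum(cs$n) >= min_total) {
        out[[length(out) + 1]] <- data.frame(
          chromosome = hit$chrom[k],
          start = s - offsets[hit$chrom[k]],
          end = e - 1 - offsets[hit$chrom[k]],
          n_miRNA = unname(cs$n["miRNA"]),
          n_mRNA = unname(cs$n["mRNA"]),
          n_protein = unname(cs$n["protein"]),
          n_total = sum(cs$n),
          members = paste(sort(cs$members$feature_id), collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot-ready Manhattan table
#'
#' One row per annotated feature with its global position and the negative
#' decade logarithm of the chosen adjusted p-value; zero p-values are
#' clamped to the smallest positive double before the log.
#'
#' @param results One differential result table or a list of them (one per
#'   omics layer).
#' @param positions Linearized positions from [linearize()].
#' @param method Which p-value to plot: `"bonferroni"` (default), `"BH"`
#'   or `"raw"`.
#' @return Data frame with `feature_id`, `omics_kind`, `global_position`,
#'   `p_adjusted`, `neg_log10_p`.
#' @export
manhattan_table <- function(results, positions, method = "bonferroni") {
  if (is.data.frame(results)) results <- list(results)
  col <- p_column(method)
  res <- do.call(rbind, lapply(results, function(r)
    r[, c("feature_id", col)]))
  m <- merge(positions[, c("feature_id", "omics_kind", "global_position")],
             res, by = "feature_id")
  p <- pmax(m[[col]], .Machine$double.xmin)
  data.frame(feature_id = m$feature_id,
             omics_kind = m$omics_kind,
             global_position = m$global_position,
             p_adjusted = m[[col]],
             neg_log10_p = -log10(p))
}
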