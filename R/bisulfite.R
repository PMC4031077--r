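# RRBS-style island aggregation. Two coverage filters are applied in
# sequence: a per-CpG minimum total read depth (default 5 reads) and a
# per-island minimum number of surviving CpGs (default 3). Island percent
# is the unweighted mean of the included per-CpG percents, so every CpG
# carries equal weight regardless of its depth.

#' Per-CpG percent methylation with a read-depth filter
#'
#' @param counts CpG count data.frame (`meth`, `total`).
#' @param min_reads Minimum total reads for a CpG to be included
#'   (default 5); the depth filter is on total reads, not methylated reads.
#' @return `counts` with `percent` (NA when excluded) and `included`
#'   columns added.
#' @export
cpg_percent <- function(counts, min_reads = 5L) {
  validate_cpg_counts(counts)
  counts$included <- counts$total >= min_reads
  counts$percent <- ifelse(counts$included,
                           100 * counts$meth / counts$total, NA_real_)
  counts
}

#' Island-level percent methylation
#'
#' Averages the included per-CpG percents within each island; islands with
#' fewer than `min_cpgs` included CpGs are excluded from the output.
#'
#' @param counts CpG count data.frame already passed through
#'   [cpg_percent()] (columns `percent`, `included`).
#' @param assignment Island assignment per CpG row (from
#'   [map_features_to_islands()]).
#' @param min_cpgs Minimum number of included CpGs per island (default 3).
#' @param sample_id Optional sample label.
#' @return data.frame with `island_id`, `sample_id`, `percent`,
#'   `n_cpgs_covered`.
#' @export
island_percent <- function(counts, assignment, min_cpgs = 3L,
                           sample_id = NA_character_) {
  stopifnot(length(assignment) == nrow(counts))
  if (is.null(counts$included))
    stop("run cpg_percent() before island_percent()", call. = FALSE)
  keep <- counts$included & assignment != BACKGROUND_KEY
  if (!any(keep)) {
    return(data.frame(island_id = character(), sample_id = character(),
                      percent = numeric(), n_cpgs_covered = integer()))
  }
  id <- assignment[keep]
  pct <- counts$percent[keep]
  out <- data.frame(island_id = names(tapply(pct, id, mean)),
                    sample_id = sample_id,
                    percent = as.numeric(tapply(pct, id, mean)),
                    n_cpgs_covered = as.integer(tapply(pct, id, length)),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cpgs_covered >= min_cpgs, , drop = FALSE]
  out <- out[order(out$island_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score an RRBS sample end to end
#'
#' Convenience wrapper: maps CpGs to islands, applies the per-CpG read
#' filter and the per-island CpG-count filter.
#'
#' @param counts Raw CpG count data.frame.
#' @param islands Validated island data.frame.
#' @inheritParams cpg_percent
#' @inheritParams island_percent
#' @return See [island_percent()].
#' @export
score_rrbs <- function(counts, islands, min_reads = 5L, min_cpgs = 3L,
                       sample_id = NA_character_) {
  mapping <- map_features_to_islands(counts, islands)
  island_percent(cpg_percent(counts, min_reads), mapping$assignment,
                 min_cpgs, sample_id)
}

#' Summarize a per-molecule amplicon bisulfite matrix
#'
#' Rows are sequenced molecules, columns CpG positions; entries are 1
#' (methylated), 0 (unmethylated) or NA (missing). Per-CpG percents are
#' taken over non-missing entries and the island percent is the mean of
#' the per-CpG percents, so each CpG position carries equal weight.
#'
#' @param mat Numeric/logical matrix of molecule calls.
#' @param island_id Optional island label.
#' @return List with `per_cpg` (percent per CpG column), `island_percent`,
#'   `n_molecules`, and `long` (plotting-ready long-format data.frame with
#'   `island_id`, `molecule_id`, `cpg_index`, `state`).
#' @export
amplicon_summary <- function(mat, island_id = NA_character_) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 1 || ncol(mat) < 1)
    stop("empty molecule matrix", call. = FALSE)
  bad <- !(mat %in% c(0, 1, NA))
  if (any(bad)) stop("molecule matrix entries must be 0, 1 or NA",
                     call. = FALSE)
  per_cpg <- 100 * colMeans(mat, na.rm = TRUE)
  per_cpg[colSums(!is.na(mat)) == 0] <- NA_real_
  island_pct <- mean(per_cpg, na.rm = TRUE)
  long <- data.frame(island_id = island_id,
                     molecule_id = rep(seq_len(nrow(mat)), ncol(mat)),
                     cpg_index = rep(seq_len(ncol(mat)),
                                     each = nrow(mat)),
                     state = as.vector(mat), stringsAsFactors = FALSE)
  list(per_cpg = unname(per_cpg), island_percent = island_pct,
       n_molecules = nrow(mat), long = long)
}
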