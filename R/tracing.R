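# Developmental tracing: the constitutively unmethylated background set is
# defined from a normal-tissue panel, and excess (aberrant) methylation in
# test samples is called against it. Both thresholds are strict
# inequalities: "unmethylated" means value < constitutive_max in every
# tissue sample, "aberrant" means value > aberrant_min in at least
# min_test_samples_hit test samples.

#' Tracing configuration
#'
#' Default thresholds depend on the measurement scale: IMS mode uses
#' constitutive < 0 and aberrant > 0.75; percent mode uses
#' constitutive < 20 and aberrant > 60.
#'
#' @param mode `"ims"` (default) or `"percent"`.
#' @param constitutive_max Upper threshold (strict) for the background set.
#' @param aberrant_min Lower threshold (strict) for an aberrant call.
#' @param min_test_samples_hit Minimum number of test samples above
#'   `aberrant_min` (default 1).
#' @return A `tracing_config` list.
#' @export
tracing_config <- function(mode = c("ims", "percent"),
                           constitutive_max = NULL, aberrant_min = NULL,
                           min_test_samples_hit = 1L) {
  mode <- match.arg(mode)
  if (is.null(constitutive_max))
    constitutive_max <- if (mode == "ims") 0 else 20
  if (is.null(aberrant_min))
    aberrant_min <- if (mode == "ims") 0.75 else 60
  if (!(aberrant_min > constitutive_max))
    stop("aberrant_min must exceed constitutive_max", call. = FALSE)
  structure(list(mode = mode, constitutive_max = constitutive_max,
                 aberrant_min = aberrant_min,
                 min_test_samples_hit = as.integer(min_test_samples_hit)),
            class = "tracing_config")
}

role_columns <- function(matrix, roles, role) {
  ids <- roles$sample_id[roles$role == role]
  intersect(colnames(matrix), ids)
}

#' Constitutively unmethylated background set
#'
#' Islands whose value is strictly below `constitutive_max` in every
#' tissue-panel sample. Islands with any missing tissue value are excluded:
#' "constitutively" unmethylated requires evidence in all panel members.
#'
#' @param matrix Islands-by-samples numeric matrix (see [build_matrix()]).
#' @param roles Sample-role manifest (see [sample_roles()]).
#' @param config A [tracing_config()].
#' @return Character vector of island ids.
#' @export
constitutive_set <- function(matrix, roles, config = tracing_config()) {
  tissue <- role_columns(matrix, roles, "tissue")
  if (!length(tissue)) stop("no tissue samples in manifest", call. = FALSE)
  sub <- matrix[, tissue, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0 &
    rowSums(sub < config$constitutive_max) == length(tissue)
  rownames(matrix)[which(ok)]
}

#' Call aberrantly methylated islands against the background set
#'
#' Within the background set, an island is aberrant when its value is
#' strictly above `aberrant_min` in at least `min_test_samples_hit` test
#' (`es_test`) samples; missing test values count as non-hits.
#'
#' @inheritParams constitutive_set
#' @param background Character vector of background island ids (from
#'   [constitutive_set()]).
#' @return A `tracing_result` list: `background_set`, `aberrant_set`,
#'   `calls` (per-island, per-test-sample 0/1), `config`.
#' @export
aberrant_set <- function(matrix, roles, background,
                         config = tracing_config()) {
  if (!length(background)) stop("empty background set", call. = FALSE)
  test <- role_columns(matrix, roles, "es_test")
  if (!length(test)) stop("no es_test samples in manifest", call. = FALSE)
  background <- intersect(rownames(matrix), background)
  sub <- matrix[background, test, drop = FALSE]
  hits <- !is.na(sub) & sub > config$aberrant_min
  aberrant <- background[rowSums(hits) >= config$min_test_samples_hit]
  calls <- data.frame(island_id = rep(background, length(test)),
                      sample_id = rep(test, each = length(background)),
                      call = as.integer(hits), stringsAsFactors = FALSE)
  structure(list(background_set = background, aberrant_set = aberrant,
                 calls = calls, config = config),
            class = "tracing_result")
}

#' Compare a tracing result against planted truth
#'
#' @param result A `tracing_result` from [aberrant_set()].
#' @param truth_ids Island ids truly carrying planted aberrant
#'   methylation.
#' @return List with TP/FP/FN counts, `sensitivity` (TP / planted) and
#'   `fdr` (FP / called; 0 when nothing is called).
#' @export
evaluate_tracing <- function(result, truth_ids) {
  called <- result$aberrant_set
  tp <- length(intersect(called, truth_ids))
  fp <- length(setdiff(called, truth_ids))
  fn <- length(setdiff(truth_ids, called))
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (length(truth_ids)) tp / length(truth_ids) else
         NA_real_,
       fdr = if (length(called)) fp / length(called) else 0)
}

#' Tissue-specific methylated islands ("group B")
#'
#' Islands methylated (value > `aberrant_min`) in exactly one tissue
#' sample and unmethylated (value < `constitutive_max`) in all other
#' tissue samples. Islands with any missing tissue value are excluded.
#'
#' @inheritParams constitutive_set
#' @return Character vector of island ids.
#' @export
tissue_specific_set <- function(matrix, roles,
                                config = tracing_config("percent")) {
  tissue <- role_columns(matrix, roles, "tissue")
  if (length(tissue) < 2)
    stop("need at least 2 tissue samples", call. = FALSE)
  sub <- matrix[, tissue, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  high <- rowSums(sub > config$aberrant_min, na.rm = TRUE)
  low <- rowSums(sub < config$constitutive_max, na.rm = TRUE)
  ok <- complete & high == 1 & low == length(tissue) - 1
  rownames(matrix)[which(ok)]
}

#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail hypergeometric test for the overlap between two island sets
#' drawn from a common universe: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set_b|, n = |set_a|)`.
#' Computed in log space so extreme significance levels survive floating
#' point underflow; `log10_p` is reported alongside `p`.
#'
#' @param set_a,set_b Character vectors of island ids.
#' @param universe Character vector containing both sets.
#' @return List with `overlap` (k), `expected` (n*K/N), `fold`
#'   (k/expected), `p`, `log10_p`.
#' @export
hypergeom_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) ||
      length(setdiff(set_b, universe)))
    stop("sets must be subsets of the universe", call. = FALSE)
  N <- length(universe); K <- length(set_b); n <- length(set_a)
  k <- length(intersect(set_a, set_b))
  log_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE)
  expected <- n * K / N
  list(overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_,
       p = exp(log_p), log10_p = log_p / log(10))
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed, non-paired, equal-variance t-test
#' (`df = n_a + n_b - 2`). Degenerate inputs with zero pooled variance are
#' handled explicitly: equal means give `t = 0, p = 1`; unequal means give
#' `p = 0` with a warning. All other cases are delegated to
#' [stats::t.test()] with `var.equal = TRUE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
group_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2", call. = FALSE)
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; p = 0",
            call. = FALSE)
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Mean methylation difference between two culture conditions
#'
#' Per-island difference (condition A minus condition B) over a target
#' island set, with a seeded bootstrap percentile interval for the mean
#' difference. Islands missing from either condition are excluded and
#' counted.
#'
#' @inheritParams constitutive_set
#' @param target_set Island ids to compare.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling (default 1).
#' @return List with `mean_diff`, `ci` (length-2), `per_island`
#'   data.frame, `n_used`, `n_excluded`.
#' @export
compare_conditions <- function(matrix, roles, target_set, n_boot = 1000L,
                               conf = 0.95, seed = 1L) {
  ca <- role_columns(matrix, roles, "condition_a")
  cb <- role_columns(matrix, roles, "condition_b")
  if (!length(ca) || !length(cb))
    stop("need condition_a and condition_b samples", call. = FALSE)
  ids <- intersect(rownames(matrix), target_set)
  va <- rowMeans(matrix[ids, ca, drop = FALSE])
  vb <- rowMeans(matrix[ids, cb, drop = FALSE])
  use <- !is.na(va) & !is.na(vb)
  n_excluded <- length(target_set) - sum(use)
  if (!any(use)) stop("no usable islands in target set", call. = FALSE)
  d <- va[use] - vb[use]
  set.seed(seed)
  boot <- replicate(n_boot, mean(sample(d, replace = TRUE)))
  alpha <- (1 - conf) / 2
  list(mean_diff = mean(d),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       per_island = data.frame(island_id = ids[use], diff = unname(d),
                               stringsAsFactors = FALSE),
       n_used = sum(use), n_excluded = n_excluded)
}

#' Export an ordered heat-map matrix for an aberrant island set
#'
#' Rows are the aberrant islands ordered by decreasing mean test-sample
#' value (ties broken by island_id); columns are the tissue-panel samples
#' followed by the test samples. Values pass through unchanged.
#'
#' @param result A `tracing_result` from [aberrant_set()].
#' @inheritParams constitutive_set
#' @return Numeric matrix (possibly with zero rows).
#' @export
export_heatmap_matrix <- function(result, matrix, roles) {
  tissue <- role_columns(matrix, roles, "tissue")
  test <- role_columns(matrix, roles, "es_test")
  cols <- c(tissue, test)
  ids <- result$aberrant_set
  if (!length(ids))
    return(base::matrix(numeric(), 0, length(cols),
                        dimnames = list(character(), cols)))
  mean_test <- rowMeans(matrix[ids, test, drop = FALSE], na.rm = TRUE)
  ord <- order(-mean_test, ids)
  matrix[ids[ord], cols, drop = FALSE]
}
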