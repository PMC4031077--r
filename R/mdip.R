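# mDIP microarray scoring: bound/input (Cy5/Cy3) log ratios, melting-
# temperature stratified Z-normalization, and per-island IMS averaging.
# Ratio orientation is bound/input so a higher IMS means more methylation.

#' Normalization configuration for mDIP probe Z-scoring
#'
#' @param tm_bins Number of melting-temperature strata (default 20).
#' @param binning_mode `"equal_count"` (default; stabilizes the per-stratum
#'   sd estimate across the Tm distribution) or `"equal_width"`.
#' @param min_stratum_size Strata smaller than this are merged with the
#'   nearest Tm-adjacent stratum (default 50).
#' @param min_probes_per_island Islands with fewer usable probes are
#'   dropped from the IMS table (default 1).
#' @param low_probe_flag_threshold IMS records based on fewer probes than
#'   this are flagged (default 3).
#' @return A `normalization_config` list.
#' @export
normalization_config <- function(tm_bins = 20L,
                                 binning_mode = c("equal_count",
                                                  "equal_width"),
                                 min_stratum_size = 50L,
                                 min_probes_per_island = 1L,
                                 low_probe_flag_threshold = 3L) {
  binning_mode <- match.arg(binning_mode)
  tm_bins <- as.integer(tm_bins)
  min_stratum_size <- as.integer(min_stratum_size)
  stopifnot(tm_bins >= 1L, min_stratum_size >= 2L,
            min_probes_per_island >= 1L)
  structure(list(tm_bins = tm_bins, binning_mode = binning_mode,
                 min_stratum_size = min_stratum_size,
                 log_base = 2,
                 min_probes_per_island = as.integer(min_probes_per_island),
                 low_probe_flag_threshold =
                   as.integer(low_probe_flag_threshold)),
            class = "normalization_config")
}

#' Compute two-channel log ratios
#'
#' With `normalization = "median_scale"` the input channel is linearly
#' rescaled by (median bound)/(median input) over probes with both channels
#' positive, then `log_ratio = log2(bound / scaled input)`. Probes with a
#' non-positive channel (possible after background subtraction) get a
#' missing log ratio and are excluded downstream.
#'
#' @param probes Probe data.frame with `bound` and `input` columns.
#' @param normalization `"median_scale"` (default) or `"none"`.
#' @return `probes` with a `log_ratio` column added.
#' @export
compute_log_ratios <- function(probes,
                               normalization = c("median_scale", "none")) {
  normalization <- match.arg(normalization)
  ok <- !is.na(probes$bound) & !is.na(probes$input) &
    probes$bound > 0 & probes$input > 0
  if (sum(ok) < 2)
    stop("insufficient signal: fewer than 2 probes with both channels ",
         "positive", call. = FALSE)
  scale <- if (normalization == "median_scale")
    stats::median(probes$bound[ok]) / stats::median(probes$input[ok]) else 1
  probes$log_ratio <- ifelse(ok,
                             log2(probes$bound / (probes$input * scale)),
                             NA_real_)
  probes
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Assign Tm strata, then merge strata below min_stratum_size into the
# Tm-adjacent neighbour whose mean Tm is nearer (tie -> lower stratum).
tm_strata <- function(tm, config) {
  n <- length(tm)
  if (config$binning_mode == "equal_count") {
    ord <- order(tm, seq_along(tm))
    sizes <- rep(n %/% config$tm_bins, config$tm_bins)
    extra <- n %% config$tm_bins
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes <- sizes[sizes > 0]
    stratum <- integer(n)
    stratum[ord] <- rep(seq_along(sizes), times = sizes)
  } else {
    breaks <- seq(min(tm), max(tm), length.out = config$tm_bins + 1L)
    if (breaks[1] == breaks[length(breaks)]) {
      stratum <- rep(1L, n)
    } else {
      stratum <- as.integer(cut(tm, breaks, include.lowest = TRUE))
    }
  }
  repeat {
    sizes <- tabulate(stratum)
    levels_in_use <- which(sizes > 0)
    if (length(levels_in_use) <= 1) break
    small <- levels_in_use[sizes[levels_in_use] < config$min_stratum_size]
    if (!length(small)) break
    victim <- small[which.min(sizes[small])]
    pos <- match(victim, levels_in_use)
    neighbours <- c(if (pos > 1) levels_in_use[pos - 1],
                    if (pos < length(levels_in_use)) levels_in_use[pos + 1])
    means <- vapply(neighbours, function(l) mean(tm[stratum == l]),
                    numeric(1))
    target <- neighbours[which.min(abs(means - mean(tm[stratum == victim])))]
    stratum[stratum == victim] <- target
  }
  match(stratum, sort(unique(stratum)))
}

#' Tm-stratified Z-normalization of probe log ratios
#'
#' Probes are partitioned into melting-temperature strata (equal-count by
#' default); within each stratum `z = (log_ratio - mean) / sd` with the
#' population (ddof = 0) standard deviation. A stratum with zero sd gets
#' all-zero Z-scores. Probes with missing log ratios keep a missing
#' `z_score` and do not influence stratum statistics.
#'
#' @param probes Probe data.frame with `tm` and `log_ratio`.
#' @param config A [normalization_config()].
#' @return `probes` with `z_score` and `tm_stratum` columns added.
#' @export
tm_zscore <- function(probes, config = normalization_config()) {
  use <- !is.na(probes$log_ratio)
  if (!any(use)) stop("all log ratios missing", call. = FALSE)
  if (sum(use) < config$min_stratum_size)
    stop("too few probes with log ratios (need >= min_stratum_size = ",
         config$min_stratum_size, ")", call. = FALSE)
  stratum_use <- tm_strata(probes$tm[use], config)
  z <- rep(NA_real_, nrow(probes))
  stratum_all <- rep(NA_integer_, nrow(probes))
  stratum_all[use] <- stratum_use
  lr <- probes$log_ratio[use]
  zu <- numeric(length(lr))
  for (s in unique(stratum_use)) {
    idx <- stratum_use == s
    m <- mean(lr[idx])
    sd_s <- pop_sd(lr[idx])
    zu[idx] <- if (sd_s > 0) (lr[idx] - m) / sd_s else 0
  }
  z[use] <- zu
  probes$z_score <- z
  probes$tm_stratum <- stratum_all
  probes
}

#' Island Methylation Score (IMS)
#'
#' IMS is the arithmetic mean of the Z-scores of the probes mapped to an
#' island. Islands with fewer than `min_probes_per_island` usable probes
#' are omitted; records based on fewer than `low_probe_flag_threshold`
#' probes carry `low_probe_flag = TRUE`.
#'
#' @param probes Z-scored probe data.frame (see [tm_zscore()]).
#' @param assignment Character vector from [map_features_to_islands()]
#'   (island_id or `"background"` per probe).
#' @param config A [normalization_config()].
#' @param sample_id Optional sample label stored on each record.
#' @return data.frame with `island_id`, `sample_id`, `ims`,
#'   `n_probes_used`, `low_probe_flag`.
#' @export
island_methylation_score <- function(probes, assignment,
                                     config = normalization_config(),
                                     sample_id = NA_character_) {
  stopifnot(length(assignment) == nrow(probes))
  keep <- assignment != BACKGROUND_KEY & !is.na(probes$z_score)
  if (!any(keep)) {
    return(data.frame(island_id = character(), sample_id = character(),
                      ims = numeric(), n_probes_used = integer(),
                      low_probe_flag = logical()))
  }
  id <- assignment[keep]
  zz <- probes$z_score[keep]
  ims <- tapply(zz, id, mean)
  n <- as.integer(tapply(zz, id, length))
  out <- data.frame(island_id = names(ims), sample_id = sample_id,
                    ims = as.numeric(ims), n_probes_used = n,
                    low_probe_flag = n < config$low_probe_flag_threshold,
                    stringsAsFactors = FALSE)
  out <- out[out$n_probes_used >= config$min_probes_per_island, ,
             drop = FALSE]
  out <- out[order(out$island_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary methylation call from an IMS value
#'
#' An island is called methylated (1) iff `ims > threshold`, with a strict
#' inequality: an IMS exactly at the threshold is called 0.
#'
#' @param ims Numeric vector of IMS values.
#' @param threshold Call threshold (default 0.75).
#' @return Integer vector of 0/1 calls (NA propagates).
#' @export
binary_call <- function(ims, threshold = 0.75) {
  as.integer(ims > threshold)
}

#' Calibrate IMS to an estimated percent methylation
#'
#' Fits an ordinary least-squares line through `(ims, percent)` calibration
#' pairs and predicts percent methylation for query IMS values, clamped to
#' the 0-100 scale.
#'
#' @param calibration data.frame with `ims` and `percent` columns (at least
#'   2 pairs with distinct IMS).
#' @param ims Query IMS values.
#' @return Numeric vector of percent estimates in `[0, 100]`.
#' @export
ims_to_percent <- function(calibration, ims) {
  stopifnot(all(c("ims", "percent") %in% names(calibration)))
  if (nrow(calibration) < 2 || length(unique(calibration$ims)) < 2)
    stop("degenerate calibration: need >= 2 pairs with distinct ims",
         call. = FALSE)
  fit <- stats::lm(percent ~ ims, data = calibration)
  pred <- stats::predict(fit, newdata = data.frame(ims = ims))
  pmin(pmax(unname(pred), 0), 100)
}

#' Assemble an islands-by-samples methylation matrix
#'
#' Stacks per-sample score records (IMS or percent) into a numeric matrix
#' with islands as rows and samples as columns; missing combinations
#' become `NA`.
#'
#' @param records data.frame with `island_id`, `sample_id` and a value
#'   column.
#' @param value Name of the value column (default `"ims"`).
#' @return Numeric matrix with island_id rownames and sample_id colnames.
#' @export
build_matrix <- function(records, value = "ims") {
  ids <- sort(unique(records$island_id))
  samples <- unique(records$sample_id)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(records$island_id, ids),
          match(records$sample_id, samples))] <- records[[value]]
  m
}

#' Sample-role manifest
#'
#' @param sample_id Character vector of sample names.
#' @param role One of `tissue`, `es_test`, `condition_a`, `condition_b`
#'   per sample.
#' @param assay One of `mdip`, `rrbs`, `amplicon` per sample.
#' @return data.frame manifest.
#' @export
sample_roles <- function(sample_id, role, assay = "mdip") {
  bad <- setdiff(unique(role),
                 c("tissue", "es_test", "condition_a", "condition_b"))
  if (length(bad)) stop("unknown sample role: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(assay), c("mdip", "rrbs", "amplicon"))
  if (length(bad)) stop("unknown assay: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in role manifest", call. = FALSE)
  data.frame(sample_id = sample_id, role = role, assay = assay,
             stringsAsFactors = FALSE)
}
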