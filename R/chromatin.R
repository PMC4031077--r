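# Chromatin-mark density per CpG island. Background is the all-island
# average of the raw density score; "above background" for the polycomb
# gate means normalized density strictly greater than 2, i.e. twice the
# all-island mean.

#' Background-normalized island chromatin density
#'
#' Normalizes per-island raw density scores to the all-island background,
#' taken as the arithmetic mean of the raw scores. With
#' `background_mode = "ratio"` (default) `norm_density = raw / background`,
#' so the normalized densities average exactly 1; with `"subtract"` the
#' background is subtracted instead.
#'
#' When a `mark` column is present, normalization is carried out within
#' each mark separately.
#'
#' @param scores data.frame with `island_id`, `raw_score` and optionally
#'   `mark`.
#' @param background_mode `"ratio"` (default) or `"subtract"`.
#' @return `scores` with a `norm_density` column added.
#' @export
island_density <- function(scores, background_mode = c("ratio",
                                                       "subtract")) {
  background_mode <- match.arg(background_mode)
  stopifnot(all(c("island_id", "raw_score") %in% names(scores)))
  if (!nrow(scores)) stop("no island density scores", call. = FALSE)
  norm_one <- function(raw) {
    bg <- mean(raw)
    if (background_mode == "ratio") {
      if (bg <= 0)
        stop("all-island background density is not positive",
             call. = FALSE)
      raw / bg
    } else {
      raw - bg
    }
  }
  if ("mark" %in% names(scores)) {
    scores$norm_density <- stats::ave(scores$raw_score, scores$mark,
                                      FUN = norm_one)
  } else {
    scores$norm_density <- norm_one(scores$raw_score)
  }
  scores
}

#' Flag islands above background density
#'
#' `above_background = norm_density > threshold` with a strict inequality:
#' an island exactly at the threshold is not flagged.
#'
#' @param records Output of [island_density()].
#' @param threshold Normalized-density threshold (default 2, i.e. twice
#'   the all-island mean).
#' @return `records` with an `above_background` column added.
#' @export
flag_above_background <- function(records, threshold = 2) {
  if (is.null(records$norm_density))
    stop("run island_density() before flag_above_background()",
         call. = FALSE)
  records$above_background <- records$norm_density > threshold
  records
}

profile_curve <- function(bin_id, bin_lo, bin_hi, density, meth) {
  split_d <- split(density, bin_id)
  split_m <- split(meth, bin_id)
  data.frame(bin_id = as.integer(names(split_d)),
             bin_lo = bin_lo, bin_hi = bin_hi,
             mean_density = vapply(split_d, mean, numeric(1)),
             mean_meth = vapply(split_m, mean, numeric(1)),
             n = vapply(split_d, length, integer(1)),
             row.names = NULL)
}

#' Methylation profile over fixed-width density windows
#'
#' Bins islands into fixed-width windows `[0, w), [w, 2w), ...` on the
#' density axis and reports the mean methylation (IMS or percent) per
#' window; empty windows are omitted. The windows apply to whichever
#' density scale (raw or background-normalized) is supplied.
#'
#' @param meth Per-island methylation values.
#' @param density Per-island density values (same order).
#' @param span_width Window width in density units (default 5).
#' @return Profile data.frame (`bin_id`, `bin_lo`, `bin_hi`,
#'   `mean_density`, `mean_meth`, `n`).
#' @export
profile_by_span <- function(meth, density, span_width = 5) {
  stopifnot(length(meth) == length(density), span_width > 0)
  keep <- !is.na(meth) & !is.na(density)
  meth <- meth[keep]; density <- density[keep]
  if (!length(meth)) stop("no paired methylation/density values",
                          call. = FALSE)
  bin <- floor(density / span_width)
  ord <- order(bin)
  bin <- bin[ord]; meth <- meth[ord]; density <- density[ord]
  lo <- sort(unique(bin)) * span_width
  out <- profile_curve(bin, lo, lo + span_width, density, meth)
  out$bin_id <- seq_len(nrow(out))
  out
}

#' Methylation profile over equal-count density bins
#'
#' Partitions islands into `n_bins` equal-count bins by density rank
#' (bin sizes differ by at most one); rank ties are broken by `island_id`
#' so the binning is deterministic and order-independent. Reports the mean
#' density and mean methylation per bin.
#'
#' @param meth Per-island methylation values.
#' @param density Per-island density values.
#' @param island_id Optional island labels used for deterministic
#'   tie-breaking (defaults to input order).
#' @param n_bins Number of bins (default 10).
#' @return Profile data.frame as in [profile_by_span()] (with `bin_lo` /
#'   `bin_hi` as the min/max density inside the bin).
#' @export
profile_by_decile <- function(meth, density, island_id = NULL,
                              n_bins = 10L) {
  stopifnot(length(meth) == length(density))
  if (is.null(island_id)) island_id <- sprintf("%09d", seq_along(meth))
  keep <- !is.na(meth) & !is.na(density)
  meth <- meth[keep]; density <- density[keep]
  island_id <- island_id[keep]
  n <- length(meth)
  if (n < n_bins)
    stop("need at least n_bins = ", n_bins, " islands, got ", n,
         call. = FALSE)
  ord <- order(density, island_id)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  lo <- vapply(split(density, bin), min, numeric(1))
  hi <- vapply(split(density, bin), max, numeric(1))
  profile_curve(bin, unname(lo), unname(hi), density, meth)
}

#' H3K4me3 protection curve on polycomb-gated islands
#'
#' Restricts to islands passing the H3K27me3 above-background gate and
#' profiles their methylation against H3K4me3 density in equal-count bins.
#' The effective bin count is capped by the number of gated islands and
#' the number of distinct H3K4me3 densities among them (so a degenerate
#' all-equal input yields a single bin).
#'
#' @param meth Per-island methylation values.
#' @param k4_density Per-island H3K4me3 density values.
#' @param gate Logical vector: island passes the H3K27me3 gate (from
#'   [flag_above_background()]).
#' @param island_id Optional labels for deterministic tie-breaking.
#' @param n_bins Maximum number of bins (default 10).
#' @return Profile data.frame as in [profile_by_decile()].
#' @export
protection_curve <- function(meth, k4_density, gate, island_id = NULL,
                             n_bins = 10L) {
  stopifnot(length(meth) == length(k4_density),
            length(gate) == length(meth))
  if (!any(gate, na.rm = TRUE))
    stop("no islands pass the H3K27me3 gate", call. = FALSE)
  sel <- which(gate)
  if (is.null(island_id)) island_id <- sprintf("%09d", seq_along(meth))
  eff_bins <- min(n_bins, length(sel),
                  length(unique(k4_density[sel])))
  profile_by_decile(meth[sel], k4_density[sel], island_id[sel], eff_bins)
}

#' Paired per-island density change between two states
#'
#' Compares per-island densities measured in two cellular states over the
#' same island universe (e.g. H3K27me3 in undifferentiated cells versus
#' derived neural precursors), summarizing the mean change inside and
#' outside a highlighted island set.
#'
#' @param state_a,state_b Named numeric vectors (names = island_id) or
#'   data.frames with `island_id` and a density column; both must cover
#'   the same island universe.
#' @param highlight_set Character vector of island ids to contrast
#'   (must be a subset of the universe).
#' @return List with `per_island` (island_id, density_a, density_b, diff,
#'   in_highlight) and `summary` (mean diff and n inside/outside the set).
#' @export
paired_density_change <- function(state_a, state_b, highlight_set) {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      val_col <- setdiff(names(x), "island_id")[1]
      stats::setNames(x[[val_col]], x$island_id)
    } else x
  }
  a <- as_named(state_a); b <- as_named(state_b)
  miss_a <- setdiff(names(b), names(a))
  miss_b <- setdiff(names(a), names(b))
  if (length(miss_a) || length(miss_b))
    stop("island universes differ; missing from A: ",
         paste(utils::head(miss_a, 5), collapse = ", "),
         "; missing from B: ",
         paste(utils::head(miss_b, 5), collapse = ", "), call. = FALSE)
  ids <- sort(names(a))
  outside <- setdiff(highlight_set, ids)
  if (length(outside))
    stop("highlight islands not in universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  per <- data.frame(island_id = ids, density_a = unname(a[ids]),
                    density_b = unname(b[ids]),
                    diff = unname(b[ids] - a[ids]),
                    in_highlight = ids %in% highlight_set,
                    stringsAsFactors = FALSE)
  summary <- data.frame(
    group = c("highlight", "other"),
    mean_diff = c(mean(per$diff[per$in_highlight]),
                  mean(per$diff[!per$in_highlight])),
    n = c(sum(per$in_highlight), sum(!per$in_highlight)))
  list(per_island = per, summary = summary)
}
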