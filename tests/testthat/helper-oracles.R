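# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package:
# plain loops and closed forms only.

# All-pairs interval assignment with the overlap-majority rule and
# lexicographic tie-break; features are rows with chrom + start/end or pos.
brute_map <- function(features, islands) {
  is_cpg <- "pos" %in% names(features) && !"start" %in% names(features)
  out <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    fs <- if (is_cpg) features$pos[i] else features$start[i]
    fe <- if (is_cpg) features$pos[i] + 2L else features$end[i]
    best_id <- "background"; best_ov <- 0L
    for (j in seq_len(nrow(islands))) {
      if (features$chrom[i] != islands$chrom[j]) next
      ov <- min(fe, islands$end[j]) - max(fs, islands$start[j])
      if (ov <= 0) next
      if (ov > best_ov || (ov == best_ov &&
                           islands$island_id[j] < best_id)) {
        best_ov <- ov; best_id <- islands$island_id[j]
      }
    }
    out[i] <- best_id
  }
  out
}

# Per-island mean of probe z-scores by explicit looping.
brute_ims <- function(z, assignment) {
  ids <- sort(unique(assignment[assignment != "background" & !is.na(z)]))
  vapply(ids, function(id) {
    v <- z[assignment == id & !is.na(z)]
    sum(v) / length(v)
  }, numeric(1))
}

# Island percent from raw counts applying both coverage filters.
brute_island_percent <- function(counts, assignment, min_reads = 5,
                                 min_cpgs = 3) {
  ids <- sort(unique(assignment[assignment != "background"]))
  res <- list()
  for (id in ids) {
    rows <- which(assignment == id & counts$total >= min_reads)
    if (length(rows) < min_cpgs) next
    pct <- 100 * counts$meth[rows] / counts$total[rows]
    res[[id]] <- c(percent = mean(pct), n = length(rows))
  }
  res
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from
# 1:N against set_b = 1:K and count overlaps >= k.
brute_hyper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Pooled-variance two-sample t statistic from the closed form.
brute_pooled_t <- function(a, b) {
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Equal-count rank bins with island_id tie-break, by explicit sorting.
brute_decile <- function(meth, density, ids, n_bins) {
  ord <- order(density, ids)
  n <- length(meth)
  sizes <- rep(floor(n / n_bins), n_bins)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[1:extra] <- sizes[1:extra] + 1
  stopifnot(sum(sizes) == n)
  res <- matrix(NA_real_, n_bins, 2)
  at <- 1
  for (b in seq_len(n_bins)) {
    take <- ord[at:(at + sizes[b] - 1)]
    res[b, ] <- c(mean(density[take]), mean(meth[take]))
    at <- at + sizes[b]
  }
  res
}

# Random fixtures -----------------------------------------------------

rand_islands <- function(n, chroms = c("chrA", "chrB")) {
  per_chrom <- split(seq_len(n), sample(chroms, n, replace = TRUE))
  out <- lapply(names(per_chrom), function(ch) {
    k <- length(per_chrom[[ch]])
    w <- sample(50:300, k, replace = TRUE)
    g <- sample(10:500, k, replace = TRUE)
    s <- cumsum(g) + cumsum(c(0L, w[-k]))
    data.frame(chrom = ch, start = s, end = s + w,
               island_id = sprintf("%s_i%03d", ch, seq_len(k)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

rand_features <- function(n, islands, cpg = FALSE) {
  lo <- min(islands$start) - 400L
  hi <- max(islands$end) + 400L
  chrom <- sample(unique(c(islands$chrom, "chrZ")), n, replace = TRUE)
  if (cpg) {
    data.frame(chrom = chrom, pos = sample(lo:hi, n, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    s <- sample(lo:hi, n, replace = TRUE)
    data.frame(chrom = chrom, start = s,
               end = s + sample(20:120, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
}
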