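# All genomic coordinates in this package are 0-based, half-open (BED
# convention): an interval [start, end) covers positions start .. end-1.
# A CpG dinucleotide occupies 2 bp, so a CpG at `pos` is [pos, pos + 2).

BACKGROUND_KEY <- "background"

tool_header <- function(what, params = character()) {
  ver <- as.character(utils::packageVersion("methtrace"))
  extra <- if (length(params)) paste0(" ", paste(params, collapse = " ")) else ""
  sprintf("# methtrace %s %s coords=0-based,half-open%s", ver, what, extra)
}

#' Validate a set of CpG islands
#'
#' Checks the CpG island invariants: `start < end` for every interval,
#' unique `island_id`, and no two islands overlapping on the same
#' chromosome. Adds zeroed `n_probes` / `n_cpgs` columns when absent.
#'
#' @param islands data.frame with columns `chrom`, `start`, `end`,
#'   `island_id` (0-based, half-open coordinates).
#' @return The validated data.frame.
#' @export
validate_islands <- function(islands) {
  req <- c("chrom", "start", "end", "island_id")
  miss <- setdiff(req, names(islands))
  if (length(miss)) stop("islands are missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  islands$start <- as.integer(islands$start)
  islands$end <- as.integer(islands$end)
  if (anyNA(islands$start) || anyNA(islands$end))
    stop("island start/end must be integer coordinates", call. = FALSE)
  bad <- which(islands$start >= islands$end)
  if (length(bad))
    stop("island interval with start >= end: ",
         paste(islands$island_id[bad], collapse = ", "), call. = FALSE)
  dup <- islands$island_id[duplicated(islands$island_id)]
  if (length(dup))
    stop("duplicate island_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (BACKGROUND_KEY %in% islands$island_id)
    stop("island_id '", BACKGROUND_KEY, "' is reserved", call. = FALSE)
  if (nrow(islands) > 1) {
    gr <- islands_granges(islands)
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)[1]
      s <- S4Vectors::subjectHits(hits)[1]
      stop("overlapping islands on the same chromosome: ",
           islands$island_id[q], " and ", islands$island_id[s],
           call. = FALSE)
    }
  }
  if (is.null(islands$n_probes))
    islands$n_probes <- integer(nrow(islands))
  if (is.null(islands$n_cpgs))
    islands$n_cpgs <- integer(nrow(islands))
  rownames(islands) <- NULL
  islands
}

islands_granges <- function(islands) {
  GenomicRanges::GRanges(islands$chrom,
                         IRanges::IRanges(islands$start + 1L, islands$end))
}

#' Read CpG island definitions from BED or TSV
#'
#' Coordinates are read as 0-based, half-open (BED convention). BED input
#' uses columns chrom/start/end and an optional fourth name column; TSV
#' input must carry a header with at least `chrom`, `start`, `end` and
#' optionally `name`. When no name is present the island_id is
#' auto-generated as `"chrom:start-end"`. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the file.
#' @param format `"bed"` (default) or `"tsv"`.
#' @return Validated island data.frame (see [validate_islands()]).
#' @export
read_islands <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  cols <- c(chrom = 1L, start = 2L, end = 3L, name = 4L)
  if (format == "tsv") {
    if (!length(body_idx))
      stop("TSV island file has no header: ", path, call. = FALSE)
    hdr <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
    for (col in c("chrom", "start", "end"))
      if (!col %in% hdr)
        stop("missing column '", col, "' in ", path, call. = FALSE)
    cols <- c(chrom = match("chrom", hdr), start = match("start", hdr),
              end = match("end", hdr), name = match("name", hdr))
    body_idx <- body_idx[-1]
  }
  if (!length(body_idx)) {
    warning("no islands read from ", path, call. = FALSE)
    return(validate_islands(data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       island_id = character())))
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  need <- max(cols[c("chrom", "start", "end")])
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line_no <- body_idx[i]
    if (length(p) < need)
      stop(sprintf("malformed island row at line %d of %s", line_no, path),
           call. = FALSE)
    start <- suppressWarnings(as.integer(p[cols[["start"]]]))
    end <- suppressWarnings(as.integer(p[cols[["end"]]]))
    if (is.na(start) || is.na(end) || start >= end)
      stop(sprintf("malformed island row at line %d of %s", line_no, path),
           call. = FALSE)
    nm <- if (!is.na(cols[["name"]]) && length(p) >= cols[["name"]] &&
              nzchar(p[cols[["name"]]])) p[cols[["name"]]] else
      sprintf("%s:%d-%d", p[cols[["chrom"]]], start, end)
    out[[i]] <- data.frame(chrom = p[cols[["chrom"]]], start = start,
                           end = end, island_id = nm,
                           stringsAsFactors = FALSE)
  }
  validate_islands(do.call(rbind, out))
}

#' Write CpG islands as BED4 with a provenance header
#'
#' @param islands Validated island data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands <- function(islands, path) {
  islands <- validate_islands(islands)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(tool_header("islands"), con)
  if (nrow(islands))
    writeLines(sprintf("%s\t%d\t%d\t%s", islands$chrom, islands$start,
                       islands$end, islands$island_id), con)
  invisible(path)
}

#' Read a probe table (TSV with header)
#'
#' Expected columns: `probe_id`, `chrom`, `start`, `end`, `tm`, `bound`,
#' `input`. Intensities are background-subtracted fluorescence values and
#' may be non-positive; `tm` must be finite.
#'
#' @param path Path to the TSV file.
#' @return data.frame of probe records.
#' @export
read_probes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "start", "end", "tm", "bound", "input")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("probe table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$tm)))
    stop("non-finite probe Tm in ", path, call. = FALSE)
  df
}

#' Write a probe table with a provenance header
#' @param probes Probe data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  write_tsv_with_header(probes, path, tool_header("probes"))
}

#' Read per-CpG bisulfite counts (TSV with header)
#'
#' Expected columns: `chrom`, `pos` (0-based position of the CpG cytosine
#' on the plus strand, strand-collapsed), `meth`, `total`.
#'
#' @param path Path to the TSV file.
#' @return data.frame of CpG counts.
#' @export
read_cpg_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "meth", "total")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("CpG count table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_cpg_counts(df)
}

validate_cpg_counts <- function(df) {
  bad <- which(df$meth < 0 | df$total < df$meth)
  if (length(bad))
    stop("invalid CpG counts (need total >= meth >= 0) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  df
}

#' Write a per-CpG count table with a provenance header
#' @param counts CpG count data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(counts, path) {
  write_tsv_with_header(validate_cpg_counts(counts), path,
                        tool_header("cpg_counts"))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Map array probes or CpG sites onto CpG islands
#'
#' A feature is assigned to an island iff its half-open interval intersects
#' the island interval; a CpG at `pos` occupies `[pos, pos + 2)`. A feature
#' overlapping two islands goes to the island with the larger overlap, with
#' exact ties broken towards the lexicographically smaller `island_id` so
#' the assignment is deterministic and order-independent. Features hitting
#' no island (including features on chromosomes absent from the island set)
#' are retained under the reserved `"background"` key.
#'
#' @param features data.frame with `chrom` and either `start`/`end`
#'   (probes) or `pos` (CpG sites).
#' @param islands Validated island data.frame.
#' @return List with `assignment` (character vector, island_id or
#'   `"background"` per feature), `islands` (with `n_probes` or `n_cpgs`
#'   refreshed), and `n_background`.
#' @export
map_features_to_islands <- function(features, islands) {
  islands <- validate_islands(islands)
  is_cpg <- "pos" %in% names(features) && !"start" %in% names(features)
  if (is_cpg) {
    fstart <- as.integer(features$pos)
    fend <- fstart + 2L
  } else {
    fstart <- as.integer(features$start)
    fend <- as.integer(features$end)
  }
  assignment <- rep(BACKGROUND_KEY, nrow(features))
  if (nrow(features) && nrow(islands)) {
    fgr <- GenomicRanges::GRanges(features$chrom,
                                  IRanges::IRanges(fstart + 1L, fend))
    igr <- islands_granges(islands)
    hits <- GenomicRanges::findOverlaps(fgr, igr)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(fgr)[q],
                                               IRanges::ranges(igr)[s]))
      id <- islands$island_id[s]
      ord <- order(q, -ov, id)
      first <- !duplicated(q[ord])
      assignment[q[ord][first]] <- id[ord][first]
    }
  }
  counts <- table(factor(assignment[assignment != BACKGROUND_KEY],
                         levels = islands$island_id))
  if (is_cpg) islands$n_cpgs <- as.integer(counts) else
    islands$n_probes <- as.integer(counts)
  list(assignment = assignment, islands = islands,
       n_background = sum(assignment == BACKGROUND_KEY))
}
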