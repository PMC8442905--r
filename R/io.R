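#' Read a BED3 interval file
#'
#' Reads a plain (optionally gzipped) BED file with at least three columns
#' (chrom, start, end; 0-based half-open) and returns a `GRanges`. Any row
#' whose start/end is non-numeric, negative or inverted raises an error that
#' names the offending line.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` with one range per BED record.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path, call. = FALSE)
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED record at line %d of %s", bad[1L], path), call. = FALSE)
  }
  .gr0(dt[[1L]], as.integer(start), as.integer(end))
}

#' Write intervals as BED3
#'
#' @param x A `GRanges` or a data.frame with chrom/start/end (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (methods::is(x, "GRanges")) {
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x)
    )
  } else {
    dt <- data.table::as.data.table(x)[, 1:3]
    data.table::setnames(dt, c("chrom", "start", "end"))
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph-style per-CpG methylation call table
#'
#' Expected columns (TSV, no header required; a header line is detected and
#' skipped): chrom, start, end, n_meth, n_unmeth, with 0-based half-open
#' coordinates. Under TAPS polarity `n_meth` is the converted (modified)
#' read count at the site.
#'
#' @param path Path to the call table (optionally gzipped).
#' @return A `data.table` with columns chrom, start, end, n_meth, n_unmeth.
#' @export
read_cpg_calls <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 5L) stop("call table needs 5 columns (chrom, start, end, n_meth, n_unmeth): ",
                          path, call. = FALSE)
  dt <- dt[, 1:5]
  data.table::setnames(dt, c("chrom", "start", "end", "n_meth", "n_unmeth"))
  if (is.character(dt$start) && nrow(dt) > 0L && is.na(suppressWarnings(as.numeric(dt$start[1L])))) {
    dt <- dt[-1L]  # header line
  }
  for (col in c("start", "end", "n_meth", "n_unmeth")) {
    data.table::set(dt, j = col, value = suppressWarnings(as.numeric(dt[[col]])))
  }
  validate_cpg_calls(dt)
}

#' Validate a per-CpG call table
#'
#' Checks column presence, non-negative counts and valid coordinates, and
#' returns the table sorted by chrom and position.
#'
#' @param calls A data.frame/data.table with chrom, start, end, n_meth, n_unmeth.
#' @return The validated, sorted `data.table`.
#' @export
validate_cpg_calls <- function(calls) {
  dt <- data.table::as.data.table(calls)
  need <- c("chrom", "start", "end", "n_meth", "n_unmeth")
  if (!all(need %in% names(dt))) {
    stop("call table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start < 0 | dt$end < dt$start |
                 is.na(dt$n_meth) | is.na(dt$n_unmeth) | dt$n_meth < 0 | dt$n_unmeth < 0)
  if (length(bad) > 0L) {
    stop(sprintf("invalid call record at row %d", bad[1L]), call. = FALSE)
  }
  data.table::setorder(dt, chrom, start)
  dt[]
}

#' Write a per-CpG call table
#'
#' @param calls Call table as from [read_cpg_calls()].
#' @param path Output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  data.table::fwrite(data.table::as.data.table(calls), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with a header containing at least `sample_id` and `group`.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.table` with sample_id and group columns.
#' @export
read_metadata <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!all(c("sample_id", "group") %in% names(dt))) {
    stop("metadata must have columns sample_id and group", call. = FALSE)
  }
  dt
}

#' Write a window-level methylation matrix as TSV
#'
#' Windows as rows (chrom, start, end), one column per sample.
#'
#' @param wmm A [window_levels()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_matrix <- function(wmm, path) {
  stopifnot(inherits(wmm, "WindowMethylationMatrix"))
  out <- data.table::data.table(wmm$windows[, c("chrom", "start", "end")])
  lv <- t(wmm$levels)
  for (s in colnames(lv)) data.table::set(out, j = s, value = lv[, s])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a window-level methylation matrix written by [write_window_matrix()]
#'
#' @param path Path to the TSV.
#' @param width Window width in bp (recorded on the object).
#' @return A `WindowMethylationMatrix` (without coverage information).
#' @export
read_window_matrix <- function(path, width = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  samples <- setdiff(names(dt), c("chrom", "start", "end"))
  lv <- t(as.matrix(dt[, samples, with = FALSE]))
  colnames(lv) <- .region_id(dt$chrom, dt$start, dt$end)
  rownames(lv) <- samples
  if (is.null(width)) width <- as.integer(stats::median(dt$end - dt$start))
  structure(list(
    windows = data.table::data.table(chrom = dt$chrom, start = dt$start, end = dt$end,
                                     id = colnames(lv)),
    levels = lv, coverage = NULL, width = width
  ), class = "WindowMethylationMatrix")
}

#' Read an Ensembl Regulatory Build GFF and reduce it to labelled intervals
#'
#' Parses a (optionally gzipped) GFF3 regulatory-feature file and returns a
#' `GRanges` with a `feature_type` column (e.g. enhancer, promoter), for use
#' as feature sets in overlap enrichment or as candidate-window masks.
#' Coordinates are converted from GFF 1-based closed intervals.
#'
#' @param path Path to the GFF file.
#' @param feature_types Optional character vector restricting the feature
#'   types kept (matched against the GFF type column, case-insensitive).
#' @return A `GRanges` with a `feature_type` metadata column.
#' @export
read_regulatory_gff <- function(path, feature_types = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                          colClasses = list(character = c(1, 3)))
  if (ncol(dt) < 5L) stop("not a GFF file (fewer than 5 columns): ", path, call. = FALSE)
  type <- dt[[3L]]
  start <- suppressWarnings(as.integer(dt[[4L]]))
  end <- suppressWarnings(as.integer(dt[[5L]]))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0L) stop(sprintf("malformed GFF record at line %d of %s", bad[1L], path),
                             call. = FALSE)
  keep <- if (is.null(feature_types)) rep(TRUE, nrow(dt)) else {
    tolower(type) %in% tolower(feature_types)
  }
  gr <- GenomicRanges::GRanges(dt[[1L]][keep],
                               IRanges::IRanges(start = start[keep], end = end[keep]))
  S4Vectors::mcols(gr)$feature_type <- type[keep]
  gr
}
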