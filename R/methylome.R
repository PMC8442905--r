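# Window-level methylome construction: masking, windowing, spike-in QC.
#
# Conventions: all coordinates are 0-based half-open (BED); windows tile each
# chromosome from position 0 at a fixed width. Under TAPS polarity a modified
# cytosine reads as T, so `n_meth` is the converted call count.

#' Remove CpG sites overlapping exclusion masks
#'
#' Drops any call whose site overlaps (by >= 1 bp, half-open semantics) any
#' interval in any of the supplied mask sets, and removes named sex
#' chromosomes outright. Typical masks: common SNPs, ENCODE blacklist,
#' centromeres.
#'
#' @param calls A per-CpG call table (see [read_cpg_calls()]).
#' @param masks A list of masks; each element is a `GRanges` or a path to a
#'   BED file.
#' @param sex_chroms Chromosome names removed entirely (default chrX/chrY).
#' @return The filtered call table.
#' @export
apply_masks <- function(calls, masks = list(), sex_chroms = c("chrX", "chrY")) {
  dt <- validate_cpg_calls(calls)
  if (length(sex_chroms) > 0L) dt <- dt[!chrom %in% sex_chroms]
  if (length(masks) > 0L && nrow(dt) > 0L) {
    grs <- lapply(masks, function(m) if (methods::is(m, "GRanges")) m else read_bed(m))
    mask <- suppressWarnings(Reduce(c, grs))
    if (length(mask) > 0L) {
      sites <- .gr0(dt$chrom, dt$start, dt$end)
      hit <- IRanges::overlapsAny(sites, mask)
      dt <- dt[!hit]
    }
  }
  dt[]
}

#' Build a window-level methylation matrix from per-sample CpG calls
#'
#' The genome is tiled into fixed-width windows starting at position 0. Per
#' sample and window, the methylation level is the pooled ratio
#' sum(n_meth) / sum(n_meth + n_unmeth) over the window's CpGs. Coverage of a
#' window is total calls divided by the number of known CpG positions in the
#' window; windows whose cohort-wide mean coverage falls below
#' `min_mean_cov` are dropped (a common window set is kept for all samples).
#' A retained window with zero covered CpGs in a given sample is missing
#' (`NA`) for that sample.
#'
#' @param calls_list Named list of per-sample call tables (already masked).
#' @param width Window width in bp (e.g. 1000 or 1e6).
#' @param min_mean_cov Minimum cohort-mean CpG coverage per window (default 2).
#' @param cpg_positions Optional table/`GRanges` of all CpG positions; when
#'   `NULL`, the union of sites observed across samples is used as the
#'   position universe.
#' @return A `WindowMethylationMatrix`: list with `windows` (chrom, start,
#'   end, n_cpg, id), `levels` (sample x window), `coverage` (sample x
#'   window) and `width`.
#' @export
window_levels <- function(calls_list, width = 1000, min_mean_cov = 2,
                          cpg_positions = NULL) {
  width <- .check_count(width, "width")
  if (length(calls_list) == 0L) stop("no samples supplied", call. = FALSE)
  if (is.null(names(calls_list)) || any(names(calls_list) == "")) {
    names(calls_list) <- sprintf("sample_%02d", seq_along(calls_list))
  }
  samples <- names(calls_list)
  long <- data.table::rbindlist(
    lapply(calls_list, function(x) data.table::as.data.table(x)[, .(chrom, start, n_meth, n_unmeth)]),
    idcol = "sample"
  )
  if (nrow(long) == 0L) stop("no retained windows: all call tables are empty", call. = FALSE)
  long[, win := (start %/% width) * width]

  # CpG position universe per window
  if (is.null(cpg_positions)) {
    pos <- unique(long[, .(chrom, start)])
  } else if (methods::is(cpg_positions, "GRanges")) {
    pos <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(cpg_positions)),
      start = GenomicRanges::start(cpg_positions) - 1L
    )
  } else {
    pos <- data.table::as.data.table(cpg_positions)[, .(chrom, start)]
  }
  pos[, win := (start %/% width) * width]
  npos <- pos[, .(n_cpg = .N), by = .(chrom, win)]

  agg <- long[, .(meth = sum(n_meth), tot = sum(n_meth) + sum(n_unmeth)),
              by = .(sample, chrom, win)]
  agg <- merge(agg, npos, by = c("chrom", "win"), all.x = TRUE)
  agg[, level := ifelse(tot > 0, meth / tot, NA_real_)]
  agg[, cov := tot / n_cpg]

  windows <- npos[order(chrom, win)]
  windows[, `:=`(start = win, end = win + width, id = .region_id(chrom, win, win + width))]

  lv <- matrix(NA_real_, nrow = length(samples), ncol = nrow(windows),
               dimnames = list(samples, windows$id))
  cv <- matrix(0, nrow = length(samples), ncol = nrow(windows),
               dimnames = list(samples, windows$id))
  ii <- cbind(match(agg$sample, samples), match(.region_id(agg$chrom, agg$win, agg$win + width), windows$id))
  lv[ii] <- agg$level
  cv[ii] <- agg$cov

  keep <- colMeans(cv) >= min_mean_cov
  if (!any(keep)) stop("no retained windows: cohort mean coverage below threshold everywhere",
                       call. = FALSE)
  structure(list(
    windows = windows[keep, .(chrom, start, end, n_cpg, id)],
    levels = lv[, keep, drop = FALSE],
    coverage = cv[, keep, drop = FALSE],
    width = width
  ), class = "WindowMethylationMatrix")
}

#' @export
print.WindowMethylationMatrix <- function(x, ...) {
  cat(sprintf("WindowMethylationMatrix: %d samples x %d windows (width %d bp)\n",
              nrow(x$levels), ncol(x$levels), x$width))
  cat(sprintf("  missing levels: %.1f%%\n", 100 * mean(is.na(x$levels))))
  invisible(x)
}

#' Restrict a window matrix to windows overlapping a feature set
#'
#' @param wmm A `WindowMethylationMatrix`.
#' @param features A `GRanges` or BED path (e.g. enhancers or promoters).
#' @return Character vector of window ids overlapping the features.
#' @export
windows_in_features <- function(wmm, features) {
  stopifnot(inherits(wmm, "WindowMethylationMatrix"))
  gr <- if (methods::is(features, "GRanges")) features else read_bed(features)
  wins <- .gr0(wmm$windows$chrom, wmm$windows$start, wmm$windows$end)
  wmm$windows$id[IRanges::overlapsAny(wins, gr)]
}

#' Spike-in conversion QC
#'
#' Conversion rate is the fraction of calls at methylated-control CpGs read
#' as converted (TAPS polarity: modified cytosine reads as T, encoded as
#' `n_meth`); the false-positive rate is the converted fraction at
#' unmodified-control cytosines.
#'
#' @param meth_control_calls Call table for the methylated spike-in control
#'   (e.g. CpG-methylated lambda DNA).
#' @param unmod_control_calls Call table for the unmodified spike-in control.
#' @return A `SpikeInQC` list: conversion_rate, false_positive_rate,
#'   n_meth_calls, n_unmod_calls.
#' @export
spikein_qc <- function(meth_control_calls, unmod_control_calls) {
  m <- validate_cpg_calls(meth_control_calls)
  u <- validate_cpg_calls(unmod_control_calls)
  n_m <- sum(m$n_meth) + sum(m$n_unmeth)
  n_u <- sum(u$n_meth) + sum(u$n_unmeth)
  if (n_m == 0 || n_u == 0) stop("undefined rate: spike-in control has zero total calls",
                                 call. = FALSE)
  structure(list(
    conversion_rate = sum(m$n_meth) / n_m,
    false_positive_rate = sum(u$n_meth) / n_u,
    n_meth_calls = n_m,
    n_unmod_calls = n_u
  ), class = "SpikeInQC")
}

#' Sample-level QC gate on spike-in conversion
#'
#' A sample is kept iff its 5mC conversion rate is at or above the threshold
#' (a sample exactly at threshold passes).
#'
#' @param qc A `SpikeInQC` object.
#' @param min_conversion Minimum acceptable conversion rate (default 0.90).
#' @return A list with `keep` (logical) and the rate/threshold.
#' @export
qc_gate <- function(qc, min_conversion = 0.90) {
  stopifnot(inherits(qc, "SpikeInQC"))
  min_conversion <- .check_fraction(min_conversion, "min_conversion")
  list(keep = qc$conversion_rate >= min_conversion,
       conversion_rate = qc$conversion_rate,
       min_conversion = min_conversion)
}
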