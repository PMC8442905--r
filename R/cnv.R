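# Binned copy-number profiling: bin counting with blacklist/mappability
# filters, median-normalised ratios, and fixed-cutoff calls with a
# patient-level positivity rule.

#' Count reads/fragments per genomic bin and apply bin filters
#'
#' Bins failing the mappability threshold or overlapping the blacklist are
#' dropped (marked `retained = FALSE`, counts kept for bookkeeping).
#'
#' @param x Either a data.frame of positions (columns chrom, pos — e.g.
#'   fragment midpoints) or a numeric vector of precomputed per-bin counts
#'   aligned to `bins`.
#' @param bins Bin annotation: data.frame with chrom, start, end and
#'   optionally mappability (0-100) and blacklist (logical).
#' @param blacklist Optional extra blacklist intervals (`GRanges`/BED path).
#' @param min_mappability Bins with mappability strictly below this are
#'   dropped (default 80).
#' @return `data.table` of bins with count and retained columns.
#' @export
bin_and_filter <- function(x, bins, blacklist = NULL, min_mappability = 80) {
  b <- data.table::as.data.table(bins)
  stopifnot(all(c("chrom", "start", "end") %in% names(b)))
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != nrow(b)) stop("count vector must align with bins", call. = FALSE)
    b[, count := as.numeric(x)]
  } else {
    pos <- data.table::as.data.table(x)
    stopifnot(all(c("chrom", "pos") %in% names(pos)))
    bgr <- .gr0(b$chrom, b$start, b$end)
    pgr <- .gr0(pos$chrom, pos$pos, pos$pos + 1L)
    hits <- GenomicRanges::findOverlaps(pgr, bgr)
    b[, count := 0]
    cnt <- table(S4Vectors::subjectHits(hits))
    b$count[as.integer(names(cnt))] <- as.numeric(cnt)
  }
  retained <- rep(TRUE, nrow(b))
  if ("mappability" %in% names(b)) retained <- retained & b$mappability >= min_mappability
  if ("blacklist" %in% names(b)) retained <- retained & !as.logical(b$blacklist)
  if (!is.null(blacklist)) {
    bl <- if (methods::is(blacklist, "GRanges")) blacklist else read_bed(blacklist)
    if (length(bl) > 0L) {
      retained <- retained & !IRanges::overlapsAny(.gr0(b$chrom, b$start, b$end), bl)
    }
  }
  b[, retained := retained]
  data.table::setorder(b, chrom, start)
  b[]
}

#' Median-normalise bin counts to copy ratios
#'
#' Ratio = count / median(count over retained autosomal bins). Scale
#' invariant: doubling all counts leaves ratios unchanged.
#'
#' @param binned Output of [bin_and_filter()].
#' @param sex_chroms Chromosomes excluded from the normalising median.
#' @return The bin table with a `ratio` column (NA for dropped bins).
#' @export
normalize_ratios <- function(binned, sex_chroms = c("chrX", "chrY")) {
  b <- data.table::as.data.table(binned)
  stopifnot(all(c("count", "retained") %in% names(b)))
  ref <- b$retained & !b$chrom %in% sex_chroms
  med <- stats::median(b$count[ref])
  if (!is.finite(med) || med <= 0) stop("all retained bin counts are zero", call. = FALSE)
  b[, ratio := ifelse(retained, count / med, NA_real_)]
  b[]
}

#' Call copy-number gains/losses and the patient-level CNV flag
#'
#' Per-bin calls by fixed cutoffs (loss if ratio < `loss_cut`, gain if
#' ratio > `gain_cut`); consecutive retained bins with the same non-neutral
#' call are merged into segments, bridging runs of up to
#' `bridge_max_dropped` dropped (filtered-out) bins so that low-mappability
#' gaps do not split an aberration. A patient is CNV-positive iff some
#' segment is strictly longer than `min_len`.
#'
#' @param binned Bin table with `ratio` (from [normalize_ratios()]).
#' @param loss_cut,gain_cut Ratio cutoffs (defaults 0.8 and 1.2).
#' @param min_len Minimum segment length in bp for patient positivity
#'   (default 500 kb, strict inequality).
#' @param bridge_max_dropped Maximum dropped bins bridged inside a segment.
#' @return A `CNVProfile`: bins (with `call`), segments, patient_positive.
#' @export
call_cnv <- function(binned, loss_cut = 0.8, gain_cut = 1.2, min_len = 5e5,
                     bridge_max_dropped = 1) {
  b <- data.table::as.data.table(binned)
  stopifnot("ratio" %in% names(b))
  data.table::setorder(b, chrom, start)
  b[, call := ifelse(!retained | is.na(ratio), NA_character_,
                     ifelse(ratio < loss_cut, "loss",
                            ifelse(ratio > gain_cut, "gain", "neutral")))]
  segs <- list()
  for (ch in unique(b$chrom)) {
    sub <- b[chrom == ch]
    cur <- NULL  # list(call, start, end, n_bins, pending_dropped)
    flush <- function() {
      if (!is.null(cur)) {
        segs[[length(segs) + 1L]] <<- data.table::data.table(
          chrom = ch, start = cur$start, end = cur$end, call = cur$call,
          n_bins = cur$n_bins, length = cur$end - cur$start)
      }
      cur <<- NULL
    }
    dropped_run <- 0L
    for (i in seq_len(nrow(sub))) {
      cl <- sub$call[i]
      if (is.na(cl)) {            # dropped bin: may be bridged
        dropped_run <- dropped_run + 1L
        if (dropped_run > bridge_max_dropped) { flush(); dropped_run <- 0L }
        next
      }
      if (cl == "neutral") { flush(); dropped_run <- 0L; next }
      if (!is.null(cur) && cur$call == cl) {
        cur$end <- sub$end[i]
        cur$n_bins <- cur$n_bins + 1L
      } else {
        flush()
        cur <- list(call = cl, start = sub$start[i], end = sub$end[i], n_bins = 1L)
      }
      dropped_run <- 0L
    }
    flush()
  }
  segments <- if (length(segs) > 0L) data.table::rbindlist(segs) else {
    data.table::data.table(chrom = character(), start = integer(), end = integer(),
                           call = character(), n_bins = integer(), length = integer())
  }
  structure(list(bins = b, segments = segments,
                 loss_cut = loss_cut, gain_cut = gain_cut, min_len = min_len,
                 patient_positive = any(segments$length > min_len)),
            class = "CNVProfile")
}
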