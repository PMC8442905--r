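# cfDNA fragmentomics: fragment-length extraction, histograms, 10-bp bin
# fractions, group rank tests and the long-fragment LOO classifier.

#' Extract fragment lengths
#'
#' Accepts a numeric vector of lengths, a one-column length TSV, or a
#' paired-end SAM/BAM alignment file (requires Rsamtools). For alignments,
#' the absolute template length of the first-in-pair record is used so each
#' pair is counted once; duplicate-marked records are excluded by default
#' and unpaired records are skipped (their count is recorded in the
#' `n_skipped` attribute).
#'
#' @param x Numeric vector, path to a length TSV, or path to a SAM/BAM file.
#' @param min_len,max_len Retained length window (default 1-1000 bp).
#' @param drop_duplicates Exclude duplicate-marked alignment records.
#' @return Integer vector of fragment lengths.
#' @export
extract_lengths <- function(x, min_len = 1, max_len = 1000, drop_duplicates = TRUE) {
  n_skipped <- 0L
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
      if (!requireNamespace("Rsamtools", quietly = TRUE)) {
        stop("reading alignments requires the Rsamtools package", call. = FALSE)
      }
      bam <- if (grepl("\\.sam$", x, ignore.case = TRUE)) {
        Rsamtools::asBam(x, destination = tempfile(), overwrite = TRUE,
                         indexDestination = FALSE)
      } else x
      res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("isize", "flag")))[[1L]]
      flag <- res$flag
    isize <- res$isize
      keep <- !is.na(isize)
      if (drop_duplicates) keep <- keep & bitwAnd(flag, 1024L) == 0L
      paired <- bitwAnd(flag, 1L) == 1L
      n_skipped <- sum(!paired | is.na(isize))
      # template length is signed; the positive copy counts the pair once
      keep <- keep & paired & isize > 0L
      lens <- abs(isize[keep])
    } else {
      lens <- data.table::fread(x, header = FALSE)[[1L]]
    }
  } else {
    lens <- as.numeric(x)
  }
  lens <- abs(as.integer(round(lens)))
  lens <- lens[!is.na(lens) & lens >= min_len & lens <= max_len]
  if (length(lens) == 0L) stop("no fragment lengths in the retained window", call. = FALSE)
  attr(lens, "n_skipped") <- n_skipped
  lens
}

#' Fragment-length profile: histogram, 10-bp bin fractions, short/long mass
#'
#' Bins are half-open `[lo, lo+bin_width)`, so a 300-bp fragment falls in
#' the first long bin. Bin fractions are computed with the full-window
#' fragment total as denominator (fractions over the full range sum to 1 and
#' sub-range features stay on one simplex). The short and long summary
#' fractions cover, inclusively, 70-150 bp and 300-500 bp by default.
#'
#' @param lengths Integer fragment lengths (see [extract_lengths()]).
#' @param bin_width Bin width in bp (default 10); must divide the range.
#' @param full_range Full length window `c(lo, hi)` (default c(0, 1000)).
#' @param short_range,long_range Summary ranges (defaults c(70,150),
#'   c(300,500)).
#' @return A `FragmentProfile`: `histogram` (data.table length/count),
#'   `bin_fractions` (named, all bins in `full_range`), `short_fraction`,
#'   `long_fraction`, `n_fragments`.
#' @export
fragment_profile <- function(lengths, bin_width = 10, full_range = c(0, 1000),
                             short_range = c(70, 150), long_range = c(300, 500)) {
  bin_width <- .check_count(bin_width, "bin_width")
  if ((full_range[2L] - full_range[1L]) %% bin_width != 0) {
    stop("bin_width must divide the full range", call. = FALSE)
  }
  lengths <- as.integer(lengths)
  lengths <- lengths[lengths >= full_range[1L] & lengths < full_range[2L]]
  n <- length(lengths)
  if (n == 0L) stop("zero fragments in range", call. = FALSE)
  tab <- data.table::data.table(length = lengths)[, .(count = .N), by = length][order(length)]
  lo <- seq(full_range[1L], full_range[2L] - bin_width, by = bin_width)
  bin_of <- (lengths - full_range[1L]) %/% bin_width + 1L
  counts <- tabulate(bin_of, nbins = length(lo))
  fr <- counts / n
  names(fr) <- sprintf("[%d,%d)", lo, lo + bin_width)
  structure(list(
    histogram = tab,
    bin_fractions = fr,
    short_fraction = sum(lengths >= short_range[1L] & lengths <= short_range[2L]) / n,
    long_fraction = sum(lengths >= long_range[1L] & lengths <= long_range[2L]) / n,
    n_fragments = n,
    bin_width = bin_width, full_range = full_range,
    short_range = short_range, long_range = long_range
  ), class = "FragmentProfile")
}

#' Long-fragment 10-bp bin-fraction feature matrix
#'
#' Stacks, per sample, the bin fractions whose bins lie inside the long
#' range (default \[300, 500), i.e. 20 features at 10 bp) into a
#' sample-by-bin matrix for PCA and classification.
#'
#' @param profiles Named list of `FragmentProfile`s.
#' @param range Sub-range of bins to keep (default c(300, 500)).
#' @return Sample-by-bin numeric matrix.
#' @export
long_bin_matrix <- function(profiles, range = c(300, 500)) {
  stopifnot(length(profiles) > 0L)
  one <- function(p) {
    stopifnot(inherits(p, "FragmentProfile"))
    lo <- as.integer(sub("\\[(\\d+),.*", "\\1", names(p$bin_fractions)))
    p$bin_fractions[lo >= range[1L] & lo < range[2L]]
  }
  m <- do.call(rbind, lapply(profiles, one))
  rownames(m) <- names(profiles)
  m
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square p-value. When every value
#' is identical the statistic is 0 and p = 1.
#'
#' @param values_by_group List (>= 2 elements) of numeric vectors.
#' @return List with statistic (H), p_value, df.
#' @export
group_test <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  if (any(vapply(values_by_group, length, 1L) < 2L)) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  vals <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_group), vapply(values_by_group, length, 1L)))
  if (stats::sd(vals) == 0) {
    return(list(statistic = 0, p_value = 1, df = length(values_by_group) - 1L))
  }
  kt <- stats::kruskal.test(vals, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Leave-one-out classification on long-fragment bin fractions
#'
#' Delegates to [loo_predict()] with the long-bin fraction matrix as
#' features and no selection step.
#'
#' @param bin_matrix Sample-by-bin matrix from [long_bin_matrix()].
#' @param labels,positive,alpha,seed As in [loo_predict()].
#' @return An `LOOResult`.
#' @export
frag_model <- function(bin_matrix, labels, positive, alpha = 1, seed = 1) {
  loo_predict(bin_matrix, labels, positive, select = FALSE,
              alpha = alpha, seed = seed)
}
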