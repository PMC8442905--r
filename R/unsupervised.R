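# Unsupervised structure: PCA of window methylation, PC-correlated windows,
# and overlap enrichment of window sets in genomic feature sets.

.levels_matrix <- function(x) {
  if (inherits(x, "WindowMethylationMatrix")) x$levels else as.matrix(x)
}

#' Principal component analysis of window methylation
#'
#' Windows containing any missing level are dropped before decomposition;
#' the remaining matrix is centred and, by default, scaled to unit variance
#' per window (constant windows are dropped). Component signs are fixed by
#' requiring the largest-magnitude loading of each component to be positive,
#' so results are reproducible across platforms.
#'
#' @param x A `WindowMethylationMatrix` or a sample-by-window numeric matrix.
#' @param n_components Number of components to retain (default: all).
#' @param scale Scale windows to unit variance before decomposition
#'   (default TRUE).
#' @return A `PCAResult` list: `scores` (sample x component), `loadings`
#'   (window x component), `explained_variance`, `windows_used`.
#' @export
methyl_pca <- function(x, n_components = NULL, scale = TRUE) {
  m <- .levels_matrix(x)
  if (nrow(m) < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  keep <- colSums(is.na(m)) == 0L
  m <- m[, keep, drop = FALSE]
  v <- apply(m, 2L, stats::var)
  if (scale) m <- m[, v > 0, drop = FALSE]
  if (ncol(m) == 0L) stop("no complete, non-constant windows for PCA", call. = FALSE)
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  k <- if (is.null(n_components)) ncol(p$rotation) else min(n_components, ncol(p$rotation))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 sdev = p$sdev, windows_used = colnames(m)),
            class = "PCAResult")
}

#' Windows most correlated with a principal component
#'
#' Pearson-correlates each window's methylation levels with the sample
#' scores of one component; windows whose correlation-test p-value (via the
#' t-distribution transform of r) falls below `proba` are kept, ranked by
#' absolute correlation, and the top `top_n` returned. Constant windows are
#' excluded (correlation undefined), not an error.
#'
#' @param x The matrix the PCA was computed on.
#' @param pca A [methyl_pca()] result.
#' @param component Component index.
#' @param proba Significance threshold on the correlation test (default 0.01).
#' @param top_n Maximum number of windows returned (default 200).
#' @return `data.table` with window, r, p_value, ranked by |r| descending.
#' @export
pc_correlates <- function(x, pca, component = 1, proba = 0.01, top_n = 200) {
  stopifnot(inherits(pca, "PCAResult"))
  component <- .check_count(component, "component")
  if (component > ncol(pca$scores)) stop("component does not exist", call. = FALSE)
  m <- .levels_matrix(x)
  m <- m[rownames(pca$scores), , drop = FALSE]
  s <- pca$scores[, component]
  keep <- colSums(is.na(m)) == 0L
  m <- m[, keep, drop = FALSE]
  v <- apply(m, 2L, stats::var)
  m <- m[, v > 0, drop = FALSE]
  n <- nrow(m)
  r <- as.vector(stats::cor(m, s))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- data.table::data.table(window = colnames(m), r = r, p_value = p)
  out <- out[p_value < proba][order(-abs(r))]
  utils::head(out, top_n)
}

#' Fisher exact test on a 2x2 contingency table of counts
#'
#' Two-sided p-value (exact conditional test) and the sample odds ratio
#' (a*d)/(b*c); a zero cell yields an infinite or zero odds ratio with the
#' p-value still defined.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with odds_ratio, p_value and the contingency counts.
#' @export
fisher_test_counts <- function(a, b, c, d) {
  for (v in list(a = a, b = b, c = c, d = d)) stopifnot(is.numeric(v), v >= 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- (a * d) / (b * c)  # sample odds ratio; Inf/NaN allowed at zero cells
  list(odds_ratio = or, p_value = p, contingency = c(a = a, b = b, c = c, d = d))
}

#' Overlap enrichment of a window set in a genomic feature set
#'
#' Window-level contingency: a = query windows overlapping the feature by
#' >= 1 bp, b = query windows not overlapping, c = background-minus-query
#' windows overlapping, d = the remainder; two-sided Fisher exact p and
#' sample odds ratio.
#'
#' @param query Window ids (chrom:start-end) or `GRanges`; must be a subset
#'   of `background`.
#' @param background Background window ids or `GRanges`.
#' @param feature Feature intervals (`GRanges` or BED path).
#' @param feature_name Label recorded on the result.
#' @return An `EnrichmentResult` list: feature_name, contingency, odds_ratio,
#'   p_value.
#' @export
fisher_overlap <- function(query, background, feature, feature_name = "feature") {
  qids <- if (methods::is(query, "GRanges")) {
    .region_id(as.character(GenomicRanges::seqnames(query)),
               GenomicRanges::start(query) - 1L, GenomicRanges::end(query))
  } else as.character(query)
  bids <- if (methods::is(background, "GRanges")) {
    .region_id(as.character(GenomicRanges::seqnames(background)),
               GenomicRanges::start(background) - 1L, GenomicRanges::end(background))
  } else as.character(background)
  if (length(qids) == 0L) stop("empty query window set", call. = FALSE)
  if (!all(qids %in% bids)) stop("query must be a subset of background", call. = FALSE)
  fg <- if (methods::is(feature, "GRanges")) feature else read_bed(feature)
  if (length(fg) == 0L) stop("feature set is empty", call. = FALSE)
  bgr <- .gr_from_ids(bids)
  hit <- IRanges::overlapsAny(bgr, fg)
  names(hit) <- bids
  inq <- bids %in% qids
  a <- sum(hit[inq]); b <- sum(!hit[inq])
  c_ <- sum(hit[!inq]); d <- sum(!hit[!inq])
  ft <- fisher_test_counts(a, b, c_, d)
  structure(list(feature_name = feature_name,
                 contingency = ft$contingency,
                 odds_ratio = ft$odds_ratio,
                 p_value = ft$p_value),
            class = "EnrichmentResult")
}
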