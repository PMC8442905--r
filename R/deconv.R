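# Tissue-of-origin deconvolution: enhancer-aggregated reference atlas,
# tissue-specific DMR selection, nonnegative least squares mixture fits and
# group comparison of the estimated contributions.

#' Aggregate per-CpG calls over enhancer regions
#'
#' Per region, the methylation level is the pooled ratio
#' sum(n_meth) / sum(n_meth + n_unmeth) over the CpGs the region contains;
#' regions with fewer than `min_cpgs` covered CpGs are missing for that
#' sample.
#'
#' @param calls_list Named list of per-sample CpG call tables.
#' @param enhancers Regions (`GRanges` or BED path).
#' @param min_cpgs Minimum covered CpGs per region (default 1).
#' @return Region-by-sample matrix of levels; rownames are region ids.
#' @export
aggregate_enhancers <- function(calls_list, enhancers, min_cpgs = 1) {
  gr <- if (methods::is(enhancers, "GRanges")) enhancers else read_bed(enhancers)
  if (length(gr) == 0L) stop("enhancer set is empty", call. = FALSE)
  min_cpgs <- .check_count(min_cpgs, "min_cpgs")
  ids <- .region_id(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  if (is.null(names(calls_list))) names(calls_list) <- sprintf("sample_%02d", seq_along(calls_list))
  out <- matrix(NA_real_, nrow = length(gr), ncol = length(calls_list),
                dimnames = list(ids, names(calls_list)))
  for (s in names(calls_list)) {
    dt <- validate_cpg_calls(calls_list[[s]])
    sites <- .gr0(dt$chrom, dt$start, dt$end)
    hits <- GenomicRanges::findOverlaps(sites, gr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    tot <- dt$n_meth[qh] + dt$n_unmeth[qh]
    agg <- data.table::data.table(region = sh, meth = dt$n_meth[qh], tot = tot)
    agg <- agg[, .(meth = sum(meth), tot = sum(tot), ncov = sum(tot > 0)), by = region]
    ok <- agg$ncov >= min_cpgs & agg$tot > 0
    out[agg$region[ok], s] <- agg$meth[ok] / agg$tot[ok]
  }
  out
}

# Row medians over a column subset, NA-tolerant.
.row_medians <- function(m, cols) {
  apply(m[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
}

#' Select tissue-specific regions from a reference set of tissue samples
#'
#' For each tissue group: regions are ranked by the absolute difference
#' between the tissue median and the median over all other samples
#' (one-versus-all); regions whose within-tissue replicate spread (max - min)
#' exceeds `consistency_max_spread`, or whose difference falls below the
#' `min_diff` floor, are dropped; the top `k_per_tissue` in each direction
#' (hyper/hypo) are kept. In addition, for each tissue the same ranking is
#' applied against its first and second most correlated tissues (Pearson
#' over tissue median profiles) and the top regions per direction are added,
#' so that closely related tissues remain separable.
#'
#' @param samples_mat Region-by-sample matrix of methylation levels.
#' @param tissue_labels Tissue group per sample column.
#' @param k_per_tissue Regions kept per tissue and direction (default 100).
#' @param consistency_max_spread Maximum replicate spread (default 0.25).
#' @param min_diff Minimum absolute median difference floor (default 0.1).
#' @return List: `selected` (data.table region/tissue/contrast/diff),
#'   `regions` (unique selected ids), `correlations` (tissue x tissue).
#' @export
tissue_specific_dmrs <- function(samples_mat, tissue_labels, k_per_tissue = 100,
                                 consistency_max_spread = 0.25, min_diff = 0.1) {
  m <- as.matrix(samples_mat)
  tissue_labels <- as.character(tissue_labels)
  stopifnot(length(tissue_labels) == ncol(m))
  tissues <- unique(tissue_labels)
  if (length(tissues) < 2L) stop("need >= 2 tissue groups", call. = FALSE)
  k_per_tissue <- .check_count(k_per_tissue, "k_per_tissue")

  med <- vapply(tissues, function(t) .row_medians(m, tissue_labels == t),
                numeric(nrow(m)))
  rownames(med) <- rownames(m)
  spread <- vapply(tissues, function(t) {
    sub <- m[, tissue_labels == t, drop = FALSE]
    apply(sub, 1L, function(x) if (all(is.na(x))) NA_real_ else diff(range(x, na.rm = TRUE)))
  }, numeric(nrow(m)))
  cors <- suppressWarnings(stats::cor(med, use = "pairwise.complete.obs"))

  take_top <- function(diffs, ok, tissue, contrast) {
    cand <- which(ok & !is.na(diffs) & abs(diffs) >= min_diff)
    res <- list()
    for (sgn in c(1, -1)) {
      side <- cand[sign(diffs[cand]) == sgn]
      side <- side[order(-abs(diffs[side]))]
      side <- utils::head(side, k_per_tissue)
      if (length(side) > 0L) {
        res[[length(res) + 1L]] <- data.table::data.table(
          region = rownames(m)[side], tissue = tissue, contrast = contrast,
          diff = diffs[side])
      }
    }
    data.table::rbindlist(res)
  }

  picks <- list()
  for (t in tissues) {
    ok <- !is.na(spread[, t]) & spread[, t] <= consistency_max_spread
    others <- .row_medians(m, tissue_labels != t)
    picks[[length(picks) + 1L]] <- take_top(med[, t] - others, ok, t, "one_vs_all")
    # top-2 most correlated tissues
    ct <- cors[t, setdiff(tissues, t)]
    ct <- ct[!is.na(ct)]
    top2 <- names(sort(ct, decreasing = TRUE))[seq_len(min(2L, length(ct)))]
    for (u in top2) {
      oku <- ok & !is.na(spread[, u]) & spread[, u] <= consistency_max_spread
      picks[[length(picks) + 1L]] <- take_top(med[, t] - med[, u], oku, t,
                                              paste0("vs_", u))
    }
  }
  sel <- data.table::rbindlist(picks)
  empty <- setdiff(tissues, unique(sel$tissue))
  if (length(empty) > 0L) {
    warning("no regions passed selection for tissue(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  list(selected = sel, regions = unique(sel$region), correlations = cors)
}

#' Build a tissue reference atlas from replicate tissue samples
#'
#' The reference matrix A holds, per selected region and tissue group, the
#' median level over that tissue's replicate samples.
#'
#' @param samples_mat Region-by-sample level matrix.
#' @param tissue_labels Tissue group per sample column.
#' @param selected_regions Region ids to retain (e.g. from
#'   [tissue_specific_dmrs()]); default all regions.
#' @return A `TissueReferenceAtlas`: `A` (region x tissue), `tissue_groups`,
#'   `selected_regions`, `tissue_correlations`.
#' @export
build_reference <- function(samples_mat, tissue_labels, selected_regions = NULL) {
  m <- as.matrix(samples_mat)
  tissue_labels <- as.character(tissue_labels)
  tissues <- unique(tissue_labels)
  if (is.null(selected_regions)) selected_regions <- rownames(m)
  selected_regions <- intersect(selected_regions, rownames(m))
  A <- vapply(tissues, function(t) .row_medians(m, tissue_labels == t),
              numeric(nrow(m)))
  rownames(A) <- rownames(m)
  cors <- suppressWarnings(stats::cor(A, use = "pairwise.complete.obs"))
  structure(list(A = A[selected_regions, , drop = FALSE],
                 tissue_groups = tissues,
                 selected_regions = selected_regions,
                 tissue_correlations = cors),
            class = "TissueReferenceAtlas")
}

#' Estimate tissue contributions by nonnegative least squares
#'
#' Solves min over x >= 0 of ||A x - y||_2 for one sample's observed
#' region-level methylation vector y against the reference matrix A. Regions
#' missing in y (or in any atlas column) are dropped pairwise before the
#' fit.
#'
#' @param atlas A `TissueReferenceAtlas` or a region-by-tissue matrix.
#' @param y Observed methylation vector; if named, aligned to atlas rows by
#'   name, otherwise taken in atlas row order.
#' @return A `TissueContribution`: `x` (raw nonnegative weights),
#'   `x_normalized` (sums to 1 when any weight is positive),
#'   `residual_norm`, `n_regions_used`, `frac_regions_used`.
#' @export
nnls_deconv <- function(atlas, y) {
  A <- if (inherits(atlas, "TissueReferenceAtlas")) atlas$A else as.matrix(atlas)
  if (!is.null(names(y)) && !is.null(rownames(A))) {
    y <- y[match(rownames(A), names(y))]
  }
  if (length(y) != nrow(A)) stop("y must align with atlas rows", call. = FALSE)
  ok <- !is.na(y) & stats::complete.cases(A)
  if (!any(ok)) stop("all regions missing: cannot deconvolve", call. = FALSE)
  fit <- pracma::lsqnonneg(A[ok, , drop = FALSE], as.numeric(y[ok]))
  x <- stats::setNames(fit$x, colnames(A))
  s <- sum(x)
  structure(list(x = x,
                 x_normalized = if (s > 0) x / s else x,
                 residual_norm = sqrt(fit$resid.norm),
                 n_regions_used = sum(ok),
                 frac_regions_used = mean(ok)),
            class = "TissueContribution")
}

#' Compare one tissue's contributions between two groups
#'
#' Two-group test on the named tissue's estimated contributions: Welch t
#' (default), paired t, or Kruskal-Wallis rank test.
#'
#' @param values_by_group List of two numeric vectors of contributions.
#' @param test One of "t", "paired-t", "kruskal".
#' @return List with statistic, p_value, method.
#' @export
compare_contribution <- function(values_by_group, test = c("t", "paired-t", "kruskal")) {
  test <- match.arg(test)
  stopifnot(length(values_by_group) == 2L)
  a <- values_by_group[[1L]]; b <- values_by_group[[2L]]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values", call. = FALSE)
  if (test == "kruskal") {
    kt <- group_test(values_by_group)
    return(list(statistic = kt$statistic, p_value = kt$p_value, method = "kruskal"))
  }
  paired <- test == "paired-t"
  if (stats::sd(c(a, b)) == 0) {
    # identical constant data: t = 0, p = 1 by convention
    return(list(statistic = 0, p_value = 1,
                method = if (paired) "paired-t" else "welch-t"))
  }
  tt <- tryCatch(stats::t.test(a, b, paired = paired, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    d <- mean(a) - mean(b)
    return(list(statistic = sign(d) * Inf, p_value = 0,
                method = if (paired) "paired-t" else "welch-t"))
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       method = if (paired) "paired-t" else "welch-t")
}

#' Leave-one-out classification on tissue contribution profiles
#'
#' Delegates to [loo_predict()] with the sample-by-tissue contribution
#' matrix as features and no feature-selection step.
#'
#' @param contributions Sample-by-tissue matrix (raw or normalised).
#' @param labels,positive,alpha,seed As in [loo_predict()].
#' @return An `LOOResult`.
#' @export
contribution_model <- function(contributions, labels, positive, alpha = 1, seed = 1) {
  loo_predict(contributions, labels, positive, select = FALSE,
              alpha = alpha, seed = seed)
}
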