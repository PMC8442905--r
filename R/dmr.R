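# Differentially methylated region (DMR) selection by per-window two-sample
# t-tests, vectorised across windows.

# Vectorised two-sample t-test per column of A vs B (samples in rows).
# Columns with any missing value in either group get NA statistics (the
# caller skips them). Welch by default; pooled-variance Student optional.
.t_test_matrix <- function(A, B, var_equal = FALSE) {
  nA <- nrow(A); nB <- nrow(B)
  okA <- colSums(is.na(A)) == 0L
  okB <- colSums(is.na(B)) == 0L
  ok <- okA & okB
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2L, stats::var); vB <- apply(B, 2L, stats::var)
  diff <- mA - mB
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, length(diff))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df = df)
  p[!ok] <- NA_real_
  diff[!ok] <- NA_real_
  list(diff = diff, t = t, p = p, df = df, ok = ok)
}

#' Find differentially methylated windows between two groups
#'
#' Per candidate window, a two-sample t-test (Welch by default) between the
#' groups; windows with p below `p_thresh` and absolute mean methylation
#' difference above `diff_thresh` are returned with direction (hyper/hypo in
#' group A). Windows with a missing level in any used sample are skipped.
#'
#' @param levels_A,levels_B Sample-by-window level matrices for the two
#'   groups (same window columns).
#' @param candidates Optional window ids restricting the candidate set (e.g.
#'   enhancer- or promoter-overlapping windows).
#' @param p_thresh p-value threshold (default 0.002).
#' @param diff_thresh Minimum absolute methylation difference (default 0.05).
#' @param var_equal Use pooled-variance Student t instead of Welch.
#' @return `data.table` with window, mean_diff (A - B), p_value, direction;
#'   ordered by p.
#' @export
find_dmrs <- function(levels_A, levels_B, candidates = NULL,
                      p_thresh = 0.002, diff_thresh = 0.05, var_equal = FALSE) {
  A <- as.matrix(levels_A); B <- as.matrix(levels_B)
  if (nrow(A) < 2L || nrow(B) < 2L) stop("each group needs >= 2 samples", call. = FALSE)
  if (!is.null(candidates)) {
    candidates <- intersect(candidates, colnames(A))
    A <- A[, candidates, drop = FALSE]
    B <- B[, candidates, drop = FALSE]
  }
  if (ncol(A) == 0L) {
    return(data.table::data.table(window = character(), mean_diff = numeric(),
                                  p_value = numeric(), direction = character()))
  }
  st <- .t_test_matrix(A, B, var_equal = var_equal)
  sel <- which(st$ok & !is.na(st$p) & st$p < p_thresh & abs(st$diff) > diff_thresh)
  out <- data.table::data.table(
    window = colnames(A)[sel],
    mean_diff = st$diff[sel],
    p_value = st$p[sel],
    direction = ifelse(st$diff[sel] > 0, "hyper", "hypo")
  )
  out[order(p_value)]
}

#' DMR stability between a reference and a down-sampled DMR set
#'
#' Fraction of the reference DMR set recovered: |intersection| / |reference|.
#'
#' @param ref_dmrs Reference window ids (e.g. the union over LOO folds at
#'   full depth).
#' @param downsampled_dmrs Window ids found on down-sampled data.
#' @return A fraction in \[0, 1\].
#' @export
dmr_stability <- function(ref_dmrs, downsampled_dmrs) {
  ref <- unique(as.character(ref_dmrs))
  if (length(ref) == 0L) stop("reference DMR set is empty", call. = FALSE)
  length(intersect(ref, unique(as.character(downsampled_dmrs)))) / length(ref)
}
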