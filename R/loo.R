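# Leave-one-out classification with feature selection nested inside each
# fold, elastic-net-regularised logistic models, and rank-based ROC/AUC.

# Impute missing entries by training-column means; drops nothing.
.impute_by_col <- function(x, means = NULL) {
  if (is.null(means)) means <- colMeans(x, na.rm = TRUE)
  means[is.nan(means)] <- 0.5
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- means[j]
  }
  list(x = x, means = means)
}

# Fit a regularised logistic model on the training rows. Returns a scoring
# closure plus whether any feature coefficient is active at the chosen
# penalty. With a single feature, plain logistic regression is used.
.fit_binary_model <- function(x, y, alpha = 1, seed = 1L) {
  set.seed(seed)
  p <- ncol(x)
  if (p >= 2L) {
    nfolds <- max(3L, min(10L, min(sum(y), sum(!y))))
    foldid <- sample(rep_len(seq_len(nfolds), length(y)))
    # small LOO folds trigger glmnet's grouped-CV fallback warning; harmless
    fit <- tryCatch(
      suppressWarnings(
        glmnet::cv.glmnet(x, factor(y), family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(score = NULL, active = FALSE))
    cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
    active <- any(abs(cf[-1L, 1L]) > 0)
    score <- function(newx) {
      as.numeric(stats::predict(fit, newx = newx, s = "lambda.min", type = "response"))
    }
  } else {
    df <- data.frame(y = y, f = x[, 1L])
    fit <- suppressWarnings(stats::glm(y ~ f, data = df, family = stats::binomial()))
    active <- is.finite(stats::coef(fit)[2L]) && abs(stats::coef(fit)[2L]) > 0
    score <- function(newx) {
      as.numeric(stats::predict(fit, newdata = data.frame(f = newx[, 1L]),
                                type = "response"))
    }
  }
  list(score = score, active = active)
}

#' Two-class leave-one-out prediction with within-fold DMR selection
#'
#' For each fold, one sample is held out; DMRs are found on the training
#' samples only ([find_dmrs()] at the configured thresholds, restricted to
#' `candidates`), an elastic-net-regularised logistic model with internally
#' cross-validated penalty is fit on the training DMR levels, and the
#' held-out sample is scored. Folds with zero selected DMRs, or whose fitted
#' model retains no feature at the chosen penalty, carry no information
#' about the held-out sample and are scored 0.5 and flagged degenerate.
#'
#' Setting `select = FALSE` skips the selection step and uses `candidates`
#' (or all columns) directly as features — the mode used for the tissue
#' contribution and fragmentation models.
#'
#' @param features Sample-by-feature matrix (window levels, contributions,
#'   or bin fractions). Missing values are imputed by training-column means.
#' @param labels Per-sample group labels (vector aligned to rows).
#' @param positive Label treated as the positive (cancer) class.
#' @param candidates Optional feature ids restricting the candidate set.
#' @param select Run within-fold DMR selection (default TRUE).
#' @param p_thresh,diff_thresh,var_equal Passed to [find_dmrs()].
#' @param alpha Elastic-net mixing parameter (1 = lasso, default).
#' @param seed Integer seed controlling penalty cross-validation folds.
#' @return A `LOOResult`: per-sample held-out `scores` (probability of the
#'   positive class), `fold_n_features`, `dmr_union`, `degenerate` flags,
#'   plus labels.
#' @export
loo_predict <- function(features, labels, positive, candidates = NULL,
                        select = TRUE, p_thresh = 0.002, diff_thresh = 0.05,
                        var_equal = FALSE, alpha = 1, seed = 1) {
  x <- as.matrix(features)
  if (is.null(rownames(x))) rownames(x) <- sprintf("sample_%02d", seq_len(nrow(x)))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  y <- labels == positive
  if (sum(y) < 2L || sum(!y) < 2L) stop("each class needs >= 2 samples", call. = FALSE)
  n <- nrow(x)
  scores <- stats::setNames(rep(NA_real_, n), rownames(x))
  nfeat <- integer(n)
  degenerate <- logical(n)
  union_feats <- character()

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (select) {
      dm <- find_dmrs(x[tr[y[tr]], , drop = FALSE], x[tr[!y[tr]], , drop = FALSE],
                      candidates = candidates, p_thresh = p_thresh,
                      diff_thresh = diff_thresh, var_equal = var_equal)
      feats <- dm$window
    } else {
      feats <- if (is.null(candidates)) colnames(x) else intersect(candidates, colnames(x))
    }
    nfeat[i] <- length(feats)
    union_feats <- union(union_feats, feats)
    if (length(feats) == 0L) {
      scores[i] <- 0.5
      degenerate[i] <- TRUE
      next
    }
    imp <- .impute_by_col(x[tr, feats, drop = FALSE])
    fit <- .fit_binary_model(imp$x, y[tr], alpha = alpha, seed = .derive_seed(seed, i))
    if (!fit$active) {
      # intercept-only model: its constant prediction is the training prior,
      # which in LOO is anti-correlated with the held-out label; report the
      # uninformative score instead.
      scores[i] <- 0.5
      degenerate[i] <- TRUE
      next
    }
    xt <- x[i, feats, drop = FALSE]
    nas <- is.na(xt[1L, ])
    if (any(nas)) xt[1L, nas] <- imp$means[nas]
    scores[i] <- fit$score(xt)
  }
  structure(list(scores = scores, labels = labels, positive = positive,
                 fold_n_features = nfeat, dmr_union = union_feats,
                 degenerate = degenerate, select = select, seed = seed,
                 alpha = alpha, p_thresh = p_thresh, diff_thresh = diff_thresh,
                 var_equal = var_equal, candidates = candidates),
            class = "LOOResult")
}

#' Score an external validation set with a refit-on-all model
#'
#' Refits a single regularised logistic model on all primary samples using
#' the union of per-fold DMRs from an [loo_predict()] run, then scores the
#' external samples. External features are matched by name; an error is
#' raised if fewer than half of the model features are present, and missing
#' values are imputed by primary-training means.
#'
#' @param loo An `LOOResult` from the primary cohort.
#' @param features The primary sample-by-feature matrix the LOO was run on.
#' @param external_features Sample-by-feature matrix for the external set.
#' @return List with `scores` (external), `refit_scores` (primary samples
#'   scored by the same refit model) and `frac_features_present`.
#' @export
score_external <- function(loo, features, external_features) {
  stopifnot(inherits(loo, "LOOResult"))
  x <- as.matrix(features)
  ext <- as.matrix(external_features)
  feats <- loo$dmr_union
  if (length(feats) == 0L) stop("no DMRs were selected in any fold", call. = FALSE)
  present <- vapply(feats, function(f) {
    f %in% colnames(ext) && any(!is.na(ext[, f]))
  }, logical(1L))
  frac <- mean(present)
  if (frac < 0.5) stop(sprintf(
    "only %.0f%% of model features present in external set (need >= 50%%)", 100 * frac),
    call. = FALSE)
  feats <- feats[present]
  y <- loo$labels == loo$positive
  imp <- .impute_by_col(x[, feats, drop = FALSE])
  fit <- .fit_binary_model(imp$x, y, alpha = loo$alpha, seed = .derive_seed(loo$seed, 0L))
  xe <- ext[, feats, drop = FALSE]
  for (j in seq_len(ncol(xe))) {
    nas <- is.na(xe[, j]); if (any(nas)) xe[nas, j] <- imp$means[j]
  }
  list(scores = stats::setNames(fit$score(xe), rownames(ext)),
       refit_scores = stats::setNames(fit$score(imp$x), rownames(x)),
       frac_features_present = frac)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC equals the probability that a random positive sample scores above
#' a random negative one, with ties counted 1/2 — computed from midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels aligned to scores.
#' @param positive Label of the positive class. For logical labels, `TRUE`.
#' @return A `ROCCurve` list: thresholds, tpf, fpf, auc.
#' @export
roc_auc <- function(scores, labels, positive = TRUE) {
  y <- as.character(labels) == as.character(positive)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpf <- vapply(thr, function(t) sum(scores >= t & y) / n1, 0)
  fpf <- vapply(thr, function(t) sum(scores >= t & !y) / n0, 0)
  structure(list(thresholds = thr, tpf = tpf, fpf = fpf, auc = auc),
            class = "ROCCurve")
}
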