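# Three-class (control / HCC-like / PDAC-like) prediction per modality and
# integration of modalities by probability averaging.

#' Top-k DMRs per pairwise comparison for three-class models
#'
#' For each of the three pairwise group comparisons, every candidate window
#' is t-tested (Welch) between the pair, windows are ranked by p-value, and
#' the top `k` per pair are taken; the union (at most 3k features) is
#' returned. The selection is purely rank-based — no p-value floor — so with
#' uninformative data 3k windows are still returned.
#'
#' @param features Sample-by-window level matrix (typically restricted to
#'   regulatory windows).
#' @param labels Three-class group labels.
#' @param k Windows kept per pairwise comparison (default 5).
#' @param candidates Optional candidate window ids.
#' @return Character vector of selected window ids (union across pairs),
#'   with a `per_pair` attribute listing each pair's picks.
#' @export
pairwise_top_dmrs <- function(features, labels, k = 5, candidates = NULL) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  k <- .check_count(k, "k")
  if (!is.null(candidates)) x <- x[, intersect(candidates, colnames(x)), drop = FALSE]
  groups <- sort(unique(labels))
  if (any(table(labels) < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  per_pair <- list()
  for (pr in pairs) {
    A <- x[labels == pr[1L], , drop = FALSE]
    B <- x[labels == pr[2L], , drop = FALSE]
    st <- .t_test_matrix(A, B)
    ord <- order(st$p, na.last = TRUE)
    per_pair[[paste(pr, collapse = "_vs_")]] <- colnames(x)[utils::head(ord, k)]
  }
  out <- unique(unlist(per_pair, use.names = FALSE))
  attr(out, "per_pair") <- per_pair
  out
}

# Linear SVM with pairwise-coupled probability calibration on the training
# rows; returns a closure giving class probabilities in `classes` order.
.fit_multiclass_svm <- function(x, y, classes, seed = 1L) {
  set.seed(seed)
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  fit <- tryCatch(
    suppressWarnings(e1071::svm(x, factor(y, levels = classes), kernel = "linear",
                                probability = TRUE, scale = !const)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  function(newx) {
    pr <- attr(stats::predict(fit, newx, probability = TRUE), "probabilities")
    pr[, classes, drop = FALSE]
  }
}

#' Three-class leave-one-out prediction for one modality
#'
#' For each fold, one sample is held out; optionally, pairwise top-k DMR
#' selection ([pairwise_top_dmrs()]) is run on the training rows only; a
#' linear maximum-margin classifier with pairwise-coupled probability
#' calibration is fit on the training rows and the held-out sample's
#' three-class probability vector recorded. Folds whose model cannot be fit
#' (e.g. all features constant) get the uniform probability vector and are
#' flagged degenerate.
#'
#' @param features Sample-by-feature matrix.
#' @param labels Three-class group labels.
#' @param modality Label recorded on the result ("methylation", "tissue",
#'   "fragmentation", ...).
#' @param k Per-pair DMR count; `NULL` (default) disables selection and uses
#'   the raw matrix.
#' @param candidates Optional candidate feature ids for selection.
#' @param seed Integer seed (probability calibration is cross-validated).
#' @return A `ModalityPrediction`: `probs` (sample x class, rows sum to 1),
#'   `predicted`, `classes`, `degenerate`.
#' @export
modality_loo <- function(features, labels, modality = "modality", k = NULL,
                         candidates = NULL, seed = 1) {
  x <- as.matrix(features)
  if (is.null(rownames(x))) rownames(x) <- sprintf("sample_%02d", seq_len(nrow(x)))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  classes <- sort(unique(labels))
  if (any(table(labels) < 2L)) stop("each class needs >= 2 samples", call. = FALSE)
  n <- nrow(x)
  probs <- matrix(NA_real_, n, length(classes), dimnames = list(rownames(x), classes))
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    feats <- colnames(x)
    if (!is.null(k)) {
      feats <- pairwise_top_dmrs(x[tr, , drop = FALSE], labels[tr], k = k,
                                 candidates = candidates)
    } else if (!is.null(candidates)) {
      feats <- intersect(candidates, colnames(x))
    }
    imp <- .impute_by_col(x[tr, feats, drop = FALSE])
    sc <- .fit_multiclass_svm(imp$x, labels[tr], classes,
                              seed = .derive_seed(seed, i))
    if (is.null(sc)) {
      probs[i, ] <- 1 / length(classes)
      degenerate[i] <- TRUE
      next
    }
    xt <- x[i, feats, drop = FALSE]
    nas <- is.na(xt[1L, ])
    if (any(nas)) xt[1L, nas] <- imp$means[nas]
    probs[i, ] <- sc(xt)[1L, ]
  }
  structure(list(modality = modality, probs = probs,
                 predicted = classes[max.col(probs, ties.method = "first")],
                 classes = classes, labels = labels, degenerate = degenerate),
            class = "ModalityPrediction")
}

#' Integrate modality predictions by probability averaging
#'
#' Element-wise mean of the class-probability matrices across modalities;
#' the final class is the argmax of the mean, with ties broken toward the
#' control class and then lexicographically.
#'
#' @param preds List of `ModalityPrediction`s over the same samples and
#'   class order.
#' @param control Name of the control class for tie-breaking (default: first
#'   class alphabetically).
#' @return An `IntegratedPrediction`: `mean_probs`, `final_class`.
#' @export
integrate_predictions <- function(preds, control = NULL) {
  stopifnot(length(preds) >= 1L, all(vapply(preds, inherits, TRUE, "ModalityPrediction")))
  ref <- preds[[1L]]
  for (p in preds[-1L]) {
    if (!identical(rownames(p$probs), rownames(ref$probs)) ||
        !identical(p$classes, ref$classes)) {
      stop("modalities must share samples and class order", call. = FALSE)
    }
  }
  classes <- ref$classes
  if (is.null(control)) control <- classes[1L]
  mean_probs <- Reduce(`+`, lapply(preds, `[[`, "probs")) / length(preds)
  pick <- function(row) {
    best <- which(row >= max(row) - 1e-12)
    cand <- classes[best]
    if (control %in% cand) control else sort(cand)[1L]
  }
  final <- apply(mean_probs, 1L, pick)
  structure(list(mean_probs = mean_probs, final_class = final,
                 classes = classes, control = control,
                 modalities = vapply(preds, `[[`, "", "modality")),
            class = "IntegratedPrediction")
}

#' Evaluate multiclass predictions against the truth
#'
#' Overall accuracy, the 3x3 confusion matrix, and the binary accuracy for
#' distinguishing control from any cancer class (cancer classes collapsed).
#'
#' @param predicted An `IntegratedPrediction`, `ModalityPrediction`, or a
#'   character vector of predicted classes.
#' @param truth True class per sample.
#' @param control Control class name for the binary collapse (default: the
#'   prediction object's control, else first class alphabetically).
#' @return List: accuracy, confusion, binary_accuracy, n.
#' @export
evaluate_multiclass <- function(predicted, truth, control = NULL) {
  if (inherits(predicted, "IntegratedPrediction")) {
    if (is.null(control)) control <- predicted$control
    predicted <- predicted$final_class
  } else if (inherits(predicted, "ModalityPrediction")) {
    predicted <- predicted$predicted
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(c(truth, predicted)))
  if (is.null(control)) control <- classes[1L]
  conf <- table(factor(truth, classes), factor(predicted, classes))
  acc <- mean(predicted == truth)
  bin <- mean((predicted == control) == (truth == control))
  list(accuracy = acc, confusion = conf, binary_accuracy = bin, n = length(truth))
}
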