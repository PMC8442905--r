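win_ids <- function(p) cfmodal:::.region_id("chr1", (0:(p - 1)) * 1000L, (1:p) * 1000L)

test_that("find_dmrs matches a hand-coded Welch t and applies both thresholds", {
  A <- matrix(c(0.80, 0.81, 0.79), 3, 1, dimnames = list(NULL, win_ids(1)))
  B <- matrix(c(0.20, 0.21, 0.19), 3, 1, dimnames = list(NULL, win_ids(1)))
  d <- find_dmrs(A, B, p_thresh = 0.002, diff_thresh = 0.05)
  expect_equal(nrow(d), 1L)
  expect_equal(d$mean_diff, 0.60)
  oracle <- welch_by_hand(A[, 1], B[, 1])
  expect_equal(d$p_value, oracle$p, tolerance = 1e-12)
  expect_lt(d$p_value, 0.002)
  expect_equal(d$direction, "hyper")

  # identical groups are never selected
  expect_equal(nrow(find_dmrs(A, A)), 0L)

  # a tiny-p window failing the difference threshold is rejected
  A2 <- matrix(c(0.500, 0.501, 0.499), 3, 1, dimnames = list(NULL, win_ids(1)))
  B2 <- A2 - 0.04
  d2 <- find_dmrs(A2, B2, p_thresh = 0.002, diff_thresh = 0.05)
  expect_equal(nrow(d2), 0L)
  d2b <- find_dmrs(A2, B2, p_thresh = 0.002, diff_thresh = 0.03)
  expect_equal(nrow(d2b), 1L)

  expect_error(find_dmrs(A[1, , drop = FALSE], B), ">= 2 samples")
})

test_that("find_dmrs is symmetric under group swap and skips missing windows", {
  set.seed(5)
  ids <- win_ids(30)
  A <- matrix(rbeta(5 * 30, 5, 2), 5, 30, dimnames = list(NULL, ids))
  B <- matrix(rbeta(5 * 30, 2, 5), 5, 30, dimnames = list(NULL, ids))
  d1 <- find_dmrs(A, B, p_thresh = 0.05, diff_thresh = 0.05)
  d2 <- find_dmrs(B, A, p_thresh = 0.05, diff_thresh = 0.05)
  expect_setequal(d1$window, d2$window)
  m <- match(d1$window, d2$window)
  expect_equal(d1$mean_diff, -d2$mean_diff[m])
  expect_equal(d1$p_value, d2$p_value[m], tolerance = 1e-12)
  expect_true(all(ifelse(d1$direction == "hyper", "hypo", "hyper") == d2$direction[m]))

  A[1, ids[1]] <- NA  # missing in a used sample: window skipped
  expect_false(ids[1] %in% find_dmrs(A, B, p_thresh = 1, diff_thresh = -1)$window)

  # vectorised Welch agrees with stats::t.test per window
  tt <- t.test(A[, 3], B[, 3])
  st <- cfmodal:::.t_test_matrix(A[, 3, drop = FALSE], B[, 3, drop = FALSE])
  expect_equal(unname(st$t), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(unname(st$p), tt$p.value, tolerance = 1e-12)
})

test_that("rank AUC equals pairwise brute force, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(sc, y)$auc, brute_force_auc(sc, y))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC curve fractions are monotone along thresholds", {
  set.seed(10)
  r <- roc_auc(runif(30), sample(c(TRUE, FALSE), 30, replace = TRUE))
  expect_true(all(diff(r$tpf) >= 0))
  expect_true(all(diff(r$fpf) >= 0))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
})

test_that("dmr_stability is the recovered fraction of the reference set", {
  expect_equal(dmr_stability(letters[1:4], letters[1:4]), 1)
  expect_equal(dmr_stability(letters[1:4], letters[5:8]), 0)
  expect_equal(dmr_stability(letters[1:4], letters[3:6]), 0.5)
  expect_error(dmr_stability(character(), letters[1:2]), "empty")
})

test_that("LOO prediction recovers planted DMR signal and reports fold selections", {
  atlas <- make_atlas(3, 600, 0.4, seed = 31)
  co <- make_cohort(atlas, c(control = 8, cancer = 8), dmr_effect = 0.2,
                    n_dmrs = 60, coverage = 10, seed = 31)
  wmm <- window_levels(co$calls, 1000, 2)
  enh <- windows_in_features(wmm, co$annotations$enhancers)
  y <- co$truth$sample_labels[rownames(wmm$levels)]
  loo <- loo_predict(wmm$levels, y, "cancer", candidates = enh, seed = 31)
  expect_length(loo$scores, 16L)
  expect_true(all(loo$scores >= 0 & loo$scores <= 1))
  expect_true(all(loo$fold_n_features > 0))            # nonzero DMRs in every fold
  expect_gt(roc_auc(loo$scores, y, "cancer")$auc, 0.9)
  # selected DMRs are dominated by planted windows
  planted <- co$truth$planted_dmrs[[1]]$window
  expect_gt(mean(loo$dmr_union %in% planted), 0.8)

  expect_error(loo_predict(wmm$levels[1:9, ], rep(c("a", "b"), c(1, 8)), "a"),
               ">= 2 samples")
})

test_that("external scoring refits on all samples and is consistent", {
  atlas <- make_atlas(3, 600, 0.4, seed = 32)
  co <- make_cohort(atlas, c(control = 8, cancer = 8), dmr_effect = 0.2,
                    n_dmrs = 60, coverage = 10, seed = 32)
  wmm <- window_levels(co$calls, 1000, 2)
  enh <- windows_in_features(wmm, co$annotations$enhancers)
  y <- co$truth$sample_labels[rownames(wmm$levels)]
  loo <- loo_predict(wmm$levels, y, "cancer", candidates = enh, seed = 32)

  # an external sample identical to a training cancer sample scores like it
  ext <- wmm$levels[c("cancer_01", "control_01"), , drop = FALSE]
  rownames(ext) <- c("ext_pos", "ext_neg")
  sc <- score_external(loo, wmm$levels, ext)
  expect_lt(abs(sc$scores["ext_pos"] - sc$refit_scores["cancer_01"]), 0.05)
  expect_gt(sc$scores["ext_pos"], sc$scores["ext_neg"])

  # cirrhosis-like samples (no planted cancer effect) score below cancer
  co2 <- make_cohort(atlas, c(control = 4, cirrhosis = 4), dmr_effect = 0,
                     n_dmrs = 0, coverage = 10, seed = 33)
  w2 <- window_levels(co2$calls, 1000, 2)
  common <- intersect(colnames(wmm$levels), colnames(w2$levels))
  sc2 <- score_external(loo, wmm$levels[, common], w2$levels[, common])
  expect_lt(mean(sc2$scores), mean(sc$refit_scores[y == "cancer"]))

  # all model features absent is an error
  none <- matrix(0.5, 2, 3, dimnames = list(c("e1", "e2"), c("x", "y", "z")))
  expect_error(score_external(loo, wmm$levels, none), "50%")
})
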