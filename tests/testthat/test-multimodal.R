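fake_pred <- function(probs, classes = c("control", "HCC", "PDAC"),
                      modality = "m") {
  colnames(probs) <- classes
  rownames(probs) <- sprintf("s%d", seq_len(nrow(probs)))
  structure(list(modality = modality, probs = probs,
                 predicted = classes[max.col(probs, ties.method = "first")],
                 classes = classes, labels = NULL, degenerate = rep(FALSE, nrow(probs))),
            class = "ModalityPrediction")
}

test_that("integration averages probabilities with the declared tie-break", {
  p1 <- fake_pred(matrix(c(0.9, 0.05, 0.05), 1))
  p2 <- fake_pred(matrix(c(0.4, 0.3, 0.3), 1))
  p3 <- fake_pred(matrix(c(0.3, 0.4, 0.3), 1))
  ip <- integrate_predictions(list(p1, p2, p3), control = "control")
  expect_equal(unname(ip$mean_probs[1, ]), c(0.9 + 0.4 + 0.3, 0.05 + 0.3 + 0.4,
                                             0.05 + 0.3 + 0.3) / 3)
  expect_equal(unname(ip$final_class), "control")

  # exact three-way tie breaks toward the control class
  q1 <- fake_pred(matrix(c(0.6, 0.2, 0.2), 1))
  q2 <- fake_pred(matrix(c(0.2, 0.6, 0.2), 1))
  q3 <- fake_pred(matrix(c(0.2, 0.2, 0.6), 1))
  it <- integrate_predictions(list(q1, q2, q3), control = "control")
  expect_equal(max(abs(it$mean_probs - 1 / 3)), 0, tolerance = 1e-12)
  expect_equal(unname(it$final_class), "control")

  # non-control tie breaks lexicographically
  r1 <- fake_pred(matrix(c(0.0, 0.5, 0.5), 1))
  expect_equal(unname(integrate_predictions(list(r1), control = "control")$final_class),
               "HCC")

  # identical matrices reproduce each modality's prediction
  same <- fake_pred(matrix(c(0.2, 0.5, 0.3, 0.6, 0.2, 0.2), 2, byrow = TRUE))
  ii <- integrate_predictions(list(same, same, same))
  expect_equal(unname(ii$final_class), same$predicted)

  other <- fake_pred(matrix(c(0.2, 0.5, 0.3, 0.1, 0.1, 0.8), 2, byrow = TRUE))
  expect_error(integrate_predictions(list(p1, other)), "share samples")
})

test_that("integrated probabilities stay within per-modality bounds and sum to 1", {
  set.seed(71)
  ps <- lapply(1:3, function(i) {
    m <- matrix(rgamma(12, 1), 4, 3)
    fake_pred(m / rowSums(m))
  })
  ip <- integrate_predictions(ps)
  expect_equal(unname(rowSums(ip$mean_probs)), rep(1, 4))
  lo <- pmin(ps[[1]]$probs, ps[[2]]$probs, ps[[3]]$probs)
  hi <- pmax(ps[[1]]$probs, ps[[2]]$probs, ps[[3]]$probs)
  expect_true(all(ip$mean_probs >= lo - 1e-12 & ip$mean_probs <= hi + 1e-12))
})

test_that("evaluation reports overall, confusion and cancer-vs-control accuracy", {
  truth <- rep(c("control", "HCC", "PDAC"), each = 4)
  perfect <- evaluate_multiclass(truth, truth, control = "control")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$binary_accuracy, 1)
  expect_equal(sum(perfect$confusion), 12)

  allc <- evaluate_multiclass(rep("control", 12), truth, control = "control")
  expect_equal(allc$accuracy, 1 / 3)

  # 64 of 74 correct
  t74 <- rep(c("control", "HCC", "PDAC"), c(30, 21, 23))
  p74 <- t74
  p74[c(1:4, 31:33, 52:54)] <- c("HCC", "HCC", "PDAC", "PDAC", "control", "control",
                                 "PDAC", "control", "control", "HCC")
  ev <- evaluate_multiclass(p74, t74, control = "control")
  expect_equal(ev$accuracy, 64 / 74)
})

test_that("pairwise top-k selection is rank-based with at most 3k features", {
  ids <- cfmodal:::.region_id("chr1", (0:99) * 1000L, (1:100) * 1000L)
  set.seed(72)
  labs <- rep(c("control", "HCC", "PDAC"), each = 6)
  x <- matrix(rnorm(18 * 100, 0.5, 0.05), 18, 100, dimnames = list(NULL, ids))
  # plant pair-specific DMRs: windows 1-3 separate HCC, 4-6 separate PDAC
  x[labs == "HCC", 1:3] <- x[labs == "HCC", 1:3] + 0.3
  x[labs == "PDAC", 4:6] <- x[labs == "PDAC", 4:6] + 0.3
  sel <- pairwise_top_dmrs(x, labs, k = 5)
  expect_lte(length(sel), 15L)
  pp <- attr(sel, "per_pair")
  expect_true(all(lengths(pp) == 5L))
  # every planted window surfaces in the union through its informative pair
  expect_true(all(ids[1:6] %in% sel))
  hcc_ctrl <- pp[[grep("HCC", grep("control", names(pp), value = TRUE), value = TRUE)]]
  expect_true(all(ids[1:3] %in% hcc_ctrl))
  pdac_ctrl <- pp[[grep("PDAC", grep("control", names(pp), value = TRUE), value = TRUE)]]
  expect_true(all(ids[4:6] %in% pdac_ctrl))

  # uninformative data: selection still returns per-pair top-k by rank
  x0 <- matrix(rnorm(18 * 100, 0.5, 0.05), 18, 100, dimnames = list(NULL, ids))
  sel0 <- pairwise_top_dmrs(x0, labs, k = 5)
  expect_true(all(lengths(attr(sel0, "per_pair")) == 5L))
  expect_gte(length(sel0), 5L)

  expect_error(pairwise_top_dmrs(x[c(1, 7:18), ], labs[c(1, 7:18)], 5), ">= 2")
})

test_that("three-class LOO with a linear margin classifier separates and calibrates", {
  mm <- make_multimodal_cohort(n_per_group = 6, effect = 6, noise_sd = 0.5, seed = 73)
  # one modality with all three classes separable
  x <- mm$modalities$methylation
  x[mm$labels == "HCC", 4:6] <- x[mm$labels == "HCC", 4:6] + 4
  pred <- modality_loo(x, mm$labels, "methylation", seed = 73)
  expect_equal(unname(rowSums(pred$probs)), rep(1, 18), tolerance = 1e-9)
  expect_true(all(pred$probs >= 0 & pred$probs <= 1))
  expect_equal(evaluate_multiclass(pred, mm$labels)$accuracy, 1)
})

test_that("label permutation drives three-class accuracy to chance", {
  accs <- vapply(1:5, function(s) {
    mm <- make_multimodal_cohort(n_per_group = 6, effect = 2, seed = 80 + s)
    set.seed(90 + s)
    perm <- sample(mm$labels)
    names(perm) <- names(mm$labels)
    pred <- modality_loo(mm$modalities$methylation, perm, "methylation", seed = s)
    evaluate_multiclass(pred, perm)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.15)
  expect_lte(mean(accs), 0.55)
})
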