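test_that("enhancer aggregation pools CpG counts with the min-CpG rule", {
  enh <- cfmodal:::.gr0("chr1", c(0L, 1000L, 2000L), c(1000L, 2000L, 3000L))
  calls <- list(s1 = cpg_table("chr1", c(100L, 200L, 1100L, 2100L),
                               c(5L, 10L, 0L, 2L), c(5L, 0L, 0L, 2L)))
  m <- aggregate_enhancers(calls, enh, min_cpgs = 1)
  expect_equal(unname(m[1, "s1"]), 0.75)        # (5+10)/(10+10)
  expect_true(is.na(m[2, "s1"]))                 # zero covered CpGs -> missing
  m3 <- aggregate_enhancers(calls, enh, min_cpgs = 3)
  expect_true(is.na(m3[1, "s1"]))                # 2 covered CpGs < 3 -> missing
})

test_that("NNLS solves the stated minimisation with clipping and homogeneity", {
  A <- diag(2); rownames(A) <- c("r1", "r2"); colnames(A) <- c("t1", "t2")
  x <- nnls_deconv(A, c(0.3, 0.7))
  expect_equal(unname(x$x), c(0.3, 0.7))
  expect_equal(sum(x$x_normalized), 1)

  # y outside the positive cone clips to the constraint
  A2 <- matrix(c(1, 0), 2, 1, dimnames = list(c("r1", "r2"), "t1"))
  x2 <- nnls_deconv(A2, c(0, 1))
  expect_equal(unname(x2$x), 0)

  # objective never exceeds the x = 0 objective ||y||^2
  set.seed(3)
  A3 <- matrix(runif(60), 20, 3)
  y3 <- runif(20)
  f <- nnls_deconv(A3, y3)
  expect_lte(f$residual_norm^2, sum(y3^2) + 1e-12)

  # homogeneity when constraints are inactive
  xt <- c(0.2, 0.5, 0.3)
  yy <- A3 %*% xt
  f1 <- nnls_deconv(A3, as.numeric(yy))
  f2 <- nnls_deconv(A3, as.numeric(3 * yy))
  expect_equal(unname(f2$x), unname(3 * f1$x), tolerance = 1e-8)

  # pairwise deletion of missing regions; all-missing errors
  ym <- as.numeric(yy); ym[1:5] <- NA
  expect_equal(unname(nnls_deconv(A3, ym)$x), xt, tolerance = 1e-6)
  expect_error(nnls_deconv(A3, rep(NA_real_, 20)), "all regions missing")
})

test_that("noise-free synthetic mixtures are recovered to numerical precision", {
  atlas <- make_atlas(6, 300, 0.4, seed = 41)
  set.seed(41)
  X <- cfmodal:::.rdirichlet(10, rep(2, 6))
  Y <- atlas$region_methylation %*% t(X)
  for (i in 1:10) {
    fit <- nnls_deconv(atlas$region_methylation, Y[, i])
    expect_lt(max(abs(fit$x_normalized - X[i, ])), 1e-6)
  }
})

test_that("tissue-specific DMR selection handles degenerate and invariance cases", {
  atlas <- make_atlas(3, 200, 0.4, seed = 42)
  reps <- atlas_replicates(atlas, 3, 100, seed = 42)

  # constant region across tissues is never selected
  m <- reps$samples
  m["chr1:0-1000", ] <- 0.5
  sel <- tissue_specific_dmrs(m, reps$tissue_labels)
  expect_false("chr1:0-1000" %in% sel$regions)

  # invariant to sample column order
  ord <- sample(ncol(m))
  sel2 <- tissue_specific_dmrs(m[, ord], reps$tissue_labels[ord])
  expect_setequal(sel$regions, sel2$regions)

  # invariant to replicate duplication (medians unchanged)
  m3 <- cbind(m, m[, reps$tissue_labels == "tissue_01"])
  lab3 <- c(reps$tissue_labels, rep("tissue_01", sum(reps$tissue_labels == "tissue_01")))
  sel3 <- tissue_specific_dmrs(m3, lab3)
  expect_setequal(sel$regions, sel3$regions)

  # two identical tissue groups: zero differences fall below the floor
  dup <- cbind(m[, 1:3], m[, 1:3])
  expect_warning(
    sel4 <- tissue_specific_dmrs(dup, rep(c("a", "b"), each = 3)),
    "no regions")
  expect_length(sel4$regions, 0L)

  # zero planted effect: nothing passes at any positive margin
  flat <- make_atlas(3, 100, effect = 0, seed = 43)
  one_rep <- flat$region_methylation  # single noise-free replicate per tissue
  expect_warning(
    sel5 <- tissue_specific_dmrs(one_rep, colnames(one_rep), min_diff = 1e-9),
    "no regions")
  expect_length(sel5$regions, 0L)
})

test_that("the reference atlas is the per-tissue median and clusters sister tissues", {
  atlas <- make_atlas(4, 200, 0.4, seed = 44)
  reps <- atlas_replicates(atlas, 3, 100, seed = 44)
  ref <- build_reference(reps$samples, reps$tissue_labels)
  expect_equal(dim(ref$A), c(200L, 4L))
  i <- reps$tissue_labels == "tissue_01"
  expect_equal(unname(ref$A[, "tissue_01"]),
               unname(apply(reps$samples[, i], 1, median)))

  # single replicate per tissue: A equals that replicate
  one <- reps$samples[, c(1, 4, 7, 10)]
  ref1 <- build_reference(one, reps$tissue_labels[c(1, 4, 7, 10)])
  expect_equal(unname(ref1$A), unname(one))

  # duplicating a tissue's replicate set leaves the median unchanged
  dup <- cbind(reps$samples, reps$samples[, i])
  ref2 <- build_reference(dup, c(reps$tissue_labels, reps$tissue_labels[i]))
  expect_equal(ref2$A, ref$A)

  # sister tissues sharing perturbed baselines cluster together
  base <- atlas$region_methylation[, 1]
  sisters <- cbind(a1 = base + rnorm(200, sd = 0.01), a2 = base + rnorm(200, sd = 0.01),
                   b1 = 1 - base + rnorm(200, sd = 0.01), b2 = 1 - base + rnorm(200, sd = 0.01))
  cl <- cutree(hclust(dist(t(cfmodal:::.clip01(sisters)))), k = 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_false(cl[["a1"]] == cl[["b1"]])
})

test_that("contribution comparison matches a hand-coded Welch test and has power", {
  a <- c(0.11, 0.14, 0.09, 0.12, 0.13)
  b <- c(0.08, 0.07, 0.10, 0.06, 0.09)
  res <- compare_contribution(list(a, b), test = "t")
  oracle <- welch_by_hand(a, b)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)

  same <- list(rep(0.1, 5), rep(0.1, 5))
  expect_equal(compare_contribution(same)$p_value, 1)
  expect_equal(compare_contribution(same)$statistic, 0)

  set.seed(45)
  g1 <- rnorm(20, 0.10, 0.02)
  g2 <- rnorm(20, 0.05, 0.02)
  expect_lt(compare_contribution(list(g1, g2))$p_value, 0.01)
  expect_error(compare_contribution(list(g1, 0.1)), ">= 2 values")
})

test_that("the contribution LOO model separates admixed groups and nails a label feature", {
  atlas <- make_atlas(5, 300, 0.4, seed = 46)
  co <- make_cohort(atlas, c(control = 8, cancer = 8), dmr_effect = 0, n_dmrs = 0,
                    coverage = 30, seed = 46,
                    admixture = list(group = "cancer", tissue = "tissue_03", fraction = 0.15))
  wmm <- window_levels(co$calls, 1000, 2)
  contrib <- t(vapply(rownames(wmm$levels), function(s) {
    nnls_deconv(atlas$region_methylation, wmm$levels[s, rownames(atlas$region_methylation)])$x_normalized
  }, numeric(5)))
  y <- co$truth$sample_labels[rownames(contrib)]
  loo <- contribution_model(contrib, y, "cancer", seed = 46)
  expect_gt(roc_auc(loo$scores, y, "cancer")$auc, 0.9)

  # a single feature equal to the label is learned perfectly
  lab <- rep(c("x", "y"), each = 6)
  feats <- cbind(f1 = as.numeric(lab == "x"), f2 = rep(0.5, 12))
  loo2 <- loo_predict(feats, lab, "x", select = FALSE, seed = 1)
  expect_equal(roc_auc(loo2$scores, lab, "x")$auc, 1)
})
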