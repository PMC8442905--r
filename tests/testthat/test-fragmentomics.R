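test_that("length extraction handles tables, sign conventions and SAM input", {
  h <- fragment_profile(extract_lengths(c(167, 167, 320)))$histogram
  expect_equal(h$count[h$length == 167], 2L)
  expect_equal(h$count[h$length == 320], 1L)

  expect_equal(as.integer(extract_lengths(c(-167, 200))), c(167L, 200L))
  expect_error(extract_lengths(numeric()), "no fragment lengths")
  expect_error(extract_lengths(c(2000, 3000)), "no fragment lengths")

  # SAM: pairs counted once via positive template length; duplicates and
  # unpaired records excluded
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t99\tchr1\t100\t60\t50M\t=\t217\t167\t*\t*",
    "r1\t147\tchr1\t217\t60\t50M\t=\t100\t-167\t*\t*",
    "r2\t1123\tchr1\t300\t60\t50M\t=\t570\t320\t*\t*",   # duplicate-marked
    "r2\t1171\tchr1\t570\t60\t50M\t=\t300\t-320\t*\t*",
    "r3\t0\tchr1\t800\t60\t50M\t*\t0\t0\t*\t*"            # unpaired
  ), sam)
  lens <- extract_lengths(sam)
  expect_equal(as.integer(lens), 167L)
  lens2 <- extract_lengths(sam, drop_duplicates = FALSE)
  expect_setequal(as.integer(lens2), c(167L, 320L))
})

test_that("bin fractions use half-open bins and the full-window denominator", {
  p <- fragment_profile(rep(305L, 100L))
  expect_equal(unname(p$bin_fractions["[300,310)"]), 1)
  expect_equal(sum(p$bin_fractions), 1)
  expect_equal(p$n_fragments, 100L)

  # a length of exactly 300 falls in the first long bin
  p2 <- fragment_profile(c(300L, 100L))
  expect_equal(unname(p2$bin_fractions["[300,310)"]), 0.5)
  expect_equal(p2$long_fraction, 0.5)
  expect_equal(p2$short_fraction, 0.5)

  # denominator is the full-window total, not the sub-range
  p3 <- fragment_profile(c(rep(305L, 10L), rep(167L, 90L)))
  expect_equal(unname(p3$bin_fractions["[300,310)"]), 0.1)

  expect_error(fragment_profile(167L, bin_width = 7), "divide")
})

test_that("histograms are order invariant, conserve totals and merge additively", {
  set.seed(51)
  a <- make_fragments(5000, seed = 51)
  b <- make_fragments(3000, group_shift = 0.05, seed = 52)
  pa <- fragment_profile(a)
  expect_equal(sum(pa$histogram$count), length(a))
  expect_equal(fragment_profile(sample(a))$bin_fractions, pa$bin_fractions)
  merged <- fragment_profile(c(a, b))$histogram
  ha <- pa$histogram; hb <- fragment_profile(b)$histogram
  joint <- merge(ha, hb, by = "length", all = TRUE)
  joint[is.na(joint)] <- 0L
  expect_equal(merged$count, joint$count.x + joint$count.y)
})

test_that("synthetic fragments show the nucleosomal peak structure and shift", {
  lens <- make_fragments(100000, seed = 53)
  p <- fragment_profile(lens)
  expect_equal(p$histogram$length[which.max(p$histogram$count)], 167L)
  # modal 10-bp bin matches the main peak
  expect_equal(names(which.max(p$bin_fractions)), "[160,170)")
  # comb peaks below 167 at 10-bp spacing: each sub-peak beats its neighbours
  cnt <- setNames(p$histogram$count, p$histogram$length)
  for (k in 1:4) {
    pk <- 167 - 10 * k
    expect_gt(cnt[as.character(pk)], cnt[as.character(pk - 5)])
    expect_gt(cnt[as.character(pk)], cnt[as.character(pk + 5)])
  }
  # secondary peak near 320: more mass in [300,340) than [340,380)
  expect_gt(sum(cnt[as.character(300:339)], na.rm = TRUE),
            sum(cnt[as.character(340:379)], na.rm = TRUE))

  shifted <- fragment_profile(make_fragments(100000, group_shift = 0.05, seed = 53))
  expect_gt(shifted$short_fraction, p$short_fraction)
  expect_equal(shifted$short_fraction - p$short_fraction, 0.05, tolerance = 0.015)
  expect_lt(shifted$long_fraction, p$long_fraction)
})

test_that("Kruskal-Wallis group test matches the rank-sum oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  res <- group_test(g)
  expect_equal(res$statistic, kruskal_by_hand(g), tolerance = 1e-12)
  expect_equal(res$p_value, kruskal.test(unlist(g), rep(1:2, each = 3))$p.value)

  tied <- list(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(group_test(tied)$statistic, kruskal_by_hand(tied), tolerance = 1e-12)

  expect_equal(group_test(list(rep(1, 3), rep(1, 3)))$statistic, 0)
  expect_equal(group_test(list(rep(1, 3), rep(1, 3)))$p_value, 1)

  set.seed(54)
  three <- list(rnorm(30), rnorm(30), rnorm(30, mean = 1))
  expect_lt(group_test(three)$p_value, 0.05)
  expect_error(group_test(list(1:3)), "2")
})

test_that("the long-bin matrix feeds the LOO fragment classifier", {
  profs <- lapply(setNames(1:6, sprintf("s%d", 1:6)), function(s) {
    fragment_profile(make_fragments(20000, group_shift = ifelse(s > 3, 0.05, 0), seed = 60 + s))
  })
  m <- long_bin_matrix(profs)
  expect_equal(dim(m), c(6L, 20L))
  expect_true(all(startsWith(colnames(m), "[3") | startsWith(colnames(m), "[4")))
  y <- rep(c("control", "cancer"), each = 3)
  # constant features trigger the degenerate-fold path
  const <- matrix(0.5, 6, 20, dimnames = dimnames(m))
  loo <- frag_model(const, y, "cancer")
  expect_true(all(loo$degenerate))
  expect_true(all(loo$scores == 0.5))
})
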