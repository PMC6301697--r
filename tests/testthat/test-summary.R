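test_that("a synchronized synthetic slice summarizes as expected", {
  t <- 0:143
  A <- outer(cos(2 * pi * t / 24), rep(1, 20)) +
    matrix(withr::with_seed(1, rnorm(144 * 20, sd = 0.05)), 144, 20)
  mov <- BiolumMovie(A, coords = data.frame(x = 1:20, y = 0))
  s <- summarizeSlice(mov)
  expect_equal(s@periodMean, 24, tolerance = 0.2)
  expect_lt(s@periodSd, 0.5)
  expect_gt(s@eig12Sum, 90)
  expect_gt(s@syncMean, 0.95)
  expect_output(show(s), "period")
  # deterministic: identical summaries for identical movies
  s2 <- summarizeSlice(mov)
  expect_identical(s@eig12Sum, s2@eig12Sum)
  expect_identical(s@periodMean, s2@periodMean)
})

test_that("an independent-noise slice shows no rhythm structure", {
  s <- summarizeSlice(fixtureMovie("white-noise"))
  expect_true(is.na(s@periodMean)) # no periodogram-significant pixels
  expect_equal(s@nRhythmic, 0L)
  expect_lt(s@eig12Sum, 35)
  expect_lt(s@syncMean, 3 / sqrt(40)) # near the finite-N floor
})

test_that("one-way ANOVA matches the textbook oracle on a toy table", {
  vals <- c(1, 2, 3, 5, 6, 7, 9, 10, 11)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- groupCompare(vals, grp, level = 0.01)
  # hand computation: group means 2, 6, 10; grand mean 6
  ssb <- 3 * ((2 - 6)^2 + (6 - 6)^2 + (10 - 6)^2) # 96
  ssw <- sum((vals - rep(c(2, 6, 10), each = 3))^2) # 6
  fOracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$fStatistic, fOracle, tolerance = 1e-12)
  expect_lt(res$pValue, 0.01)

  # Fisher LSD equals unpooled... pairwise t with pooled SD, no adjustment
  pt <- stats::pairwise.t.test(vals, grp, p.adjust.method = "none",
                               pool.sd = TRUE)
  expect_equal(res$lsd$p[res$lsd$group1 == "a" & res$lsd$group2 == "b"],
               pt$p.value["b", "a"], tolerance = 1e-12)
  expect_equal(res$lsd$p[res$lsd$group1 == "b" & res$lsd$group2 == "c"],
               pt$p.value["c", "b"], tolerance = 1e-12)
})

test_that("clearly separated groups are detected, singletons dropped", {
  vals <- withr::with_seed(2, c(rnorm(4), rnorm(4, mean = 5)))
  expect_true(groupCompare(vals, rep(c("x", "y"), each = 4))$lsd$significant)
  expect_warning(
    res <- groupCompare(c(vals, 99), c(rep(c("x", "y"), each = 4), "z")),
    "single slice")
  expect_equal(nrow(res$lsd), 1)
  expect_error(suppressWarnings(groupCompare(1:3, c("a", "a", "b"))),
               "two groups")
})

test_that("ANOVA type-I error is near nominal under the null", {
  hits <- vapply(seq_len(400), function(s) {
    vals <- withr::with_seed(s, rnorm(30))
    groupCompare(vals, rep(letters[1:6], each = 5), level = 0.01)$pValue < 0.01
  }, logical(1))
  expect_lt(mean(hits), 0.035)
})
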