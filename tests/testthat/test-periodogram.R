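test_that("noiseless cosine periods are located exactly on the grid", {
  t <- 0:143
  for (p in c(20, 24, 32)) {
    best <- chisqPeriodogram(cos(2 * pi * t / p))$bestPeriod
    expect_equal(best, p, tolerance = 1e-9)
  }
})

test_that("white noise is declared arrhythmic at the 1 percent line", {
  hits <- vapply(seq_len(100), function(s) {
    x <- withr::with_seed(s, rnorm(144))
    !is.na(chisqPeriodogram(x)$bestPeriod)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("the pointwise line is available and behaves as a pointwise test", {
  # per-candidate false-positive rate near the nominal 1% when unadjusted
  rate <- mean(vapply(seq_len(40), function(s) {
    x <- withr::with_seed(s + 500, rnorm(144))
    cv <- chisqPeriodogram(x, adjust = "none")$curve
    mean(cv$significant)
  }, numeric(1)))
  expect_lt(rate, 0.05)
  expect_gt(rate, 0.0005)
})

test_that("periodogram guards its grid", {
  expect_error(chisqPeriodogram(rnorm(144), periods = c(24, 20)), "increasing")
  expect_error(chisqPeriodogram(rnorm(144), dt = 20, periods = c(24, 30)),
               "coarser")
  expect_error(chisqPeriodogram(rnorm(60)), "3 cycles")
})

test_that("acrophase reads off the cosine peak time", {
  t <- 0:143
  expect_equal(acrophase(cos(2 * pi * (t - 5) / 24), period = 24, times = t),
               5, tolerance = 1e-6)
  expect_equal(acrophase(-cos(2 * pi * t / 24), period = 24, times = t),
               12, tolerance = 1e-6)
  expect_warning(ph <- acrophase(rep(0, 144), period = 24),
                 "zero-amplitude")
  expect_true(is.na(ph))
})

test_that("acrophase is robust to noise at moderate SNR", {
  t <- 0:143
  ok <- vapply(seq_len(40), function(s) {
    x <- cos(2 * pi * (t - 7) / 24) +
      withr::with_seed(s, rnorm(144, sd = sqrt(0.5 / 5)))
    err <- abs(acrophase(x, period = 24, times = t) - 7)
    min(err, 24 - err) < 1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
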