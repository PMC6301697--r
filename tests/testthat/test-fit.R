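test_that("a noise-free cosine is recognized as a clean oscillator", {
  t <- 0:239
  tr <- new("CellTrace", times = as.numeric(t),
            x = cos(2 * pi * t / 24), y = numeric(0))
  fit <- fitOscillator(tr, seed = 1)
  expect_equal(intrinsicPeriod(fit$params), 24, tolerance = 0.02)
  expect_lt(fit$params@dPhi, 0.01)
  expect_lt(fit$params@dR, 0.02)
  expect_equal(fit$label, "self-sustained")
})

test_that("identifiable shape parameters are recovered from the exact ACF", {
  # the normalized ACF identifies (period, gamma, D_phi) at known CV; the
  # CV direction itself is near-degenerate and is estimated from the
  # fourth-moment channel instead (see the estimation tests below)
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.316^2 * 0.05, dPhi = 0.005)
  lag <- 0:72
  mod <- modelACF(p, lag, method = "spectral")
  fit <- fitACFCurve(lag, mod, traceLength = Inf, varX = NA, seed = 1,
                     fixedCV = computeCV(p)$cv)
  expect_equal(intrinsicPeriod(fit$params), 24, tolerance = 1e-3)
  expect_equal(fit$params@dPhi, 0.005, tolerance = 0.05)
  expect_equal(fit$params@damping, 0.05, tolerance = 0.05)
  expect_lt(fit$residual, 1e-8)
})

test_that("period and CV class are recovered from simulated records", {
  # a weakly damped, weakly noisy oscillator over 10 days: the period is
  # sharply identified; the CV direction is only weakly identified at
  # these parameters (slow amplitude dynamics give ~12 independent
  # amplitude draws per record), so the recovery claim is at the level of
  # the oscillator class, not the 25% point estimate
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.005, dPhi = 0.005)
  truthCV <- computeCV(p)$cv
  res <- vapply(seq_len(20), function(s) {
    tr <- simulateCell(p, duration = 240, seed = s)
    f <- fitOscillator(tr, seed = s)
    c(intrinsicPeriod(f$params), f$cv)
  }, numeric(2))
  expect_equal(median(res[1, ]), 24, tolerance = 0.05 * 24)
  expect_lt(median(res[2, ]), 1)            # self-sustained class
  expect_lt(abs(log(median(res[2, ]) / truthCV)), log(3)) # within 3x
})

test_that("estimated CV is monotone in the true CV and labels the extremes", {
  gam <- 0.3
  med <- vapply(c(0.2, 0.8, 2.0), function(cv) {
    p <- OscillatorParams(alpha = 1, period = 24, damping = gam,
                          dR = cv^2 * gam, dPhi = 0.01)
    est <- vapply(seq_len(8), function(s)
      fitOscillator(simulateCell(p, duration = 480, seed = s + 40),
                    seed = s)$cv, numeric(1))
    median(est)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_lt(med[1], 1) # clean oscillators labelled self-sustained
  expect_gt(med[3], 1) # heavily noisy ones labelled damped
})

test_that("fitting is deterministic given trace and seed", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.005, dPhi = 0.005)
  tr <- simulateCell(p, duration = 240, seed = 2)
  f1 <- fitOscillator(tr, seed = 9)
  f2 <- fitOscillator(tr, seed = 9)
  expect_identical(f1$cv, f2$cv)
  expect_identical(f1$params@omega, f2$params@omega)
})

test_that("estimation refuses records that are too short", {
  tr <- new("CellTrace", times = as.numeric(0:80),
            x = cos(2 * pi * (0:80) / 24), y = numeric(0))
  expect_error(fitOscillator(tr), "96 h")
})
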