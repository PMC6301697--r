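test_that("noise-free rendering preserves the traces exactly", {
  sc <- tinyScenario(cellsPerLobe = 12, duration = 72)
  run <- simulateNetwork(sc, seed = 1)
  im <- ImagingModel(baseline = 1000, decayTau = 1e9, gain = 0.5,
                     noiseModel = "gaussian-scaled", noiseScale = 0,
                     pixelsPerCell = 1L)
  mov <- renderMovie(run, imaging = im, seed = 1)
  A <- movieMatrix(mov)
  for (k in c(1, 5, 12))
    expect_equal(cor(A[, k], run@traces[, k]), 1, tolerance = 1e-9)
})

test_that("decaying movies survive the preprocessing round trip", {
  sc <- tinyScenario(cellsPerLobe = 12, duration = 144)
  run <- simulateNetwork(sc, seed = 2)
  im <- ImagingModel(decayTau = 100)
  pp <- preprocessMovie(renderMovie(run, imaging = im, seed = 2))
  A <- movieMatrix(pp)
  ppc <- im@pixelsPerCell
  for (k in c(1, 7)) {
    cell <- (k - 1) %/% ppc + 1
    expect_gt(cor(A[, k], run@traces[, cell]), 0.9)
  }
})

test_that("poisson-like noise has variance proportional to the mean", {
  mu <- rep(c(1e3, 5e3, 2e4, 1e5), each = 4000)
  im <- ImagingModel(noiseModel = "poisson-like")
  counts <- withr::with_seed(3, scnCoupling:::addImagingNoise(mu, im))
  ratio <- tapply((counts - mu)^2, mu, mean) / unique(mu)
  expect_true(all(abs(ratio - 1) < 0.1))
  expect_true(all(counts >= 0))
})

test_that("rendered pixels reflect the two-lobed geometry", {
  sc <- tinyScenario(cellsPerLobe = 12, duration = 72)
  run <- simulateNetwork(sc, seed = 4)
  mov <- renderMovie(run, seed = 4)
  expect_equal(nrow(movieMatrix(mov)), length(run@times))
  expect_equal(ncol(movieMatrix(mov)), 4 * 24)
  co <- pixelCoords(mov)
  expect_equal(sum(co$x < 0), sum(co$x > 0))
})

test_that("dispersed rendering recovers the two cell populations", {
  mk <- function(cv, gam, dphi)
    OscillatorParams(alpha = 1, period = 24, damping = gam,
                     dR = cv^2 * gam, dPhi = dphi)
  wt <- mk(0.3, 0.05, 0.005)
  dko <- mk(1.8, 0.3, 0.02)
  for (cfg in list(list(p = wt, damped = FALSE),
                   list(p = dko, damped = TRUE))) {
    traces <- renderDispersed(rep(list(cfg$p), 10), duration = 360,
                              seed = 42)
    cvs <- vapply(seq_along(traces), function(i)
      fitOscillator(traces[[i]], seed = i, detrend = "moving")$cv,
      numeric(1))
    if (cfg$damped) expect_gt(median(cvs), 1) else expect_lt(median(cvs), 1)
  }
})

test_that("degenerate rendering inputs are handled explicitly", {
  empty <- renderDispersed(list(wtParams()), duration = 0, seed = 1)
  expect_length(empty, 1)
  expect_length(empty[[1]]@times, 0)
  expect_error(ImagingModel(baseline = -5), "baseline")
  expect_error(ImagingModel(decayTau = 0), "decayTau")
})

test_that("fixtures are bit-identical across calls and leave the RNG alone", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  f1 <- fixtureMovie("white-noise")
  after <- rnorm(1)
  expect_identical(before, after) # RNG state restored
  f2 <- fixtureMovie("white-noise")
  expect_identical(movieMatrix(f1), movieMatrix(f2))
  expect_error(fixtureMovie("nope"))
})

test_that("render -> preprocess -> EOF round trip matches the noise-free path", {
  sc <- scenarioPreset("neonate-wt", seed = 5, cellsPerLobe = 40,
                       duration = 144)
  run <- simulateNetwork(sc)
  eigNoisy <- sum(normalizedEigenvalues(
    computeEOF(preprocessMovie(renderMovie(run, seed = 5))))[1:2])
  eigClean <- sum(normalizedEigenvalues(
    computeEOF(preprocessMovie(runToMovie(run))))[1:2])
  expect_lt(abs(eigNoisy - eigClean), 5)
})
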