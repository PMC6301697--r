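test_that("diffusive coupling is conservative (antisymmetry)", {
  sc <- tinyScenario(cellsPerLobe = 25)
  W <- scnCoupling:::couplingMatrix(sc)
  deg <- Matrix::rowSums(W)
  x <- withr::with_seed(3, rnorm(nrow(sc@geometry@cells)))
  coupling <- as.vector(W %*% x) - deg * x
  expect_lt(abs(sum(coupling)) / sum(abs(coupling)), 1e-10)
})

test_that("strong coupling locks identical noise-free cells", {
  sc <- tinyScenario(cellsPerLobe = 16, duration = 72)
  sc@params <- quietParams()
  sc@omega <- rep(2 * pi / 24, nrow(sc@geometry@cells))
  sc@initPhaseSd <- NA_real_ # uniform random start
  sc@burnin <- 96
  run <- simulateNetwork(sc, seed = 4)
  sync <- syncIndex(preprocessMovie(runToMovie(run)))
  expect_gt(sync$mean, 0.98)
})

test_that("uncoupled heterogeneous cells disperse like independent cells", {
  sc <- tinyScenario(cellsPerLobe = 20, duration = 96)
  sc@aVip <- 0; sc@aAvp <- 0
  sc@initPhaseSd <- NA_real_
  run <- simulateNetwork(sc, seed = 5)
  syncNet <- syncIndex(preprocessMovie(runToMovie(run)))$mean

  # oracle: the same cells simulated one by one (no coupling by design)
  n <- nrow(sc@geometry@cells)
  oracle <- vapply(seq_len(n), function(i) {
    p <- sc@params
    pi_ <- OscillatorParams(alpha = p@alpha, omega = sc@omega[i],
                            damping = p@damping, dR = p@dR, dPhi = p@dPhi)
    simulateCell(pi_, duration = 96, dt = sc@dt, seed = 100 + i)@x
  }, numeric(96))
  syncInd <- syncIndex(preprocessMovie(
    BiolumMovie(oracle, coords = data.frame(x = seq_len(n), y = 0))))$mean
  # both sit near the finite-N floor, far below synchrony
  expect_lt(syncNet, 0.5)
  expect_lt(abs(syncNet - syncInd), 0.35)
})

test_that("strong single-channel forcing entrains uncoupled cells to 24 h", {
  sc <- tinyScenario(cellsPerLobe = 16, duration = 144)
  sc@aVip <- 0; sc@aAvp <- 0
  sc@iAvp <- 0.3; sc@iVip <- 0
  sc@initPhaseSd <- NA_real_
  sc@burnin <- 48
  run <- simulateNetwork(sc, seed = 6)
  pp <- preprocessMovie(runToMovie(run))
  pg <- periodogramMovie(pp)
  per <- pg$bestPeriod[!is.na(pg$bestPeriod)]
  expect_gt(length(per), 0.8 * ncol(movieMatrix(pp)))
  expect_equal(as.numeric(names(which.max(table(round(per))))), 24)
  expect_gt(syncIndex(pp)$mean, 0.9)
})

test_that("simulation is reproducible and guards against divergence", {
  sc <- tinyScenario(cellsPerLobe = 16, duration = 48)
  r1 <- simulateNetwork(sc, seed = 7)
  r2 <- simulateNetwork(sc, seed = 7)
  expect_identical(r1@traces, r2@traces)
  r3 <- simulateNetwork(sc, seed = 8)
  expect_false(identical(r1@traces, r3@traces))

  scBad <- sc
  scBad@iAvp <- 1e7 # absurd forcing escapes the attractor
  expect_error(simulateNetwork(scBad, seed = 1), "diverged")
  scStiff <- sc
  scStiff@dt <- 1
  expect_error(simulateNetwork(scStiff, seed = 1), "step size")
})

test_that("synchronization index is non-decreasing in coupling strength", {
  sc <- scenarioPreset("neonate-tko", seed = 2, cellsPerLobe = 30,
                       duration = 96)
  sw <- sweepSynchronization(sc, list(aAvp = c(0, 0.5, 1)),
                             replicates = 4, seed = 2)
  expect_true(all(diff(sw$syncMean) > -sw$syncSd[-1] / 2))
  expect_gt(sw$syncMean[3], sw$syncMean[1])
})

test_that("sweeps are deterministic and validate their grid", {
  sc <- tinyScenario(cellsPerLobe = 12, duration = 48)
  s1 <- sweepSynchronization(sc, list(aVip = c(0, 1)), replicates = 1,
                             seed = 3)
  s2 <- sweepSynchronization(sc, list(aVip = c(0, 1)), replicates = 1,
                             seed = 3)
  expect_identical(s1, s2)
  expect_error(sweepSynchronization(sc, list(), replicates = 1), "grid")
  expect_error(sweepSynchronization(sc, list(nope = 1), replicates = 1),
               "unknown")
})

test_that("scenario presets encode the genotype and co-culture conditions", {
  tko <- scenarioPreset("neonate-tko", seed = 1, cellsPerLobe = 10)
  expect_equal(tko@aVip, 0)
  expect_equal(tko@iAvp, 0)
  expect_equal(tko@iVip, 0)
  expect_false(tko@vipReceptor)

  dko <- scenarioPreset("neonate-dko", seed = 1, cellsPerLobe = 10)
  expect_equal(dko@aVip, 0.1)
  expect_equal(dko@aAvp, 0.1)

  cc <- scenarioPreset("coculture-dko", seed = 1, cellsPerLobe = 10)
  expect_equal(cc@iVip, 0.01)
  expect_equal(cc@iAvp, 0.01)
  expect_equal(cc@phi, 11)

  ccA <- scenarioPreset("coculture-dko-antagonist", seed = 1,
                        cellsPerLobe = 10)
  expect_true(ccA@antagonist)
  expect_equal(ccA@iAvp, 0)
  expect_equal(ccA@aAvp, 0)

  off <- scenarioPreset("coculture-tko-antagonist", seed = 1,
                        cellsPerLobe = 10)
  expect_equal(off@aVip, 0)
  expect_equal(off@aAvp, 0)
  expect_equal(off@iAvp, 0)
  expect_false(off@vipReceptor) # graft VIP cannot act either

  sp <- scenarioPreset("neonate-dko-split", seed = 1, cellsPerLobe = 30)
  right <- sp@geometry@cells$lobe == "right"
  expect_gt(mean(2 * pi / sp@omega[right]),
            mean(2 * pi / sp@omega[!right]) + 3)
  expect_lt(sp@bridgeFactor, 0.1)

  expect_error(scenarioPreset("neonate-wildtype"), "unknown preset")
  expect_error(NetworkScenario(buildGeometry(10), wtParams(), phi = 30),
               "phi")
})
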