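test_that("parameter container enforces its invariants", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.005, dPhi = 0.005)
  expect_s4_class(p, "OscillatorParams")
  expect_equal(intrinsicPeriod(p), 24)
  expect_equal(omega(p), 2 * pi / 24)
  expect_error(OscillatorParams(alpha = -1), "alpha")
  expect_error(OscillatorParams(omega = 0), "omega")
  expect_error(OscillatorParams(damping = 0), "damping")
  expect_error(OscillatorParams(dR = -0.1), "dR")
})

test_that("CV criterion separates self-sustained from damped oscillators", {
  # no amplitude noise: CV = 0
  p0 <- OscillatorParams(alpha = 1, period = 24, damping = 0.05, dR = 0)
  expect_equal(computeCV(p0)$cv, 0)
  expect_equal(computeCV(p0)$label, "self-sustained")

  # parameters tuned so the stationary amplitude s.d. is 0.5 alpha
  gam <- 0.05 # damping * alpha^2 at alpha = 1
  pHalf <- OscillatorParams(alpha = 1, period = 24, damping = gam,
                            dR = 0.25 * gam)
  expect_equal(computeCV(pHalf)$cv, 0.5)
  expect_equal(computeCV(pHalf)$label, "self-sustained")

  # tuned so the stationary s.d. is 2 alpha: damped
  pTwo <- OscillatorParams(alpha = 1, period = 24, damping = gam,
                           dR = 4 * gam)
  expect_equal(computeCV(pTwo)$cv, 2)
  expect_equal(computeCV(pTwo)$label, "damped")
})

test_that("CV conventions coincide at alpha = 1 and scale as documented", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05, dR = 0.0045)
  cvs <- vapply(c("linearized", "lambda-alpha", "lambda"),
                function(r) computeCV(p, rate = r)$cv, numeric(1))
  expect_equal(unname(cvs), rep(0.3, 3))

  p2 <- OscillatorParams(alpha = 0.5, period = 24, damping = 0.2, dR = 0.0045)
  expect_equal(computeCV(p2, rate = "linearized")$cv,
               sqrt(0.0045 / (0.2 * 0.25)) / 0.5)
  expect_equal(computeCV(p2, rate = "lambda")$cv,
               sqrt(0.0045 / 0.2) / 0.5)
})

test_that("reference parameter sets land in their intended regimes", {
  expect_equal(computeCV(oscillatorPreset("wild-type fit"))$label,
               "self-sustained")
  expect_equal(computeCV(oscillatorPreset("dko fit"))$label, "damped")
  expect_equal(computeCV(oscillatorPreset("dko fit"))$cv, 1.5,
               tolerance = 1e-6)
  expect_lt(computeCV(oscillatorPreset("dko-rhythmic fit"))$cv, 1)
  expect_output(show(oscillatorPreset("wild-type fit")), "self-sustained")
})
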