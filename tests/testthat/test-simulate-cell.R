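test_that("noise-free on-cycle simulation conserves radius and phase", {
  p <- quietParams(damping = 0.03)
  tr <- simulateCell(p, duration = 240, dt = 0.01, seed = 1)
  r <- sqrt(tr@x^2 + tr@y^2)
  expect_lt(max(abs(r - 1)), 1e-3) # 10 periods at dt = 0.01
  expect_equal(tr@x, cos(2 * pi * tr@times / 24), tolerance = 1e-3)
  # reproducibility given seed
  tr2 <- simulateCell(p, duration = 240, dt = 0.01, seed = 1)
  expect_identical(tr@x, tr2@x)
})

test_that("off-cycle relaxation matches a high-resolution radial ODE oracle", {
  # the radial equation implied by the Cartesian model is
  # dr/dt = -damping * r^2 * (r - alpha)
  p <- quietParams(damping = 0.03)
  tr <- simulateCell(p, duration = 96, dt = 0.01, seed = 1,
                     initialState = c(2, 0))
  r <- sqrt(tr@x^2 + tr@y^2)
  expect_true(all(diff(r) <= 1e-9)) # monotone decay toward the cycle
  oracle <- deSolve::ode(
    y = c(r = 2), times = tr@times,
    func = function(t, y, parms) list(-0.03 * y^2 * (y - 1)))[, "r"]
  expect_equal(r, unname(oracle), tolerance = 1e-4)
})

test_that("radial noise reproduces the 1-D radial SDE's stationary variance", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.005, dPhi = 0)
  tr <- simulateCell(p, duration = 8000, seed = 3)
  r2d <- sqrt(tr@x^2 + tr@y^2)
  # independent oracle: reflected 1-D Euler of dr = -l r^2 (r-a) dt + ...
  oracle <- local({
    set.seed(11)
    dt <- 0.01
    sig <- sqrt(2 * 0.005 * dt)
    r <- 1
    out <- numeric(8000)
    k <- 0
    for (i in seq_len(8e5)) {
      r <- abs(r - 0.05 * r^2 * (r - 1) * dt + sig * rnorm(1))
      if (i %% 100 == 0) { k <- k + 1; out[k] <- r }
    }
    out
  })
  expect_equal(var(r2d), var(oracle), tolerance = 0.1)
})

test_that("ensemble phase variance grows linearly at rate 2 D_phi", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0, dPhi = 0.005)
  tms <- NULL
  dev <- vapply(seq_len(200), function(s) {
    tr <- simulateCell(p, duration = 120, seed = s)
    tms <<- tr@times
    raw <- atan2(tr@y, tr@x)
    d <- diff(raw)
    d[d > pi] <- d[d > pi] - 2 * pi
    d[d < -pi] <- d[d < -pi] + 2 * pi
    th <- cumsum(c(raw[1], d))
    (th - 2 * pi / 24 * tr@times)[length(th)]
  }, numeric(1))
  slope <- var(dev) / tms[length(tms)]
  expect_equal(slope, 2 * 0.005, tolerance = 0.15)
})

test_that("ACF envelope decay increases monotonically with phase noise", {
  envAt24 <- vapply(c(0.002, 0.01, 0.05), function(dphi) {
    p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                          dR = 0, dPhi = dphi)
    tr <- simulateCell(p, duration = 2000, seed = 4)
    abs(traceACF(tr, maxLag = 48)$acf[25])
  }, numeric(1))
  expect_true(all(diff(envAt24) < 0))
})

test_that("simulation guards reject unusable arguments", {
  p <- quietParams()
  expect_error(simulateCell(p, duration = -5, seed = 1), "duration")
  expect_error(simulateCell(p, duration = 48, dt = 2, seed = 1), "step size")
  expect_error(simulateCell(p, duration = 48, dt = 0.011, seed = 1),
               "multiple of dt")
})

test_that("spectral model ACF agrees with the empirical ACF of long runs", {
  for (cv in c(0.316, 1)) {
    gam <- 0.05
    p <- OscillatorParams(alpha = 1, period = 24, damping = gam,
                          dR = cv^2 * gam, dPhi = 0.005)
    tr <- simulateCell(p, duration = 20000, seed = 9)
    emp <- traceACF(tr, maxLag = 72, detrend = FALSE)
    mod <- modelACF(p, emp$lag, method = "spectral")
    expect_lt(sqrt(mean((emp$acf - mod)^2)), 0.05)
  }
})

test_that("analytic and spectral model ACFs agree in the small-CV limit", {
  p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
                        dR = 0.1^2 * 0.05, dPhi = 0.01)
  lag <- 0:72
  expect_equal(modelACF(p, lag, method = "spectral"),
               modelACF(p, lag, method = "analytic"), tolerance = 0.02)
})
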