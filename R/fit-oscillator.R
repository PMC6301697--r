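#' Estimate oscillator parameters from a trace by autocorrelation fitting
#'
#' The five model parameters are estimated by least-squares matching of the
#' sample ACF to the model ACF over lags \code{[0, maxLag]}. A normalized
#' ACF identifies only the shape parameters (period \eqn{2\pi/\omega},
#' phase diffusion \eqn{D_\phi}, radial relaxation rate
#' \eqn{\gamma = \lambda\alpha^2}, and the amplitude coefficient of
#' variation CV); the amplitude scale is then recovered from the trace
#' variance via \eqn{Var(x) = \alpha^2 E[v^2] / 2} (with \eqn{E[v^2]} the
#' second moment of the dimensionless radial process, see [modelACF()]),
#' after which \eqn{\lambda = \gamma/\alpha^2} and
#' \eqn{D_r = CV^2\alpha^2\gamma}. Because the biased sample ACF of a
#' stationary process has expectation \eqn{(1 - \tau/T)\rho(\tau)}, the
#' model curve is tapered by the same finite-sample factor before
#' comparison.
#'
#' With the default spectral model ACF the fit is profiled over CV: for
#' each candidate CV (whose radial correlation is one exact
#' eigendecomposition) the remaining three parameters are optimized by
#' bounded quasi-Newton (L-BFGS-B) from \code{restarts} deterministic
#' multi-starts, and the CV profile is then refined by golden-section
#' search. Ties are broken by lowest residual, then lowest CV.
#'
#' The normalized ACF is close to degenerate in CV (for CV above roughly
#' 0.3 the radial correlation reduces to a Kramers-hopping exponential
#' that is exchangeable with phase diffusion), so by default
#' (\code{cvFromKurtosis = TRUE}) the CV is estimated through a second,
#' independent data channel: the fourth moment. The sample kurtosis of the
#' detrended trace is inverted against a parametric-bootstrap reference
#' curve — the mean sample kurtosis of traces simulated from the fitted
#' model at the observed record length over a grid of candidate CVs —
#' which self-calibrates the substantial short-record bias of the
#' kurtosis. The shape parameters are then re-fitted at the final CV.
#'
#' @param detrend trend removal before analysis: "linear" (least-squares
#'   line, default, appropriate for stationary model traces) or "moving"
#'   (centered 24-h moving average, for raw luminescence records with
#'   baseline decay).
#' @param cvFromKurtosis logical; estimate CV via the bootstrap-calibrated
#'   kurtosis channel (default) rather than from the ACF profile alone.
#' @param trace a [CellTrace-class]; at least 96 h at hourly sampling.
#' @param init initial [OscillatorParams-class] or \code{"auto"}.
#' @param maxLag fitting lag range in hours (default 72).
#' @param method model-ACF route passed to [modelACF()].
#' @param restarts number of multi-start restarts (default 5).
#' @param seed seed controlling the deterministic jittered restarts.
#' @param periodRange search bounds for the period (h).
#' @return A list: \code{params} (fitted [OscillatorParams-class]),
#'   \code{residual} (mean squared ACF misfit), \code{cv}, \code{label},
#'   and \code{converged} (FALSE when all restarts hit the iteration
#'   bound; the best attempt is still returned).
#' @examples
#' p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
#'                       dR = 0.005, dPhi = 0.005)
#' tr <- simulateCell(p, duration = 240, seed = 7)
#' fit <- fitOscillator(tr, seed = 7)
#' intrinsicPeriod(fit$params)
#' @export
fitOscillator <- function(trace, init = "auto", maxLag = 72,
                          method = c("spectral", "analytic", "simulated"),
                          restarts = 5, seed = 1L,
                          periodRange = c(16, 40),
                          detrend = c("linear", "moving"),
                          cvFromKurtosis = TRUE) {
  stopifnot(is(trace, "CellTrace"))
  dt <- if (length(trace@times) > 1) diff(trace@times)[1] else 1
  T <- length(trace@x)
  if (T * dt < 96) stop("need a record of at least 96 h for estimation")
  maxLag <- min(maxLag, (T - 1) * dt / 3)
  method <- match.arg(method)
  detrend <- match.arg(detrend)
  xd <- if (detrend == "linear") {
    stats::residuals(stats::lm(trace@x ~ trace@times))
  } else {
    # raw luminescence: remove the slow baseline AND equalize the decaying
    # oscillation amplitude, as in the slice-movie preprocessing; without
    # the moving-s.d. normalization the amplitude decay masquerades as
    # heavy-tailed amplitude noise
    h <- max(1L, round(24 / dt / 2))
    mom <- runningMoments(matrix(trace@x, ncol = 1), h)
    s <- pmax(mom$sd, 1e-12)
    as.vector((trace@x - mom$mean) / s)
  }
  emp <- traceACF(xd, maxLag = maxLag, detrend = FALSE, dt = dt)
  fit <- fitACFCurve(emp$lag, emp$acf, traceLength = T * dt,
                     varX = stats::var(xd), init = init, method = method,
                     restarts = restarts, seed = seed,
                     periodRange = periodRange)
  if (cvFromKurtosis && method == "spectral") {
    statObs <- shapeStatistics(xd)
    # reference traces must pass through the same detrending operator as
    # the data: moving-window normalization leaves its own signature
    # (anti-correlation near the window scale, suppressed slow power)
    # that the references have to share for the inversion to be fair
    detrendFun <- if (detrend == "linear") {
      function(x, tms) stats::residuals(stats::lm(x ~ tms))
    } else {
      function(x, tms) {
        mom <- runningMoments(matrix(x, ncol = 1),
                              max(1L, round(24 / dt / 2)))
        as.vector((x - mom$mean) / pmax(mom$sd, 1e-12))
      }
    }
    # per-candidate shape parameters: the best ACF fit the data admits at
    # each candidate CV, so the bootstrap reference is self-consistent
    cvGrid <- c(0.05, 0.15, 0.3, 0.5, 0.75, 1, 1.4, 2, 3)
    cand <- lapply(cvGrid, function(cv)
      fitACFCurve(emp$lag, emp$acf, traceLength = T * dt, varX = NA,
                  init = fit$params, method = method, restarts = 2,
                  seed = seed, periodRange = periodRange, fixedCV = cv))
    cvK <- calibratedKurtosisCV(
      statObs,
      gam = vapply(cand, function(f)
        radialRelaxationRate(f$params, "linearized"), numeric(1)),
      dPhi = vapply(cand, function(f) f$params@dPhi, numeric(1)),
      omega = fit$params@omega,
      recordLength = T * dt, sampleInterval = dt, cvGrid = cvGrid,
      seed = deriveSeed(seed, "kurt-boot"), detrendFun = detrendFun)
    fit <- fitACFCurve(emp$lag, emp$acf, traceLength = T * dt,
                       varX = stats::var(xd), init = fit$params,
                       method = method, restarts = restarts, seed = seed,
                       periodRange = periodRange, fixedCV = cvK)
  }
  fit
}

# Scale-invariant distribution-shape statistics of a detrended trace:
# excess of the fourth moment, mid-range occupation (self-sustained
# oscillators avoid zero, noisy damped ones concentrate there), and
# L-kurtosis (a robust tail-weight measure).
shapeStatistics <- function(xd) {
  rms <- sqrt(mean(xd^2))
  z <- sort(xd / rms)
  n <- length(z)
  i <- seq_len(n)
  b0 <- mean(z)
  b1 <- sum((i - 1) / (n - 1) * z) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * z) / n
  b3 <- sum((i - 1) * (i - 2) * (i - 3) /
              ((n - 1) * (n - 2) * (n - 3)) * z) / n
  l2 <- 2 * b1 - b0
  l4 <- 20 * b3 - 30 * b2 + 12 * b1 - b0
  qs <- stats::quantile(abs(z), c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  # envelope dynamics: increment variance and short-lag coherence of the
  # analytic-signal amplitude track the radial noise channel directly,
  # which the marginal shape statistics cannot resolve at large CV
  e <- Mod(analyticSignal(matrix(xd, ncol = 1)))
  de <- diff(e)
  ac1 <- stats::cor(e[-length(e)], e[-1])
  # fourth-order temporal structure: the autocorrelation of x^2 probes the
  # amplitude-channel timescale, which the (second-order) ACF of x cannot
  # separate from the CV along its degeneracy ridge
  sq <- stats::acf(xd^2, lag.max = 8, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  c(kurt = mean(xd^4) / rms^4,
    mid = mean(abs(xd) < 0.35 * rms),
    lkurt = l4 / l2,
    q10 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q90 = qs[5],
    envInc = mean(de^2) / mean(e^2),
    envAc1 = if (is.finite(ac1)) ac1 else 0,
    envCV = stats::sd(e) / mean(e),
    sq1 = sq[2], sq2 = sq[3], sq4 = sq[5], sq8 = sq[9])
}

# Invert observed distribution-shape statistics against a
# parametric-bootstrap reference: for each candidate CV, model traces of
# the observed length are simulated (dimensionless signed-radius process
# plus an independently sampled diffusing phase; shape statistics are
# scale-invariant) with that candidate's own best-fitting shape
# parameters, and the candidate minimizing the noise-normalized distance
# to the observed statistics is selected, with quadratic interpolation of
# the distance profile around the minimum.
calibratedKurtosisCV <- function(statObs, gam, dPhi, omega, recordLength,
                                 sampleInterval = 1, seed = 1L,
                                 cvGrid = c(0.05, 0.15, 0.3, 0.5, 0.75,
                                            1, 1.4, 2, 3),
                                 replicates = 12L, detrendFun = NULL) {
  if (is.null(detrendFun))
    detrendFun <- function(x, tms) stats::residuals(stats::lm(x ~ tms))
  gam <- pmin(pmax(rep_len(gam, length(cvGrid)), 1e-3), 1)
  dPhi <- rep_len(dPhi, length(cvGrid))
  nSamp <- floor(recordLength / sampleInterval)
  tms <- (seq_len(nSamp) - 1) * sampleInterval
  nStat <- length(statObs)
  refMean <- matrix(NA_real_, length(cvGrid), nStat)
  refSd <- matrix(NA_real_, length(cvGrid), nStat)
  for (i in seq_along(cvGrid)) {
    ks <- vapply(seq_len(replicates), function(r) {
      sd <- deriveSeed(seed, sprintf("kb-%d-%d", i, r))
      u <- signedRadiusPath(cvGrid[i], sScale = gam[i], times = tms,
                            seed = sd)
      th <- withSeed(sd + 1L, omega * tms +
                       cumsum(rnorm(nSamp, 0,
                                    sqrt(2 * dPhi[i] * sampleInterval))))
      x <- u * cos(th)
      shapeStatistics(detrendFun(x, tms))
    }, numeric(nStat))
    refMean[i, ] <- rowMeans(ks)
    refSd[i, ] <- apply(ks, 1, stats::sd)
  }
  pooledSd <- pmax(colMeans(refSd), 1e-6)
  dist <- rowSums(sweep(sweep(refMean, 2, statObs), 2, pooledSd, "/")^2)
  iBest <- which.min(dist)
  # quadratic interpolation of the distance profile in log CV
  if (iBest > 1 && iBest < length(cvGrid)) {
    lx <- log(cvGrid[(iBest - 1):(iBest + 1)])
    dy <- dist[(iBest - 1):(iBest + 1)]
    den <- (dy[1] - 2 * dy[2] + dy[3])
    if (is.finite(den) && den > 0) {
      delta <- 0.5 * (dy[1] - dy[3]) / den
      delta <- max(min(delta, 1), -1)
      return(exp(lx[2] + delta * (lx[3] - lx[1]) / 2))
    }
  }
  cvGrid[iBest]
}

# Tamed-Euler path of the dimensionless signed-radius diffusion
# dv = -v^2 (v - sgn v) ds + sqrt(2) CV dW, sampled at s = sScale * times;
# drift taming keeps the superlinear restoring force stable at coarse
# steps and large CV.
signedRadiusPath <- function(cv, sScale, times, seed = 1L) {
  dsTarget <- min(0.01, 0.2 / (1 + cv)^3)
  dsSample <- sScale * (if (length(times) > 1) diff(times)[1] else 1)
  sub <- max(1L, ceiling(dsSample / dsTarget))
  ds <- dsSample / sub
  n <- length(times)
  out <- numeric(n)
  withSeed(seed, {
    xi <- rnorm((n - 1L) * sub, 0, sqrt(2 * ds) * cv)
    v <- 1
    out[1] <- v
    k <- 0L
    for (i in seq_len((n - 1L) * sub)) {
      f <- -v^2 * (v - sign(v))
      v <- v + f * ds / (1 + ds * abs(f)) + xi[i]
      if (i %% sub == 0L) { k <- k + 1L; out[k + 1L] <- v }
    }
  })
  out
}

#' Fit the model ACF to an autocorrelation curve
#'
#' Lower-level engine behind [fitOscillator()], exposed so that a model ACF
#' (or any externally computed ACF) can be fitted directly. With
#' \code{traceLength = Inf} no finite-sample taper is applied.
#'
#' @param lags,acf the ACF curve to fit.
#' @param traceLength record length (h) used for the finite-sample taper;
#'   \code{Inf} for an exact (population) ACF.
#' @param varX trace variance used to set the amplitude scale; \code{NA}
#'   leaves \code{alpha = 1}.
#' @inheritParams fitOscillator
#' @return See [fitOscillator()].
#' @export
fitACFCurve <- function(lags, acf, traceLength = Inf, varX = NA,
                        init = "auto",
                        method = c("spectral", "analytic", "simulated"),
                        restarts = 5, seed = 1L, periodRange = c(16, 40),
                        fixedCV = NULL) {
  method <- match.arg(method)
  keep <- is.finite(acf)
  lags <- lags[keep]; acf <- acf[keep]
  taper <- if (is.finite(traceLength)) pmax(1 - lags / traceLength, 0) else 1

  lower <- c(periodRange[1], log(1e-4), log(1e-6))
  upper <- c(periodRange[2], log(2), log(1))

  starts0 <- list()
  initCV <- NA_real_
  if (is(init, "OscillatorParams")) {
    initCV <- computeCV(init)$cv
    starts0[[1]] <- c(intrinsicPeriod(init),
                      log(max(radialRelaxationRate(init, "linearized"), 1e-4)),
                      log(max(init@dPhi, 1e-6)))
  } else {
    starts0[[1]] <- autoStart(lags, acf, periodRange)
  }
  if (restarts > 1) {
    jit <- withSeed(deriveSeed(seed, "fit-restarts"), {
      lapply(seq_len(restarts - 1), function(i)
        c(runif(1, periodRange[1], periodRange[2]),
          log(runif(1, 5e-3, 0.5)), log(runif(1, 1e-4, 0.3))))
    })
    starts0 <- c(starts0, jit)
  }
  starts0 <- lapply(starts0, function(s) pmin(pmax(s, lower), upper))

  # inner optimization of (period, log gamma, log dPhi) at fixed CV;
  # subsequent grid points are warm-started from the previous optimum
  innerFit <- function(cv, starts) {
    radialShape <- switch(method,
      spectral = {
        rad <- radialCorrelation(cv)
        function(gam) radialCorrEval(rad, gam * lags)
      },
      analytic = function(gam)
        (1 + cv^2 * exp(-gam * lags)) / (1 + cv^2),
      simulated = {
        mc <- simulatedRadialCorr(cv, seed = seed)
        function(gam) stats::approx(mc$s, mc$corr, xout = gam * lags,
                                    rule = 2)$y
      })
    objective <- function(theta) {
      mu <- radialShape(exp(theta[2])) * exp(-exp(theta[3]) * lags) *
        cos(2 * pi / theta[1] * lags)
      mean((acf - taper * mu)^2)
    }
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      res <- tryCatch(
        stats::optim(s, objective, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (res$convergence == 0) conv <- TRUE
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) return(list(value = Inf, converged = FALSE))
    list(value = best$value, par = best$par, converged = conv)
  }

  if (!is.null(fixedCV)) {
    best <- innerFit(fixedCV, starts0)
    if (!is.finite(best$value)) stop("ACF fitting failed from every start")
    return(finishFit(fixedCV, best, method, varX))
  }
  cvGrid <- c(0.02, 0.05, 0.1, 0.15, 0.22, 0.32, 0.45, 0.65, 0.9,
              1.2, 1.6, 2.2, 3)
  if (is.finite(initCV)) cvGrid <- sort(unique(c(cvGrid, initCV)))
  prof <- vector("list", length(cvGrid))
  prevPar <- NULL
  for (i in seq_along(cvGrid)) {
    starts <- if (is.null(prevPar)) starts0
              else c(list(prevPar), starts0[1])
    prof[[i]] <- innerFit(cvGrid[i], starts)
    if (is.finite(prof[[i]]$value)) prevPar <- prof[[i]]$par
  }
  vals <- vapply(prof, `[[`, numeric(1), "value")
  iBest <- which(vals <= min(vals) + 1e-15)[1] # ties -> lowest CV
  bestCV <- cvGrid[iBest]
  best <- prof[[iBest]]
  warm <- function(cv) innerFit(cv, c(list(best$par), starts0[1]))

  # golden-section refinement of the CV profile around the grid minimum
  lo <- cvGrid[max(iBest - 1, 1)]
  hi <- cvGrid[min(iBest + 1, length(cvGrid))]
  if (hi > lo) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- warm(c1); f2 <- warm(c2)
    for (i in seq_len(6)) {
      if (f1$value < f2$value) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- warm(c1)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- warm(c2)
      }
    }
    cand <- if (f1$value < f2$value) list(cv = c1, fit = f1)
            else list(cv = c2, fit = f2)
    if (cand$fit$value < best$value) { bestCV <- cand$cv; best <- cand$fit }
  }
  if (!is.finite(best$value)) stop("ACF fitting failed from every start")
  finishFit(bestCV, best, method, varX)
}

# assemble OscillatorParams from the profile optimum and the trace variance
finishFit <- function(cv, best, method, varX) {
  gam <- exp(best$par[2])
  Ev2 <- if (method == "spectral") radialMoment(cv) else 1 + cv^2
  alphaScale <- if (is.na(varX)) 1 else sqrt(2 * varX / Ev2)
  params <- OscillatorParams(alpha = alphaScale, period = best$par[1],
                             damping = gam / alphaScale^2,
                             dR = cv^2 * alphaScale^2 * gam,
                             dPhi = exp(best$par[3]))
  cvOut <- computeCV(params)
  list(params = params, residual = best$value, cv = cvOut$cv,
       label = cvOut$label, converged = best$converged)
}

# second moment E[v^2] of the dimensionless radial process
radialMoment <- function(cv, nGrid = 201L) {
  if (cv < 1e-6) return(1)
  vmax <- 1 + max(4 * sqrt(cv), 2.5 * cv)
  v <- seq(-vmax, vmax, length.out = nGrid)
  U <- v^4 / 4 - abs(v)^3 / 3
  p <- exp(-U / cv^2); p <- p / sum(p)
  sum(p * v^2)
}

# spectral/envelope initial guess for the ACF fit
autoStart <- function(lags, acf, periodRange) {
  pos <- lags > 0
  # dominant period from the ACF's own spectrum
  sp <- stats::spec.pgram(acf, plot = FALSE, detrend = TRUE, taper = 0)
  dlag <- if (sum(pos)) min(diff(lags)) else 1
  per <- dlag / sp$freq
  ok <- per >= periodRange[1] & per <= periodRange[2]
  p0 <- if (any(ok)) per[ok][which.max(sp$spec[ok])] else mean(periodRange)
  # envelope decay from the ACF magnitude near one period
  i1 <- which.min(abs(lags - p0))
  env <- min(max(abs(acf[i1]), 1e-3), 0.999)
  d0 <- max(-log(env) / p0, 1e-5)
  c(p0, log(0.05), log(d0))
}

# Monte-Carlo estimate of the dimensionless radial correlation (the
# simulation-based alternative to the spectral route): one long Euler run
# of dv = -v^2(v - sgn v) ds + sqrt(2) CV dW.
simulatedRadialCorr <- function(cv, length = 3000, ds = 0.01, seed = 1L) {
  if (cv < 1e-6) return(list(s = c(0, 1e6), corr = c(1, 1)))
  thin <- 5L
  n <- round(length / ds)
  out <- numeric(n %/% thin)
  withSeed(deriveSeed(seed, "radial-mc"), {
    xi <- rnorm(n) * sqrt(2 * ds) * cv
    v <- 1
    k <- 0L
    for (i in seq_len(n)) {
      v <- v - v^2 * (v - sign(v)) * ds + xi[i]
      if (i %% thin == 0L) { k <- k + 1L; out[k] <- v }
    }
  })
  a <- stats::acf(out, lag.max = min(k - 1, 4000), plot = FALSE,
                  demean = FALSE)$acf[, 1, 1]
  list(s = (seq_along(a) - 1) * ds * thin, corr = a)
}
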