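#' Simulate a single stochastic amplitude-phase oscillator
#'
#' Stochastic Heun integration (second-order predictor-corrector drift with
#' explicit Gaussian increments) of the noisy limit-cycle model (see
#' [OscillatorParams-class]). The Gaussian noise pair acts in the local
#' radial/tangential frame: an increment of s.d. \code{sqrt(2 dR dt)} along
#' the radial unit vector and a phase increment of s.d.
#' \code{sqrt(2 dPhi dt)} along the tangential direction (displacement
#' \code{r dphi}), rotated back into Cartesian coordinates. This makes both
#' named noise intensities directly interpretable: the radial deviation is
#' an Ornstein-Uhlenbeck process of intensity \code{dR}, and the unwrapped
#' phase diffuses with variance \code{2 dPhi t}.
#'
#' @param params an [OscillatorParams-class].
#' @param duration total simulated time (h, > 0).
#' @param dt integration step (h); must satisfy the stability guard
#'   \code{dt * max(damping * alpha, omega) < 0.1}.
#' @param sampleInterval recording interval (h), a multiple of \code{dt};
#'   samples are taken at \code{0, sampleInterval, ...} (the endpoint
#'   \code{duration} is excluded).
#' @param seed integer seed; the trajectory is reproducible given the seed.
#' @param initialState either the string \code{"on-cycle"} (start at
#'   \code{(alpha, 0)}, i.e. on the limit cycle at phase 0) or a numeric
#'   \code{c(x, y)}.
#' @return A [CellTrace-class] carrying both coordinates.
#' @examples
#' p <- OscillatorParams(alpha = 1, period = 24, damping = 0.03)
#' tr <- simulateCell(p, duration = 48, seed = 1)
#' max(abs(sqrt(tr@x^2 + tr@y^2) - 1)) # noise-free: stays on the cycle
#' @export
simulateCell <- function(params, duration, dt = 0.01, sampleInterval = 1,
                         seed = 1L, initialState = "on-cycle") {
  stopifnot(is(params, "OscillatorParams"))
  if (!isScalarNumber(duration) || duration < 0)
    stop("duration must be a non-negative number")
  if (duration < sampleInterval)
    stop("duration must cover at least one sample interval")
  if (dt * max(params@damping * params@alpha, params@omega) >= 0.1)
    stop("unstable step size: require dt * max(damping*alpha, omega) < 0.1")
  thin <- round(sampleInterval / dt)
  if (abs(thin * dt - sampleInterval) > 1e-9)
    stop("sampleInterval must be a multiple of dt")

  if (identical(initialState, "on-cycle")) {
    x0 <- params@alpha; y0 <- 0
  } else {
    stopifnot(is.numeric(initialState), length(initialState) == 2L)
    x0 <- initialState[1]; y0 <- initialState[2]
  }
  lam <- params@damping; al <- params@alpha; om <- params@omega
  sigR <- sqrt(2 * params@dR * dt)
  sigP <- sqrt(2 * params@dPhi * dt)
  nSamp <- floor(duration / sampleInterval)
  nStep <- (nSamp - 1L) * thin
  xs <- numeric(nSamp); ys <- numeric(nSamp)
  xs[1] <- x0; ys[1] <- y0
  withSeed(seed, {
    x <- x0; y <- y0
    if (nStep > 0) {
      xi1 <- rnorm(nStep); xi2 <- rnorm(nStep)
      k <- 1L
      for (s in seq_len(nStep)) {
        # Heun (predictor-corrector) drift + explicit noise increment:
        # the second-order drift step removes the outward radius bias of
        # the plain Euler rotation.
        r <- sqrt(x * x + y * y)
        common <- lam * r * (r - al)
        f1x <- -common * x - om * y
        f1y <- -common * y + om * x
        xp <- x + f1x * dt; yp <- y + f1y * dt
        rp <- sqrt(xp * xp + yp * yp)
        commonP <- lam * rp * (rp - al)
        f2x <- -commonP * xp - om * yp
        f2y <- -commonP * yp + om * xp
        rs <- max(r, 1e-8)
        ux <- x / rs; uy <- y / rs
        xn <- x + (f1x + f2x) * dt / 2 + sigR * xi1[s] * ux - sigP * xi2[s] * y
        yn <- y + (f1y + f2y) * dt / 2 + sigR * xi1[s] * uy + sigP * xi2[s] * x
        x <- xn; y <- yn
        if (s %% thin == 0L) {
          k <- k + 1L
          xs[k] <- x; ys[k] <- y
        }
      }
    }
  })
  new("CellTrace", times = (seq_len(nSamp) - 1) * sampleInterval, x = xs, y = ys)
}

#' Autocorrelation function of a trace
#'
#' Biased sample ACF (normalized by the total length, so values are bounded
#' in [-1, 1]), returned for non-negative lags only. The trace is linearly
#' detrended by default before the ACF is formed.
#'
#' @param trace a [CellTrace-class] (or numeric vector; then \code{dt}
#'   gives the sampling interval).
#' @param maxLag maximum lag in hours; must not exceed a third of the
#'   record length.
#' @param detrend logical, remove a least-squares linear trend first.
#' @param dt sampling interval when \code{trace} is a bare vector.
#' @return A data.frame with columns \code{lag} (h) and \code{acf}.
#' @export
traceACF <- function(trace, maxLag = 72, detrend = TRUE, dt = NULL) {
  if (is(trace, "CellTrace")) {
    x <- trace@x
    dt <- if (length(trace@times) > 1) diff(trace@times)[1] else 1
  } else {
    x <- as.numeric(trace)
    if (is.null(dt)) dt <- 1
  }
  T <- length(x)
  if (maxLag > (T - 1) * dt / 3 + 1e-9)
    stop("maxLag must not exceed a third of the record length")
  if (detrend) x <- stats::residuals(stats::lm(x ~ seq_along(x)))
  v <- sum((x - mean(x))^2) / T
  if (v <= .Machine$double.eps * max(1, mean(x)^2))
    stop("constant trace: autocorrelation normalization undefined")
  nlag <- floor(maxLag / dt)
  a <- stats::acf(x, lag.max = nlag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  data.frame(lag = (0:nlag) * dt, acf = a)
}

#' Model autocorrelation function of the stochastic oscillator
#'
#' In the signed-radius representation \eqn{x = u\cos\theta} (the radial
#' coordinate continued through the origin, so that near-origin passages
#' appear as sign changes of \eqn{u} rather than phase slips of
#' \eqn{\theta}), the model ACF factorizes exactly:
#' \deqn{\rho(\tau) = \hat{C}(\gamma\tau;\, CV)\, e^{-D_\phi\tau}
#'   \cos(\omega\tau),}
#' where \eqn{\gamma = \lambda\alpha^2} and \eqn{\hat{C}} is the
#' normalized autocorrelation of the dimensionless radial diffusion
#' \eqn{dv = -v^2(v - \mathrm{sgn}\,v)\,ds + \sqrt{2}\,CV\,dW}, a symmetric
#' double-well process whose shape depends on CV alone. The default
#' \code{method = "spectral"} computes \eqn{\hat{C}} exactly from the
#' eigendecomposition of the discretized radial generator (this captures
#' the Kramers hopping between the two wells, i.e. amplitude-noise-induced
#' phase slips, which dominate decorrelation for CV above roughly 0.3).
#' \code{method = "analytic"} is the fast Ornstein-Uhlenbeck closed form
#' \eqn{(1 + CV^2 e^{-\gamma\tau}) e^{-D_\phi\tau}\cos(\omega\tau)/(1+CV^2)}
#' (accurate for small CV only), and \code{method = "simulated"} estimates
#' the ACF from long seed-averaged simulations of the full model.
#'
#' @param params an [OscillatorParams-class].
#' @param lags numeric vector of lags (h).
#' @param method "spectral" (exact, default), "analytic" (small-CV closed
#'   form), or "simulated".
#' @param simLength,simReplicates length (h) and number of averaged
#'   replicate simulations for \code{method = "simulated"}.
#' @param seed seed for the simulated estimate.
#' @return Numeric vector of ACF values at \code{lags}.
#' @export
modelACF <- function(params, lags,
                     method = c("spectral", "analytic", "simulated"),
                     simLength = 2000, simReplicates = 4, seed = 1L) {
  method <- match.arg(method)
  if (method == "spectral") {
    gam <- radialRelaxationRate(params, "linearized")
    cv <- computeCV(params)$cv
    rad <- radialCorrelation(cv)
    radialCorrEval(rad, gam * lags) *
      exp(-params@dPhi * lags) * cos(params@omega * lags)
  } else if (method == "analytic") {
    gam <- radialRelaxationRate(params, "linearized")
    cv2 <- computeCV(params)$cv^2
    (1 + cv2 * exp(-gam * lags)) / (1 + cv2) *
      exp(-params@dPhi * lags) * cos(params@omega * lags)
  } else {
    dtS <- 1
    maxLag <- max(lags)
    acfs <- vapply(seq_len(simReplicates), function(i) {
      tr <- simulateCell(params, duration = simLength, dt = 0.01,
                         sampleInterval = dtS, seed = deriveSeed(seed, paste0("macf", i)))
      traceACF(tr, maxLag = min(maxLag, (length(tr@x) - 1) / 3),
               detrend = FALSE)$acf
    }, numeric(floor(min(maxLag, (simLength - 1) / 3) / dtS) + 1))
    m <- rowMeans(acfs)
    grid <- (seq_along(m) - 1) * dtS
    stats::approx(grid, m, xout = pmin(lags, max(grid)), rule = 2)$y
  }
}

#' Normalized autocorrelation of the dimensionless radial diffusion
#'
#' Spectral solution of the signed-radius process
#' \eqn{dv = -v^2(v - \mathrm{sgn}\, v)\,ds + \sqrt{2}\,CV\,dW}: the
#' generator is discretized on a grid with detailed-balance nearest-
#' neighbour rates, symmetrized by the stationary density, and
#' eigendecomposed. The correlation is
#' \eqn{\hat{C}(s) = \sum_k w_k e^{\mu_k s}} with weights from the overlap
#' of \eqn{v} with the eigenmodes, normalized so \eqn{\hat{C}(0) = 1}.
#' Time is in units of \eqn{1/\gamma} with \eqn{\gamma = \lambda\alpha^2}.
#'
#' @param cv amplitude coefficient of variation (>= 0).
#' @param nGrid number of grid points.
#' @return A list with \code{mu} (decay rates, <= 0) and \code{w}
#'   (weights summing to 1); evaluate with [radialCorrEval()]. For
#'   \code{cv = 0} the process is frozen at the cycle and
#'   \eqn{\hat{C} \equiv 1}.
#' @keywords internal
radialCorrelation <- function(cv, nGrid = 201L) {
  if (cv < 1e-6) return(list(mu = 0, w = 1))
  vmax <- 1 + max(4 * sqrt(cv), 2.5 * cv)
  v <- seq(-vmax, vmax, length.out = nGrid)
  h <- v[2] - v[1]
  U <- v^4 / 4 - abs(v)^3 / 3
  D <- cv^2
  # detailed-balance hop rates; symmetrized generator is tridiagonal with
  # constant off-diagonal D/h^2
  up <- (D / h^2) * exp(-diff(U) / (2 * D))     # i -> i+1
  dn <- (D / h^2) * exp(diff(U) / (2 * D))      # i+1 -> i
  diagA <- -(c(up, 0) + c(0, dn))
  B <- matrix(0, nGrid, nGrid)
  diag(B) <- diagA
  off <- D / h^2
  B[cbind(1:(nGrid - 1), 2:nGrid)] <- off
  B[cbind(2:nGrid, 1:(nGrid - 1))] <- off
  ee <- eigen(B, symmetric = TRUE)
  p <- exp(-U / D); p <- p / sum(p)
  g <- sqrt(p) * v
  ov <- as.vector(crossprod(ee$vectors, g))
  w <- ov^2
  keep <- w > 1e-6 * sum(w)
  list(mu = pmin(ee$values[keep], 0), w = w[keep] / sum(w))
}

#' @rdname radialCorrelation
#' @param rad a list from [radialCorrelation()].
#' @param s dimensionless time lags.
#' @keywords internal
radialCorrEval <- function(rad, s) {
  as.vector(exp(outer(s, rad$mu)) %*% rad$w)
}
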