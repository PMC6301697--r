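#' Simulate the coupled SCN network
#'
#' Stochastic Heun integration (second-order predictor-corrector drift with
#' explicit Gaussian increments) of the dual-coupled lattice: each cell obeys
#' \deqn{dx_i/dt = -\lambda x_i r_i (r_i-\alpha) - \omega_i y_i
#'   + \sum_{j \in N_i} K (x_j - x_i)
#'   + I_{avp}\sin(2\pi t/24) + I_{vip}\sin(2\pi (t+\phi)/24) + \xi_{x,i},}
#' \deqn{dy_i/dt = -\lambda y_i r_i (r_i-\alpha) + \omega_i x_i + \xi_{y,i},}
#' with the effective coupling \eqn{K = a_{avp} K_{avp} + a_{vip} K_{vip}}
#' (bridge edges scaled by the bridge factor). Forcing and coupling act on
#' the x-equation only. External VIP forcing is multiplied by zero when the
#' scenario lacks the VIP receptor; the antagonist flag has already zeroed
#' \eqn{I_{avp}} (and AVP coupling) at scenario construction. Initial
#' states are on-cycle with phases drawn uniformly (or with the scenario's
#' initial phase spread); the burn-in transient is discarded.
#'
#' @param scenario a [NetworkScenario-class].
#' @param seed dynamics seed; defaults to the scenario's root seed (the
#'   dynamics stream is derived from it).
#' @return A [NetworkRun-class].
#' @examples
#' sc <- scenarioPreset("neonate-wt", seed = 1, cellsPerLobe = 20,
#'                      duration = 72)
#' run <- simulateNetwork(sc)
#' dim(run@traces)
#' @export
simulateNetwork <- function(scenario, seed = scenario@seed) {
  stopifnot(is(scenario, "NetworkScenario"))
  p <- scenario@params
  n <- nrow(scenario@geometry@cells)
  dt <- scenario@dt
  W <- couplingMatrix(scenario)
  deg <- Matrix::rowSums(W)
  guard <- max(p@damping * p@alpha, max(scenario@omega), max(deg, 0))
  if (dt * guard >= 0.1)
    stop("unstable step size: require dt * max(damping*alpha, omega, coupling degree) < 0.1")
  thin <- round(scenario@sampleInterval / dt)
  if (abs(thin * dt - scenario@sampleInterval) > 1e-9)
    stop("sampleInterval must be a multiple of dt")

  iAvp <- scenario@iAvp
  iVip <- if (scenario@vipReceptor) scenario@iVip else 0
  phi <- scenario@phi
  om <- scenario@omega
  lam <- p@damping; al <- p@alpha
  sigR <- sqrt(2 * p@dR * dt)
  sigP <- sqrt(2 * p@dPhi * dt)

  nSamp <- floor(scenario@duration / scenario@sampleInterval)
  burnSteps <- round(scenario@burnin / dt)
  totSteps <- burnSteps + (nSamp - 1L) * thin
  out <- matrix(NA_real_, nSamp, n)
  times <- (seq_len(nSamp) - 1) * scenario@sampleInterval

  hasCoupling <- length(W@x) > 0 && any(W@x != 0)
  drift <- function(x, y, t) {
    r <- sqrt(x * x + y * y)
    common <- lam * r * (r - al)
    force <- iAvp * sin(2 * pi * t / 24) +
      iVip * sin(2 * pi * (t + phi) / 24)
    cpl <- if (hasCoupling) as.vector(W %*% x) - deg * x else 0
    list(x = -common * x - om * y + cpl + force,
         y = -common * y + om * x)
  }
  withSeed(deriveSeed(seed, "dynamics"), {
    theta0 <- if (is.na(scenario@initPhaseSd)) runif(n, 0, 2 * pi)
              else rnorm(n, 0, scenario@initPhaseSd)
    x <- al * cos(theta0)
    y <- al * sin(theta0)
    k <- 0L
    for (s in 0:totSteps) {
      if (s >= burnSteps && (s - burnSteps) %% thin == 0L) {
        k <- k + 1L
        if (k <= nSamp) { out[k, ] <- x }
      }
      if (s == totSteps) break
      t <- s * dt
      # Heun (predictor-corrector) drift + explicit noise increment
      f1 <- drift(x, y, t)
      f2 <- drift(x + f1$x * dt, y + f1$y * dt, t + dt)
      r <- sqrt(x * x + y * y)
      rs <- pmax(r, 1e-8)
      xi1 <- rnorm(n); xi2 <- rnorm(n)
      xn <- x + (f1$x + f2$x) * dt / 2 + sigR * xi1 * x / rs - sigP * xi2 * y
      yn <- y + (f1$y + f2$y) * dt / 2 + sigR * xi1 * y / rs + sigP * xi2 * x
      x <- xn; y <- yn
      if (s %% 200L == 0L && !isTRUE(all(abs(x) <= 1e3 * al)))
        stop(sprintf("network integration diverged at step %d (t = %.2f h)",
                     s, t))
    }
  })
  new("NetworkRun", scenario = scenario, times = times, traces = out,
      seed = as.integer(seed))
}

#' Synchronization index sweep over scenario parameters
#'
#' Re-runs a scenario over a grid of parameter values (full factorial over
#' the supplied value vectors) with \code{replicates} seeded repeats each,
#' and records the synchronization index computed over the final 24 h of
#' every run.
#'
#' @param scenario the base [NetworkScenario-class].
#' @param grid named list of parameter values, e.g.
#'   \code{list(aVip = c(0, 0.5, 1))}; names must be numeric scenario
#'   slots.
#' @param replicates number of seeded replicates per grid point.
#' @param seed root seed for the replicate streams.
#' @return data.frame: one row per grid point with the swept parameter
#'   values, \code{syncMean}, and \code{syncSd} across replicates.
#' @examples
#' sc <- scenarioPreset("neonate-wt", seed = 1, cellsPerLobe = 16,
#'                      duration = 72)
#' sweepSynchronization(sc, list(aVip = c(0, 1)), replicates = 2)
#' @export
sweepSynchronization <- function(scenario, grid, replicates = 3, seed = 1L) {
  stopifnot(is(scenario, "NetworkScenario"))
  if (!is.list(grid) || !length(grid) || is.null(names(grid)) ||
      any(names(grid) == ""))
    stop("grid must be a non-empty named list of parameter values")
  bad <- setdiff(names(grid), slotNames(scenario))
  if (length(bad))
    stop("unknown scenario parameters: ", paste(bad, collapse = ", "))
  if (replicates < 1) stop("replicates must be >= 1")

  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- points
  res$syncMean <- NA_real_
  res$syncSd <- NA_real_
  for (i in seq_len(nrow(points))) {
    sc <- scenario
    for (nm in names(grid)) slot(sc, nm) <- as.numeric(points[i, nm])
    if (sc@antagonist) sc@iAvp <- 0
    validObject(sc)
    rs <- vapply(seq_len(replicates), function(rep) {
      run <- simulateNetwork(sc, seed = deriveSeed(seed, sprintf("sweep-%d-%d", i, rep)))
      mov <- preprocessMovie(runToMovie(run))
      syncIndex(mov)$mean
    }, numeric(1))
    res$syncMean[i] <- mean(rs)
    res$syncSd[i] <- if (replicates > 1) sd(rs) else 0
  }
  res
}

#' Convert a network run to a movie of raw cell traces
#'
#' One pixel per cell, located at the cell's lattice coordinates; no
#' imaging model is applied (use [renderMovie()] for PER2::LUC-like
#' rendering).
#'
#' @param run a [NetworkRun-class].
#' @return A [BiolumMovie-class].
#' @export
runToMovie <- function(run) {
  stopifnot(is(run, "NetworkRun"))
  cells <- run@scenario@geometry@cells
  BiolumMovie(samples = run@traces,
              coords = data.frame(x = cells$x, y = cells$y),
              times = run@times)
}
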