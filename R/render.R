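#' Construct an imaging model
#'
#' Defaults emulate a cooled-EMCCD PER2::LUC slice recording with 59-min
#' exposures: a bright baseline (5e4 counts) with photon-counting
#' ("poisson-like", variance = mean) noise, a slow culture decay with a
#' 120 h time constant, a relative modulation of 0.5 per signal unit, and
#' 4 pixels per cell (a single-cell ROI of ~100 um^2 over ~2 um pixels).
#'
#' @param baseline baseline intensity, counts.
#' @param decayTau culture decay time constant, h.
#' @param gain relative modulation per signal unit.
#' @param noiseModel "poisson-like" (variance proportional to the mean) or
#'   "gaussian-scaled" (constant variance \code{noiseScale^2}).
#' @param noiseScale s.d. for "gaussian-scaled" noise; defaults to
#'   \code{sqrt(baseline)}.
#' @param pixelsPerCell 1 or 4 pixels rendered per cell.
#' @return An [ImagingModel-class].
#' @export
ImagingModel <- function(baseline = 5e4, decayTau = 120, gain = 0.5,
                         noiseModel = c("poisson-like", "gaussian-scaled"),
                         noiseScale = sqrt(max(baseline, 0)),
                         pixelsPerCell = 4L) {
  new("ImagingModel", baseline = baseline, decayTau = decayTau, gain = gain,
      noiseModel = match.arg(noiseModel), noiseScale = noiseScale,
      pixelsPerCell = as.integer(pixelsPerCell))
}

setMethod("show", "ImagingModel", function(object) {
  cat(sprintf(
    "ImagingModel: baseline %.3g counts, decay tau %.3g h, gain %.3g, %s noise, %d px/cell\n",
    object@baseline, object@decayTau, object@gain, object@noiseModel,
    object@pixelsPerCell))
})

# deterministic noise-free pixel expectation for one trace
renderExpectation <- function(x, times, imaging) {
  imaging@baseline * exp(-times / imaging@decayTau) *
    pmax(1 + imaging@gain * x, 0)
}

addImagingNoise <- function(mu, imaging) {
  noise <- switch(imaging@noiseModel,
    "poisson-like" = rnorm(length(mu), sd = sqrt(pmax(mu, 0))),
    "gaussian-scaled" = rnorm(length(mu), sd = imaging@noiseScale))
  pmax(mu + noise, 0) # bioluminescence counts are non-negative
}

#' Render a network run as a PER2::LUC-like movie
#'
#' Each cell maps to \code{pixelsPerCell} adjacent pixels (a 2x2 block at
#' twice the lattice coordinates) sharing the cell's trace; every pixel
#' gets the deterministic expectation
#' \code{baseline * exp(-t/decayTau) * (1 + gain * x_i(t))_+} plus
#' independent measurement noise, clipped at zero counts.
#'
#' @param run a [NetworkRun-class].
#' @param imaging an [ImagingModel-class].
#' @param seed integer seed for the measurement noise.
#' @return A [BiolumMovie-class] whose pixel coordinates reflect the
#'   two-lobed geometry.
#' @examples
#' sc <- scenarioPreset("neonate-wt", seed = 1, cellsPerLobe = 16,
#'                      duration = 72)
#' mov <- renderMovie(simulateNetwork(sc), seed = 1)
#' @export
renderMovie <- function(run, imaging = ImagingModel(), seed = 1L) {
  stopifnot(is(run, "NetworkRun"), is(imaging, "ImagingModel"))
  cells <- run@scenario@geometry@cells
  n <- nrow(cells)
  ppc <- imaging@pixelsPerCell
  offs <- if (ppc == 4L) cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)) else cbind(0, 0)
  cellOf <- rep(seq_len(n), each = ppc)
  px <- 2 * cells$x[cellOf] + offs[rep(seq_len(ppc), times = n), 1]
  py <- 2 * cells$y[cellOf] + offs[rep(seq_len(ppc), times = n), 2]
  # gain expresses relative modulation per unit of the cell's own
  # limit-cycle amplitude, so rendering is invariant to the arbitrary
  # signal units of the oscillator model
  al <- run@scenario@params@alpha
  mu <- vapply(cellOf, function(i)
    renderExpectation(run@traces[, i] / al, run@times, imaging),
    numeric(length(run@times)))
  samples <- withSeed(deriveSeed(seed, "imaging"), {
    matrix(addImagingNoise(as.vector(mu), imaging), nrow = nrow(mu))
  })
  BiolumMovie(samples, coords = data.frame(x = px, y = py),
              times = run@times)
}

#' Render dispersed single-cell traces
#'
#' Simulates independent (uncoupled) cells, one per parameter set, and
#' renders each through the imaging model, emulating ROI-averaged
#' dispersed-culture recordings.
#'
#' @param paramsList list of [OscillatorParams-class] objects (one cell
#'   each).
#' @param duration recording length (h); \code{duration = 0} returns
#'   empty traces.
#' @param imaging an [ImagingModel-class].
#' @param seed root seed; per-cell child seeds are derived from it.
#' @param dt,sampleInterval integration and sampling grid (h).
#' @return A list of [CellTrace-class] objects with rendered counts in
#'   \code{x}.
#' @export
renderDispersed <- function(paramsList, duration = 240,
                            imaging = ImagingModel(), seed = 1L,
                            dt = 0.01, sampleInterval = 1) {
  stopifnot(length(paramsList) >= 1,
            all(vapply(paramsList, is, TRUE, "OscillatorParams")))
  if (duration <= 0)
    return(lapply(paramsList, function(p)
      new("CellTrace", times = numeric(0), x = numeric(0), y = numeric(0))))
  lapply(seq_along(paramsList), function(i) {
    p <- paramsList[[i]]
    tr <- simulateCell(p, duration = duration, dt = dt,
                       sampleInterval = sampleInterval,
                       seed = deriveSeed(seed, sprintf("cell-%d", i)))
    mu <- renderExpectation(tr@x / p@alpha, tr@times, imaging)
    counts <- withSeed(deriveSeed(seed, sprintf("noise-%d", i)),
                       addImagingNoise(mu, imaging))
    new("CellTrace", times = tr@times, x = counts, y = numeric(0))
  })
}
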