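#' @import methods
#' @importFrom stats rnorm runif sd var cor qchisq pf pt aov anova lm coef
#'   fft mvfft median quantile acf optim setNames pchisq
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Matrix sparseMatrix rowSums
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Five-parameter stochastic amplitude-phase oscillator
#'
#' The single-cell model is a noisy limit-cycle oscillator in Cartesian
#' coordinates \eqn{(x, y)} with radius \eqn{r = \sqrt{x^2+y^2}}:
#' \deqn{dx/dt = -\lambda x r (r-\alpha) - \omega y + \xi_x,}
#' \deqn{dy/dt = -\lambda y r (r-\alpha) + \omega x + \xi_y,}
#' a limit cycle of amplitude \eqn{\alpha} and angular frequency
#' \eqn{\omega} to which perturbations relax at a rate set by the damping
#' \eqn{\lambda}. The Gaussian noise pair is parameterized by a radial
#' intensity \eqn{D_r} (signal units squared per hour) and a phase intensity
#' \eqn{D_\phi} (rad squared per hour); see [simulateCell()] for the
#' radial/tangential noise convention.
#'
#' @slot alpha limit-cycle amplitude, signal units (> 0).
#' @slot omega angular frequency, rad/h (> 0); intrinsic period is
#'   \eqn{2\pi/\omega}.
#' @slot damping relaxation rate \eqn{\lambda}, 1/h (> 0).
#' @slot dR radial noise intensity \eqn{D_r} (>= 0).
#' @slot dPhi phase noise intensity \eqn{D_\phi} (>= 0).
#' @seealso [OscillatorParams()], [computeCV()], [simulateCell()]
#' @export
setClass("OscillatorParams",
  representation(
    alpha = "numeric", omega = "numeric", damping = "numeric",
    dR = "numeric", dPhi = "numeric"
  )
)

setValidity("OscillatorParams", function(object) {
  msg <- character()
  for (s in c("alpha", "omega", "damping", "dR", "dPhi")) {
    if (!isScalarNumber(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@omega <= 0) msg <- c(msg, "omega must be > 0 (finite period)")
  if (object@damping <= 0) msg <- c(msg, "damping must be > 0")
  if (object@dR < 0) msg <- c(msg, "dR must be >= 0")
  if (object@dPhi < 0) msg <- c(msg, "dPhi must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Uniformly sampled single-cell trace
#'
#' Container for one observed or simulated bioluminescence time course: a
#' time grid in hours with uniform spacing, the observed coordinate
#' \code{x}, and optionally the conjugate coordinate \code{y} (available for
#' simulated traces, empty for measured ones).
#'
#' @slot times sample times in hours (uniform spacing).
#' @slot x observed coordinate sequence, signal units.
#' @slot y conjugate coordinate sequence, or \code{numeric(0)}.
#' @export
setClass("CellTrace",
  representation(times = "numeric", x = "numeric", y = "numeric")
)

setValidity("CellTrace", function(object) {
  msg <- character()
  if (length(object@x) != length(object@times))
    msg <- c(msg, "x and times must have equal length")
  if (length(object@y) && length(object@y) != length(object@times))
    msg <- c(msg, "y must be empty or match times")
  if (any(!is.finite(object@times)) || any(!is.finite(object@x)))
    msg <- c(msg, "times and x must be finite")
  if (length(object@times) > 2) {
    dt <- diff(object@times)
    if (max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1))
      msg <- c(msg, "sampling must be uniform")
  }
  if (length(msg)) msg else TRUE
})

#' Two-lobed SCN lattice geometry
#'
#' Cells live on two disc-shaped 4-neighbour lattices (left and right lobe);
#' a small number of symmetric bridge edges connects the lobes across the
#' midline. A top-medial subset of each lobe is labelled dorsomedial, the
#' region whose cells are conventionally assigned shorter intrinsic periods.
#'
#' @slot cells data.frame with columns \code{id}, \code{lobe}
#'   ("left"/"right"), \code{region} ("dorsomedial"/"other"), \code{x},
#'   \code{y} (lattice coordinates).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{bridge} (logical); each undirected edge is stored once with
#'   \code{from < to}.
#' @seealso [buildGeometry()]
#' @export
setClass("NetworkGeometry",
  representation(cells = "data.frame", edges = "data.frame")
)

setValidity("NetworkGeometry", function(object) {
  msg <- character()
  cells <- object@cells
  edges <- object@edges
  need <- c("id", "lobe", "region", "x", "y")
  if (!all(need %in% names(cells))) return("cells must have id/lobe/region/x/y")
  if (!all(c("from", "to", "bridge") %in% names(edges)))
    return("edges must have from/to/bridge")
  if (anyDuplicated(cells$id)) msg <- c(msg, "cell ids must be unique")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) msg <- c(msg, "self-edges not allowed")
    if (any(!(edges$from %in% cells$id)) || any(!(edges$to %in% cells$id)))
      msg <- c(msg, "edges must reference existing cells")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    lb <- setNames(as.character(cells$lobe), cells$id)
    br <- lb[as.character(edges$from)] != lb[as.character(edges$to)]
    if (!all(br == edges$bridge))
      msg <- c(msg, "bridge flag must mark exactly the inter-lobe edges")
  }
  if (length(msg)) msg else TRUE
})

#' Complete specification of one in-silico slice experiment
#'
#' Bundles the lattice, the base single-cell parameters, per-cell intrinsic
#' angular frequencies, the dual-coupling attenuation factors, coupling
#' strengths, co-culture forcing intensities with their phase delay, and
#' the integration grid. `antagonist = TRUE` encodes an AVP-receptor
#' antagonist cocktail and forces \code{iAvp = 0} (and, by default,
#' \code{aAvp = 0}: the blockade also silences AVP coupling within the
#' slice). `vipReceptor = FALSE` encodes Vipr2 loss: external VIP forcing
#' is ineffective regardless of \code{iVip}.
#'
#' @slot name scenario label (preset name or "custom").
#' @slot geometry a [NetworkGeometry-class].
#' @slot params base [OscillatorParams-class] shared by all cells.
#' @slot omega per-cell angular frequencies (rad/h), one per cell.
#' @slot aVip,aAvp attenuation factors in [0, 1].
#' @slot kVip,kAvp default coupling strengths of the two channels; the
#'   effective per-edge coupling is \eqn{K = a_{avp} K_{avp} + a_{vip} K_{vip}}.
#' @slot bridgeFactor multiplier applied to K on inter-lobe bridge edges.
#' @slot iVip,iAvp forcing intensities (signal units/h, >= 0).
#' @slot phi forcing phase delay of the VIP input in hours, [0, 24).
#' @slot antagonist logical, AVP receptor antagonist applied.
#' @slot vipReceptor logical, VIP receptor present.
#' @slot duration,burnin,dt,sampleInterval integration grid in hours; the
#'   burn-in transient is discarded before sampling.
#' @slot initPhaseSd s.d. (rad) of the initial phase spread; \code{NA}
#'   draws initial phases uniformly on the circle.
#' @slot seed integer root seed recorded with the scenario.
#' @seealso [scenarioPreset()], [simulateNetwork()]
#' @export
setClass("NetworkScenario",
  representation(
    name = "character",
    geometry = "NetworkGeometry",
    params = "OscillatorParams",
    omega = "numeric",
    aVip = "numeric", aAvp = "numeric",
    kVip = "numeric", kAvp = "numeric",
    bridgeFactor = "numeric",
    iVip = "numeric", iAvp = "numeric",
    phi = "numeric",
    antagonist = "logical",
    vipReceptor = "logical",
    duration = "numeric", burnin = "numeric",
    dt = "numeric", sampleInterval = "numeric",
    initPhaseSd = "numeric",
    seed = "integer"
  )
)

setValidity("NetworkScenario", function(object) {
  msg <- character()
  n <- nrow(object@geometry@cells)
  if (length(object@omega) != n)
    msg <- c(msg, "omega must have one entry per cell")
  if (any(object@omega <= 0)) msg <- c(msg, "omega must be positive")
  if (object@aVip < 0 || object@aVip > 1) msg <- c(msg, "aVip must be in [0, 1]")
  if (object@aAvp < 0 || object@aAvp > 1) msg <- c(msg, "aAvp must be in [0, 1]")
  if (object@iVip < 0 || object@iAvp < 0)
    msg <- c(msg, "forcing intensities must be >= 0")
  if (object@phi < 0 || object@phi >= 24) msg <- c(msg, "phi must be in [0, 24)")
  if (object@antagonist && object@iAvp != 0)
    msg <- c(msg, "antagonist scenarios must have iAvp = 0")
  if (object@duration < object@sampleInterval)
    msg <- c(msg, "duration must cover at least one sample interval")
  if (object@dt <= 0 || object@sampleInterval <= 0 || object@burnin < 0)
    msg <- c(msg, "dt and sampleInterval must be > 0, burnin >= 0")
  if (length(msg)) msg else TRUE
})

#' Sampled network trajectory
#'
#' @slot scenario the [NetworkScenario-class] that produced the run.
#' @slot times sample grid in hours (post burn-in, starting at 0).
#' @slot traces T x N matrix of the observed coordinate \eqn{x_i};
#'   one column per cell.
#' @slot seed the dynamics seed actually used.
#' @export
setClass("NetworkRun",
  representation(
    scenario = "NetworkScenario", times = "numeric",
    traces = "matrix", seed = "integer"
  )
)

setValidity("NetworkRun", function(object) {
  msg <- character()
  if (ncol(object@traces) != nrow(object@scenario@geometry@cells))
    msg <- c(msg, "column count must equal cell count")
  if (nrow(object@traces) != length(object@times))
    msg <- c(msg, "row count must equal number of sample times")
  if (length(msg)) msg else TRUE
})

#' Pixel-level bioluminescence movie
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' single assay \code{"luminescence"} holds pixels as rows and time points as
#' columns (the analysis-facing accessor [movieMatrix()] returns the
#' transposed T x N sample matrix, one column per pixel). Pixel coordinates
#' live in \code{rowData} (columns \code{x}, \code{y}), sample times in
#' hours in \code{colData$time}.
#'
#' @seealso [BiolumMovie()], [movieMatrix()], [preprocessMovie()],
#'   [computeEOF()]
#' @export
setClass("BiolumMovie", contains = "SummarizedExperiment")

setValidity("BiolumMovie", function(object) {
  msg <- character()
  if (!"luminescence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'luminescence' is required")
  if (nrow(object) < 2) msg <- c(msg, "need at least 2 pixels")
  if (ncol(object) < 48) msg <- c(msg, "need at least 48 time points")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("x", "y") %in% colnames(rd)))
    msg <- c(msg, "rowData must provide pixel coordinates x, y")
  if (!"time" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must provide sample times")
  tm <- object$time
  if (length(tm) > 2 && max(abs(diff(tm) - diff(tm)[1])) > 1e-8)
    msg <- c(msg, "sampling must be uniform")
  if (anyNA(SummarizedExperiment::assay(object, "luminescence")))
    msg <- c(msg, "missing values are not allowed")
  if (length(msg)) msg else TRUE
})

#' Empirical orthogonal function decomposition of a movie
#'
#' Eigen-decomposition of the pixel-by-pixel covariance matrix
#' \eqn{R = A^T A} of the (column-centered) T x N sample matrix A. The
#' eigenvectors \eqn{e_i} are spatial loadings, the projections
#' \eqn{c_i(t)} are the temporal empirical modes, and the normalized
#' eigenvalues \eqn{100 \Omega_i / \sum_j \Omega_j} give each mode's share
#' of the total variance in percent.
#'
#' @slot eigenvalues eigenvalues \eqn{\Omega_i}, descending, >= 0.
#' @slot normalized normalized eigenvalues in percent (sum to 100).
#' @slot vectors N x k matrix of orthonormal spatial loadings.
#' @slot modes T x k matrix of temporal modes \eqn{c_i(t)}.
#' @slot totalVariance \eqn{\sum_i \Omega_i}, the squared Frobenius norm of
#'   the analyzed (centered) matrix.
#' @slot centered logical; whether columns were mean-removed.
#' @seealso [computeEOF()], [classifyPixels()]
#' @export
setClass("EOFResult",
  representation(
    eigenvalues = "numeric", normalized = "numeric",
    vectors = "matrix", modes = "matrix",
    totalVariance = "numeric", centered = "logical"
  )
)

setValidity("EOFResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(ev < -1e-8 * max(ev, 0))) msg <- c(msg, "eigenvalues must be >= 0")
  if (is.unsorted(rev(ev))) msg <- c(msg, "eigenvalues must be descending")
  if (length(ev) && abs(sum(object@normalized) - 100) > 1e-6)
    msg <- c(msg, "normalized eigenvalues must sum to 100%")
  if (ncol(object@vectors) != length(ev) || ncol(object@modes) != length(ev))
    msg <- c(msg, "vectors/modes must have one column per eigenvalue")
  if (length(msg)) msg else TRUE
})

#' Pixel classification derived from the leading EOF modes
#'
#' @slot labels integer per-pixel label (1..nComponents, NA = unclassified).
#' @slot nComponents number of modes used.
#' @slot threshold loading-fraction threshold used (scaled by 1/sqrt(N)).
#' @slot periods named list, per-class vectors of periodogram-significant
#'   pixel periods (h).
#' @slot acrophases named list, per-class vectors of acrophases (h in
#'   [0, 24)).
#' @export
setClass("PixelClassification",
  representation(
    labels = "integer", nComponents = "integer", threshold = "numeric",
    periods = "list", acrophases = "list"
  )
)

#' Per-slice rhythm summary
#'
#' The slice-level metrics used to compare genotype/age groups: mean and
#' s.d. of the periodogram-significant pixel periods, the summed normalized
#' first and second EOF eigenvalues, and the mean and s.d. of the
#' synchronization index over the final 24 hourly time points.
#'
#' @slot periodMean,periodSd period statistics (h); NA when no pixel
#'   reaches periodogram significance.
#' @slot nRhythmic number of periodogram-significant pixels.
#' @slot eig12Sum normalized first plus second eigenvalue, percent.
#' @slot syncMean,syncSd synchronization index statistics over 24 points.
#' @seealso [summarizeSlice()], [groupCompare()]
#' @export
setClass("SliceSummary",
  representation(
    periodMean = "numeric", periodSd = "numeric", nRhythmic = "integer",
    eig12Sum = "numeric", syncMean = "numeric", syncSd = "numeric"
  )
)

setValidity("SliceSummary", function(object) {
  msg <- character()
  if (!is.na(object@eig12Sum) &&
      (object@eig12Sum < 0 || object@eig12Sum > 100 + 1e-9))
    msg <- c(msg, "eig12Sum must be in [0, 100]")
  if (!is.na(object@syncMean) &&
      (object@syncMean < 0 || object@syncMean > 1 + 1e-9))
    msg <- c(msg, "syncMean must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Imaging model turning simulated signals into PER2::LUC-like counts
#'
#' Pixel values are
#' \code{baseline * exp(-t/decayTau) * max(0, 1 + gain * x(t))} plus
#' measurement noise whose variance is proportional to the expected count
#' ("poisson-like", photon counting) or constant ("gaussian-scaled",
#' variance \code{noiseScale^2}). Each simulated cell is rendered as
#' \code{pixelsPerCell} adjacent pixels sharing the cell's trace with
#' independent noise; negative counts are clipped to zero.
#'
#' @slot baseline baseline intensity, counts (>= 0).
#' @slot decayTau slow culture decay time constant, h (> 0).
#' @slot gain relative modulation per signal unit (> 0).
#' @slot noiseModel "poisson-like" or "gaussian-scaled".
#' @slot noiseScale s.d. of the gaussian-scaled noise, counts.
#' @slot pixelsPerCell pixels rendered per cell (1 or 4).
#' @seealso [renderMovie()], [renderDispersed()]
#' @export
setClass("ImagingModel",
  representation(
    baseline = "numeric", decayTau = "numeric", gain = "numeric",
    noiseModel = "character", noiseScale = "numeric",
    pixelsPerCell = "integer"
  )
)

setValidity("ImagingModel", function(object) {
  msg <- character()
  if (object@baseline < 0) msg <- c(msg, "baseline must be >= 0")
  if (object@decayTau <= 0) msg <- c(msg, "decayTau must be > 0")
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (!object@noiseModel %in% c("poisson-like", "gaussian-scaled"))
    msg <- c(msg, "noiseModel must be 'poisson-like' or 'gaussian-scaled'")
  if (!object@pixelsPerCell %in% c(1L, 4L))
    msg <- c(msg, "pixelsPerCell must be 1 or 4")
  if (length(msg)) msg else TRUE
})
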