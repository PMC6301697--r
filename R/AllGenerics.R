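#' @rdname OscillatorParams-class
#' @param object an object.
#' @export
setGeneric("alpha", function(object) standardGeneric("alpha"))

#' @rdname OscillatorParams-class
#' @export
setGeneric("omega", function(object) standardGeneric("omega"))

#' @rdname OscillatorParams-class
#' @export
setGeneric("damping", function(object) standardGeneric("damping"))

#' @rdname OscillatorParams-class
#' @export
setGeneric("noiseRadial", function(object) standardGeneric("noiseRadial"))

#' @rdname OscillatorParams-class
#' @export
setGeneric("noisePhase", function(object) standardGeneric("noisePhase"))

#' @rdname OscillatorParams-class
#' @export
setGeneric("intrinsicPeriod", function(object) standardGeneric("intrinsicPeriod"))

#' Coefficient of variation of the amplitude fluctuations
#'
#' @param params an [OscillatorParams-class].
#' @param ... further arguments passed to methods.
#' @return A list with elements \code{cv} and \code{label}
#'   ("self-sustained" for CV < 1, "damped" otherwise).
#' @export
setGeneric("computeCV", function(params, ...) standardGeneric("computeCV"))

#' @rdname EOFResult-class
#' @param object an object.
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname EOFResult-class
#' @export
setGeneric("normalizedEigenvalues",
  function(object) standardGeneric("normalizedEigenvalues"))

#' @rdname EOFResult-class
#' @export
setGeneric("eofVectors", function(object) standardGeneric("eofVectors"))

#' @rdname EOFResult-class
#' @export
setGeneric("eofModes", function(object) standardGeneric("eofModes"))

#' Empirical orthogonal function decomposition
#'
#' @param x a T x N numeric matrix (rows = time points, columns = pixels)
#'   or a [BiolumMovie-class].
#' @param center logical; remove each column's temporal mean before forming
#'   the covariance (default TRUE, so \eqn{R = A^T A} is a true covariance
#'   matrix). Set FALSE to decompose the raw second-moment matrix.
#' @param ... further arguments passed to methods.
#' @return An [EOFResult-class].
#' @export
setGeneric("computeEOF", function(x, center = TRUE, ...) standardGeneric("computeEOF"))

#' @rdname BiolumMovie
#' @param object an object.
#' @export
setGeneric("movieMatrix", function(object) standardGeneric("movieMatrix"))

#' @rdname BiolumMovie
#' @export
setGeneric("pixelCoords", function(object) standardGeneric("pixelCoords"))

#' @rdname BiolumMovie
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname BiolumMovie
#' @export
setGeneric("samplingInterval", function(object) standardGeneric("samplingInterval"))
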