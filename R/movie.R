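#' Construct a bioluminescence movie
#'
#' @param samples T x N numeric matrix: one row per time point, one column
#'   per pixel (the sample-matrix convention; internally pixels are stored
#'   as SummarizedExperiment rows).
#' @param coords data.frame or matrix with pixel coordinates (columns
#'   \code{x}, \code{y}), one row per pixel.
#' @param times sample times in hours; alternatively give \code{dt}.
#' @param dt sampling interval in hours (default 1) used when \code{times}
#'   is missing.
#' @return A [BiolumMovie-class].
#' @examples
#' t <- 0:143
#' A <- outer(cos(2 * pi * t / 24), rep(1, 4))
#' mov <- BiolumMovie(A, coords = data.frame(x = 1:4, y = 1))
#' dim(movieMatrix(mov))
#' @rdname BiolumMovie
#' @export
BiolumMovie <- function(samples, coords, times = NULL, dt = 1) {
  samples <- as.matrix(samples)
  if (is.null(times)) times <- (seq_len(nrow(samples)) - 1) * dt
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords))) {
    stopifnot(ncol(coords) >= 2)
    names(coords)[1:2] <- c("x", "y")
  }
  stopifnot(nrow(coords) == ncol(samples), length(times) == nrow(samples))
  assay <- t(samples)
  rownames(assay) <- sprintf("px%d", seq_len(nrow(assay)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(luminescence = assay),
    rowData = S4Vectors::DataFrame(x = coords$x, y = coords$y),
    colData = S4Vectors::DataFrame(time = as.numeric(times))
  )
  new("BiolumMovie", se)
}

#' @rdname BiolumMovie
#' @export
setMethod("movieMatrix", "BiolumMovie", function(object) {
  t(SummarizedExperiment::assay(object, "luminescence"))
})

#' @rdname BiolumMovie
#' @export
setMethod("pixelCoords", "BiolumMovie", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  data.frame(x = rd$x, y = rd$y)
})

#' @rdname BiolumMovie
#' @export
setMethod("sampleTimes", "BiolumMovie", function(object) object$time)

#' @rdname BiolumMovie
#' @export
setMethod("samplingInterval", "BiolumMovie", function(object) {
  tm <- object$time
  if (length(tm) > 1) diff(tm)[1] else NA_real_
})

setMethod("show", "BiolumMovie", function(object) {
  tm <- object$time
  cat(sprintf("BiolumMovie: %d pixels x %d time points (%.1f h at dt = %.2g h)\n",
              nrow(object), ncol(object), diff(range(tm)),
              samplingInterval(object)))
  cat(sprintf("  intensity range: [%.3g, %.3g]\n",
              min(SummarizedExperiment::assay(object)),
              max(SummarizedExperiment::assay(object))))
})
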