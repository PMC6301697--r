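#' Four-panel EOF summary figure
#'
#' Base-graphics figure mirroring the standard slice report: normalized
#' eigenvalue spectrum, spatial map of the classified pixels (component 1
#' red, component 2 green), per-class period histograms, and the
#' class-mean traces.
#'
#' @param movie a preprocessed [BiolumMovie-class].
#' @param eof the matching [EOFResult-class]; computed when NULL.
#' @param classification the matching [PixelClassification-class];
#'   computed when NULL.
#' @return Invisibly, the classification used.
#' @export
plotEOFSummary <- function(movie, eof = NULL, classification = NULL) {
  stopifnot(is(movie, "BiolumMovie"))
  if (is.null(eof)) eof <- computeEOF(movie)
  if (is.null(classification))
    classification <- classifyPixels(eof, movie = movie)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  nz <- normalizedEigenvalues(eof)
  k <- min(10, length(nz))
  graphics::barplot(nz[seq_len(k)], names.arg = seq_len(k),
                    xlab = "mode", ylab = "variance [%]",
                    main = "EOF eigenvalues", col = "grey40")

  co <- pixelCoords(movie)
  lab <- classification@labels
  colors <- c("red", "green3")
  cl <- ifelse(is.na(lab), "grey80",
               colors[pmin(lab, 2)])
  graphics::plot(co$x, co$y, col = cl, pch = 15, cex = 0.8, asp = 1,
                 xlab = "x", ylab = "y", main = "classified pixels")

  pers <- classification@periods
  allPer <- unlist(pers)
  if (length(allPer)) {
    br <- seq(floor(min(allPer)) - 0.5, ceiling(max(allPer)) + 0.5, by = 1)
    h1 <- if (length(pers[[1]])) graphics::hist(pers[[1]], breaks = br,
                                                plot = FALSE)
    graphics::hist(if (length(pers[[1]])) pers[[1]] else NA, breaks = br,
                   col = grDevices::adjustcolor("red", 0.5),
                   xlab = "period [h]", main = "period distribution")
    if (length(pers) > 1 && length(pers[[2]]))
      graphics::hist(pers[[2]], breaks = br, add = TRUE,
                     col = grDevices::adjustcolor("green3", 0.5))
  } else {
    graphics::plot.new(); graphics::title("period distribution (none significant)")
  }

  A <- movieMatrix(movie)
  tm <- sampleTimes(movie)
  graphics::plot(NULL, xlim = range(tm), ylim = range(A),
                 xlab = "time [h]", ylab = "signal", main = "class-mean traces")
  for (i in seq_len(min(2, classification@nComponents))) {
    sel <- which(lab == i)
    if (length(sel))
      graphics::lines(tm, rowMeans(A[, sel, drop = FALSE]), col = colors[i])
  }
  invisible(classification)
}
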