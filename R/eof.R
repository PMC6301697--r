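#' @describeIn computeEOF Decompose a T x N sample matrix. When N > T the
#'   decomposition runs through the dual T x T problem
#'   (\eqn{A A^T u = \Omega u}, \eqn{e = A^T u / \sqrt{\Omega}}), which
#'   yields the identical nonzero spectrum. Modes with eigenvalues below
#'   \code{1e-12} of the leading one are dropped (they carry no variance),
#'   so the retained reconstruction
#'   \eqn{A = \sum_i c_i(t) e_i^T} is complete to numerical precision.
#' @export
setMethod("computeEOF", "matrix", function(x, center = TRUE, ...) {
  A <- x
  storage.mode(A) <- "double"
  if (any(!is.finite(A))) stop("movie matrix contains non-finite values")
  if (center) A <- sweep(A, 2, colMeans(A))
  total <- sum(A * A)
  if (total <= 0) stop("degenerate all-zero movie: no variance to decompose")
  T <- nrow(A); N <- ncol(A)
  if (N <= T) {
    R <- crossprod(A)                       # N x N covariance matrix
    ee <- eigen(R, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    vecs <- ee$vectors
  } else {
    C <- tcrossprod(A)                      # dual T x T problem
    ee <- eigen(C, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    pos <- vals > 1e-12 * vals[1]
    vecs <- crossprod(A, ee$vectors[, pos, drop = FALSE]) /
      rep(sqrt(vals[pos]), each = N)
    vals <- vals[pos]
  }
  keep <- vals > 1e-12 * max(vals[1], .Machine$double.eps)
  keep[1] <- TRUE
  vals <- vals[keep]
  vecs <- vecs[, seq_along(vals), drop = FALSE]
  modes <- A %*% vecs
  new("EOFResult",
      eigenvalues = vals,
      normalized = 100 * vals / sum(vals),
      vectors = vecs, modes = modes,
      totalVariance = total, centered = center)
})

#' @describeIn computeEOF Decompose a movie's sample matrix (typically
#'   after [preprocessMovie()]).
#' @export
setMethod("computeEOF", "BiolumMovie", function(x, center = TRUE, ...) {
  computeEOF(movieMatrix(x), center = center, ...)
})

#' @rdname EOFResult-class
#' @export
setMethod("eigenvalues", "EOFResult", function(object) object@eigenvalues)

#' @rdname EOFResult-class
#' @export
setMethod("normalizedEigenvalues", "EOFResult",
  function(object) object@normalized)

#' @rdname EOFResult-class
#' @export
setMethod("eofVectors", "EOFResult", function(object) object@vectors)

#' @rdname EOFResult-class
#' @export
setMethod("eofModes", "EOFResult", function(object) object@modes)

setMethod("show", "EOFResult", function(object) {
  k <- min(5, length(object@eigenvalues))
  cat(sprintf("EOFResult: %d modes over %d pixels\n",
              length(object@eigenvalues), nrow(object@vectors)))
  cat("  leading normalized eigenvalues (%):",
      paste(sprintf("%.1f", object@normalized[seq_len(k)]), collapse = ", "),
      "\n")
})

#' Classify pixels by their dominant EOF loading
#'
#' Pixel k receives the label of the mode \eqn{i \le} \code{nComponents}
#' maximizing the absolute loading \eqn{|e_i(k)|}, provided that loading
#' reaches \code{threshold / sqrt(N)} (the natural loading scale of an
#' N-pixel mode); otherwise the pixel stays unclassified. When the movie is
#' supplied, per-class period and acrophase distributions are computed for
#' the classified, periodogram-significant pixels.
#'
#' @param eof an [EOFResult-class].
#' @param movie optional [BiolumMovie-class] (preprocessed) used for the
#'   per-class period/acrophase distributions.
#' @param nComponents number of leading modes to classify into (default 2).
#' @param threshold loading fraction threshold (default 1; larger is
#'   stricter).
#' @param periods candidate period grid for the per-pixel periodogram.
#' @param alphaLevel periodogram significance level (default 0.01).
#' @return A [PixelClassification-class].
#' @export
classifyPixels <- function(eof, movie = NULL, nComponents = 2L, threshold = 1,
                           periods = seq(15, 40, by = 0.1),
                           alphaLevel = 0.01) {
  stopifnot(is(eof, "EOFResult"))
  nComponents <- as.integer(nComponents)
  if (nComponents > ncol(eof@vectors))
    stop("nComponents exceeds the number of computed modes")
  L <- abs(eof@vectors[, seq_len(nComponents), drop = FALSE])
  N <- nrow(L)
  lab <- max.col(L, ties.method = "first")
  top <- L[cbind(seq_len(N), lab)]
  lab[top < threshold / sqrt(N)] <- NA_integer_

  per <- setNames(vector("list", nComponents),
                  paste0("component", seq_len(nComponents)))
  acr <- per
  if (!is.null(movie)) {
    A <- movieMatrix(movie)
    tm <- sampleTimes(movie)
    pg <- periodogramMovie(A, dt = samplingInterval(movie),
                           periods = periods, alphaLevel = alphaLevel)
    for (i in seq_len(nComponents)) {
      sel <- which(lab == i & !is.na(pg$bestPeriod))
      per[[i]] <- pg$bestPeriod[sel]
      acr[[i]] <- vapply(sel, function(k)
        acrophase(A[, k], period = pg$bestPeriod[k], times = tm) %% 24,
        numeric(1))
    }
  }
  new("PixelClassification", labels = as.integer(lab),
      nComponents = nComponents, threshold = threshold,
      periods = per, acrophases = acr)
}

setMethod("show", "PixelClassification", function(object) {
  tab <- table(factor(object@labels, levels = seq_len(object@nComponents)),
               useNA = "always")
  cat("PixelClassification:",
      paste(sprintf("component %s: %d",
                    c(seq_len(object@nComponents), "unclassified"),
                    as.integer(tab)), collapse = ", "), "\n")
})
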