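#' Detrend and normalize a movie
#'
#' Each pixel's centered moving average over \code{window} hours is
#' subtracted and the residual is divided by the centered moving standard
#' deviation over the same window, removing the slow culture baseline decay
#' and equalizing pixel brightness. The moving mean uses symmetrically
#' shrinking windows toward the edges (which removes a linear trend exactly
#' everywhere); the moving s.d. uses clipped windows with a minimum of 5
#' samples. Columns are mean-centered afterwards so each pixel has exactly
#' zero temporal mean. Constant pixels cannot be normalized; they are
#' zero-filled with a warning.
#'
#' @param movie a [BiolumMovie-class].
#' @param window moving-window length in hours (>= one expected period;
#'   default 24).
#' @return A [BiolumMovie-class] with the detrended, normalized signal.
#' @examples
#' t <- 0:143
#' raw <- outer(exp(-t / 100), rep(1, 3)) *
#'   (1 + 0.5 * outer(cos(2 * pi * t / 24), rep(1, 3)))
#' mov <- BiolumMovie(raw, coords = data.frame(x = 1:3, y = 1))
#' pp <- preprocessMovie(mov)
#' @export
preprocessMovie <- function(movie, window = 24) {
  stopifnot(is(movie, "BiolumMovie"))
  if (window < 24) warning("window shorter than one expected period (24 h)")
  A <- movieMatrix(movie)
  dt <- samplingInterval(movie)
  h <- max(1L, round(window / dt / 2))
  mom <- runningMoments(A, halfwidth = h)
  S <- mom$sd
  flat <- apply(S, 2, function(s) all(s < 1e-12))
  S[S < 1e-12] <- 1
  out <- (A - mom$mean) / S
  if (any(flat)) {
    warning(sum(flat), " constant pixel(s) zero-filled")
    out[, flat] <- 0
  }
  out <- sweep(out, 2, colMeans(out))
  BiolumMovie(out, coords = pixelCoords(movie), times = sampleTimes(movie))
}
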