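#' Synchronization index of a movie
#'
#' Kuramoto order parameter
#' \eqn{R(t) = |N^{-1} \sum_k e^{i\theta_k(t)}|} across pixels, evaluated
#' at 24 hourly time points in the final window of the recording. Pixel
#' phases \eqn{\theta_k(t)} are extracted as the argument of the discrete
#' analytic signal (FFT construction) of each detrended pixel trace, so
#' the movie should normally be passed through [preprocessMovie()] first.
#'
#' @param movie a [BiolumMovie-class] (preprocessed) or a T x N matrix.
#' @param window length of the evaluation window (h, default 24; must
#'   contain at least 24 samples).
#' @param dt sampling interval when a bare matrix is given.
#' @return A list: \code{mean}, \code{sd} (over the 24 time points), and
#'   \code{series}, a data.frame with \code{time} and \code{R}.
#' @examples
#' t <- 0:143
#' A <- outer(cos(2 * pi * t / 24), rep(1, 10)) # identical pixels
#' syncIndex(A)$mean
#' @export
syncIndex <- function(movie, window = 24, dt = 1) {
  if (is(movie, "BiolumMovie")) {
    dt <- samplingInterval(movie)
    tm <- sampleTimes(movie)
    A <- movieMatrix(movie)
  } else {
    A <- as.matrix(movie)
    tm <- (seq_len(nrow(A)) - 1) * dt
  }
  step <- max(1L, round(1 / dt))     # hourly evaluation points
  nPts <- round(window / 1)
  need <- (nPts - 1L) * step + 1L
  if (nrow(A) < need || nPts < 24)
    stop("window must contain at least 24 hourly samples")
  z <- analyticSignal(sweep(A, 2, colMeans(A)))
  theta <- Arg(z)
  idx <- seq(nrow(A) - (nPts - 1L) * step, nrow(A), by = step)
  Rt <- Mod(rowMeans(exp(1i * theta[idx, , drop = FALSE])))
  list(mean = mean(Rt), sd = sd(Rt),
       series = data.frame(time = tm[idx], R = Rt))
}

#' Ratio of 24-h spectral components between two recording windows
#'
#' The ensemble-mean trace of each movie is trimmed to a whole number of
#' 24-h cycles (avoiding spectral leakage) and the discrete Fourier
#' amplitude at the frequency bin nearest 1/24 h is taken; the returned
#' ratio is after / before. Values above 1 mean the rhythm strengthened
#' between the windows (e.g. after a drug treatment).
#'
#' @param movieBefore,movieAfter two [BiolumMovie-class] windows of at
#'   least 48 h each, typically before and after a treatment.
#' @param period reference period (h, default 24).
#' @return The amplitude ratio (dimensionless); \code{Inf} with a warning
#'   when the before-window amplitude is numerically zero.
#' @export
periodComponentRatio <- function(movieBefore, movieAfter, period = 24) {
  ampOf <- function(movie) {
    stopifnot(is(movie, "BiolumMovie"))
    dt <- samplingInterval(movie)
    if (nrow(movieMatrix(movie)) * dt < 48)
      stop("each window must cover at least 48 h")
    m <- rowMeans(movieMatrix(movie))
    cyc <- floor(length(m) * dt / period)
    keep <- round(cyc * period / dt)
    m <- m[seq_len(keep)]
    tt <- (seq_len(keep) - 1) * dt
    co <- sum(m * exp(-2i * pi * tt / period))
    2 * Mod(co) / keep
  }
  before <- ampOf(movieBefore)
  after <- ampOf(movieAfter)
  if (before < .Machine$double.eps * 100) {
    warning("zero 24-h amplitude in the before window: ratio is infinite")
    return(Inf)
  }
  after / before
}
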