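#' Derive a reproducible child seed from a root seed and a stream name
#'
#' One root seed spawns named sub-streams (geometry, periods, dynamics,
#' imaging, replicate indices) so that individual pipeline stages can be
#' re-seeded independently without correlating their random draws.
#'
#' @param seed integer root seed.
#' @param stream character scalar naming the sub-stream.
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @examples
#' deriveSeed(1, "dynamics")
#' @export
deriveSeed <- function(seed, stream = "default") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stream)) {
    # multiplicative string hash kept in double precision (< 2^53 throughout)
    h <- (h * 69069 + code) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar numeric check used by validity methods
isScalarNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Centered running mean / sd used by movie preprocessing.
#
# The mean uses symmetrically shrinking windows (halfwidth min(h, t-1, T-t)),
# which removes a linear trend exactly at every sample including the edges.
# The sd uses clipped windows with at least `minCount` samples so it never
# degenerates at the boundaries.
runningMoments <- function(A, halfwidth, minCount = 5L) {
  A <- as.matrix(A)
  T <- nrow(A)
  h <- as.integer(halfwidth)
  cs <- apply(A, 2, cumsum)
  cs2 <- apply(A * A, 2, cumsum)
  if (is.null(dim(cs))) { cs <- matrix(cs, nrow = T); cs2 <- matrix(cs2, nrow = T) }
  zero <- matrix(0, 1L, ncol(A))
  cs <- rbind(zero, cs)
  cs2 <- rbind(zero, cs2)
  idx <- seq_len(T)
  wSym <- pmin(h, idx - 1L, T - idx)
  loM <- idx - wSym
  hiM <- idx + wSym
  nM <- hiM - loM + 1
  M <- (cs[hiM + 1L, , drop = FALSE] - cs[loM, , drop = FALSE]) / nM
  loS <- pmax(1L, idx - h)
  hiS <- pmin(T, idx + h)
  # widen clipped sd windows until they hold at least minCount samples
  short <- (hiS - loS + 1L) < minCount
  hiS[short] <- pmin(T, loS[short] + minCount - 1L)
  loS[short] <- pmax(1L, hiS[short] - minCount + 1L)
  nS <- hiS - loS + 1
  s1 <- cs[hiS + 1L, , drop = FALSE] - cs[loS, , drop = FALSE]
  s2 <- cs2[hiS + 1L, , drop = FALSE] - cs2[loS, , drop = FALSE]
  v <- (s2 - s1 * s1 / nS) / pmax(nS - 1, 1)
  v[v < 0] <- 0
  list(mean = M, sd = sqrt(v))
}

# Discrete analytic signal (FFT construction); columns of x are independent
# signals. Exact for frequencies on the DFT grid; standard one-sided spectrum
# doubling elsewhere. Returns a complex matrix of the same shape.
analyticSignal <- function(x) {
  x <- as.matrix(x)
  T <- nrow(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[c(1, T / 2 + 1)] <- 1
    h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T + 1) / 2)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / T
  z
}

# Polynomial rolling hash of a character scalar, reported as hex; used to
# stamp configurations into run logs and sidecar files.
configHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 17
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2^31
  sprintf("%08x", as.integer(h))
}
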