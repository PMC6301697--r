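#' Deterministic analytic test movies
#'
#' Small movies with analytically known EOF spectra and periods, used
#' throughout the test suite and as quick sanity inputs. All fixtures are
#' byte-identical across calls (the white-noise fixture uses an internal
#' fixed seed and restores the caller's RNG state).
#'
#' \describe{
#'   \item{"rank1"}{144 x 20: one 24-h cosine shared by all pixels with
#'     pixel-specific weights; a single EOF mode carries 100\% of the
#'     variance.}
#'   \item{"sincos-50-50"}{144 x 40: half the pixels sin, half cos at 24 h
#'     over exactly 6 cycles; two EOF modes of exactly 50\% each.}
#'   \item{"two-cluster-periods"}{192 x 40: a 21-h cluster (amplitude 1.2)
#'     and a 32-h cluster (amplitude 1.0), emulating a split slice with
#'     lobe-segregated rhythms.}
#'   \item{"white-noise"}{144 x 40 i.i.d. standard normal.}
#' }
#'
#' @param name fixture name.
#' @return A [BiolumMovie-class].
#' @examples
#' normalizedEigenvalues(computeEOF(preprocessMovie(fixtureMovie("rank1"))))[1]
#' @export
fixtureMovie <- function(name = c("rank1", "sincos-50-50",
                                  "two-cluster-periods", "white-noise")) {
  if (!is.character(name) || length(name) != 1L)
    stop("fixture name must be a single string")
  name <- match.arg(name)
  coords40 <- data.frame(x = rep(1:8, 5), y = rep(1:5, each = 8))
  switch(name,
    "rank1" = {
      t <- 0:143
      w <- seq(0.5, 1.5, length.out = 20)
      BiolumMovie(outer(cos(2 * pi * t / 24), w),
                  coords = data.frame(x = rep(1:5, 4), y = rep(1:4, each = 5)))
    },
    "sincos-50-50" = {
      t <- 0:143
      A <- cbind(outer(sin(2 * pi * t / 24), rep(1, 20)),
                 outer(cos(2 * pi * t / 24), rep(1, 20)))
      BiolumMovie(A, coords = coords40)
    },
    "two-cluster-periods" = {
      t <- 0:191
      ph <- rep(c(0, 0.4), 10) # mild within-cluster phase texture
      A <- cbind(
        vapply(ph, function(p) 1.2 * cos(2 * pi * t / 21 + p), numeric(192)),
        vapply(ph, function(p) 1.0 * cos(2 * pi * t / 32 + p), numeric(192)))
      BiolumMovie(A, coords = data.frame(
        x = c(rep(1:4, 5), rep(9:12, 5)), y = rep(rep(1:5, each = 4), 2)))
    },
    "white-noise" = {
      A <- withSeed(48151623, matrix(rnorm(144 * 40), 144, 40))
      BiolumMovie(A, coords = coords40)
    })
}
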