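#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period \eqn{p} the trace is folded into
#' \eqn{B = \lfloor p/dt \rfloor} phase bins with means \eqn{M_h} over
#' \eqn{K_h} samples each, and the statistic
#' \deqn{Q_p = \frac{n \sum_h K_h (M_h - \bar{x})^2}{\sum_i (x_i - \bar{x})^2}}
#' (the count-weighted between-bin sum of squares over the pooled
#' variance) is compared against the \eqn{\chi^2_{B-1}} quantile at
#' \code{alphaLevel}. Fractional periods (non-multiples of the sampling
#' interval) are handled by folding sample times onto a continuous phase
#' before binning. The best period is the significant candidate maximizing
#' \eqn{Q_p}; \code{NA} when no candidate is significant. By default the
#' significance line is Bonferroni-adjusted for the number of candidate
#' periods, so \code{alphaLevel} bounds the probability of declaring any
#' rhythm in noise (see the \code{adjust} argument for the raw pointwise
#' line).
#'
#' @param x numeric trace (or a [CellTrace-class]).
#' @param dt sampling interval (h).
#' @param periods candidate period grid (h), default \code{seq(15, 40,
#'   0.1)}; must be coarser than \code{dt} and at most a third of the
#'   record length.
#' @param alphaLevel significance level (default 0.01).
#' @param adjust "bonferroni" (default) or "none": whether the significance
#'   line accounts for the size of the candidate grid.
#' @return A list: \code{bestPeriod} (h or NA), and \code{curve}, a
#'   data.frame with \code{period}, \code{Q}, \code{df},
#'   \code{threshold}, \code{significant}.
#' @examples
#' x <- cos(2 * pi * (0:143) / 24)
#' chisqPeriodogram(x)$bestPeriod
#' @export
chisqPeriodogram <- function(x, dt = 1, periods = seq(15, 40, by = 0.1),
                             alphaLevel = 0.01,
                             adjust = c("bonferroni", "none")) {
  if (is(x, "CellTrace")) {
    dt <- if (length(x@times) > 1) diff(x@times)[1] else dt
    x <- x@x
  }
  res <- periodogramMovie(matrix(x, ncol = 1), dt = dt, periods = periods,
                          alphaLevel = alphaLevel, adjust = adjust)
  list(bestPeriod = res$bestPeriod[1],
       curve = data.frame(period = periods, Q = res$Q[, 1], df = res$df,
                          threshold = res$threshold,
                          significant = res$Q[, 1] > res$threshold))
}

#' Chi-square periodogram across all pixels of a movie
#'
#' Vectorized form of [chisqPeriodogram()]: the fold/bin structure of each
#' candidate period depends only on the time grid, so bin means for all
#' pixels are accumulated in one pass per candidate.
#'
#' @param A T x N sample matrix (or a [BiolumMovie-class]).
#' @inheritParams chisqPeriodogram
#' @return A list: \code{bestPeriod} (length N, NA where not significant),
#'   \code{Q} (candidates x N), \code{df}, \code{threshold}.
#' @export
periodogramMovie <- function(A, dt = 1, periods = seq(15, 40, by = 0.1),
                             alphaLevel = 0.01,
                             adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (is(A, "BiolumMovie")) { dt <- samplingInterval(A); A <- movieMatrix(A) }
  A <- as.matrix(A)
  n <- nrow(A)
  if (length(periods) > 1 && min(diff(periods)) <= 0)
    stop("period grid must be strictly increasing")
  if (min(periods) < 2 * dt)
    stop("period grid coarser than the sampling interval is required")
  if (max(periods) > n * dt / 3)
    stop("record must cover at least 3 cycles of the largest candidate period")
  tms <- (seq_len(n) - 1) * dt
  xbar <- colMeans(A)
  Ac <- sweep(A, 2, xbar)
  ssTot <- colSums(Ac * Ac)
  ssTot[ssTot <= 0] <- NA_real_

  nP <- length(periods)
  Q <- matrix(NA_real_, nP, ncol(A))
  df <- integer(nP)
  for (j in seq_len(nP)) {
    p <- periods[j]
    B <- max(2L, floor(p / dt))
    bin <- pmin(floor(((tms %% p) / p) * B) + 1L, B)
    cnt <- tabulate(bin, nbins = B)
    used <- cnt > 0
    M <- rowsum(Ac, bin, reorder = TRUE) / cnt[used]
    Bu <- sum(used)
    # count-weighted between-bin sum of squares over the pooled variance:
    # exactly chi-square with B-1 df for Gaussian noise, and free of the
    # unequal-bin-count bias of the equal-weight form
    Q[j, ] <- n * colSums(cnt[used] * M * M) / ssTot
    df[j] <- Bu - 1L
  }
  alphaEff <- if (adjust == "bonferroni") alphaLevel / nP else alphaLevel
  threshold <- qchisq(1 - alphaEff, df)
  sig <- Q > threshold
  best <- vapply(seq_len(ncol(A)), function(k) {
    ok <- which(sig[, k])
    if (!length(ok)) NA_real_ else periods[ok[which.max(Q[ok, k])]]
  }, numeric(1))
  list(bestPeriod = best, Q = Q, df = df, threshold = threshold)
}

#' Acrophase of a rhythmic trace
#'
#' Least-squares cosine fit \eqn{A\cos(2\pi(t-\phi_a)/p) + c} at the given
#' period; the acrophase is the fitted peak time modulo the period.
#'
#' @param x numeric trace (or a [CellTrace-class]).
#' @param period oscillation period (h), typically the periodogram's
#'   significant best period.
#' @param times sample times (h); defaults to hourly from 0.
#' @return Acrophase in hours in \code{[0, period)}; \code{NA} with a
#'   warning when the fitted amplitude is numerically zero.
#' @examples
#' t <- 0:143
#' acrophase(cos(2 * pi * (t - 5) / 24), period = 24, times = t)
#' @export
acrophase <- function(x, period, times = NULL) {
  if (is(x, "CellTrace")) { times <- x@times; x <- x@x }
  if (is.null(times)) times <- seq_along(x) - 1
  cc <- cos(2 * pi * times / period)
  ss <- sin(2 * pi * times / period)
  fit <- lm(x ~ cc + ss)
  b <- coef(fit)
  amp <- sqrt(b["cc"]^2 + b["ss"]^2)
  if (!is.finite(amp) || amp < 1e-10 * max(sd(x), .Machine$double.eps)) {
    warning("zero-amplitude fit: acrophase undefined")
    return(NA_real_)
  }
  ph <- atan2(b[["ss"]], b[["cc"]]) * period / (2 * pi)
  ph %% period
}
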