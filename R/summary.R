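#' Summarize a slice movie into the standard rhythm metrics
#'
#' Runs the full analysis chain on one movie: detrending/normalization,
#' per-pixel chi-square periodogram (period mean and s.d. over the
#' significant pixels), EOF decomposition (summed normalized first and
#' second eigenvalues), and the synchronization index over the final 24
#' hourly time points. Deterministic: the same movie always yields the
#' identical summary.
#'
#' @param movie a raw [BiolumMovie-class].
#' @param window detrending window (h).
#' @param periods candidate period grid for the periodogram.
#' @param alphaLevel periodogram significance level.
#' @param adjust periodogram significance-line adjustment, see
#'   [chisqPeriodogram()].
#' @return A [SliceSummary-class]. When no pixel reaches periodogram
#'   significance the period fields are NA and the remaining metrics are
#'   still computed.
#' @examples
#' t <- 0:143
#' A <- outer(cos(2 * pi * t / 24), rep(1, 20)) +
#'   matrix(rnorm(144 * 20, sd = 0.05), 144, 20)
#' summarizeSlice(BiolumMovie(A, coords = cbind(1:20, 1)))
#' @export
summarizeSlice <- function(movie, window = 24,
                           periods = seq(15, 40, by = 0.1),
                           alphaLevel = 0.01,
                           adjust = c("bonferroni", "none")) {
  stopifnot(is(movie, "BiolumMovie"))
  pp <- preprocessMovie(movie, window = window)
  eof <- computeEOF(pp)
  pg <- periodogramMovie(pp, periods = periods, alphaLevel = alphaLevel,
                         adjust = adjust)
  per <- pg$bestPeriod[!is.na(pg$bestPeriod)]
  sync <- syncIndex(pp)
  nz <- normalizedEigenvalues(eof)
  new("SliceSummary",
      periodMean = if (length(per)) mean(per) else NA_real_,
      periodSd = if (length(per) > 1) sd(per) else
        if (length(per) == 1) 0 else NA_real_,
      nRhythmic = length(per),
      eig12Sum = sum(nz[seq_len(min(2, length(nz)))]),
      syncMean = sync$mean, syncSd = sync$sd)
}

setMethod("show", "SliceSummary", function(object) {
  cat("SliceSummary\n")
  cat(sprintf("  period: %.2f +/- %.2f h over %d rhythmic pixels\n",
              object@periodMean, object@periodSd, object@nRhythmic))
  cat(sprintf("  eigenvalues 1+2: %.1f%%   sync index: %.3f +/- %.3f\n",
              object@eig12Sum, object@syncMean, object@syncSd))
})

#' Compare a slice metric across groups (ANOVA + Fisher LSD)
#'
#' One-way analysis of variance over the group means followed by Fisher's
#' least-significant-difference post hoc comparisons (pairwise t statistics
#' using the pooled ANOVA mean square error, no multiplicity correction,
#' as is conventional for LSD after a significant omnibus F). Groups with
#' fewer than two observations are excluded with a warning.
#'
#' @param values numeric metric values, one per slice; alternatively a list
#'   of [SliceSummary-class] objects together with \code{metric}.
#' @param groups group labels, same length as \code{values}.
#' @param metric slot name extracted when \code{values} is a list of
#'   summaries (e.g. "eig12Sum", "periodMean", "syncMean").
#' @param level significance level for flagging pairs (default 0.01).
#' @return A list: \code{fStatistic}, \code{pValue}, \code{df}, and
#'   \code{lsd}, a data.frame of pairwise comparisons with columns
#'   \code{group1}, \code{group2}, \code{diff}, \code{t}, \code{p},
#'   \code{significant}.
#' @examples
#' set.seed(1)
#' groupCompare(c(rnorm(4), rnorm(4, 5)), rep(c("a", "b"), each = 4))
#' @export
groupCompare <- function(values, groups, metric = "eig12Sum", level = 0.01) {
  if (is.list(values) && all(vapply(values, is, TRUE, "SliceSummary")))
    values <- vapply(values, slot, numeric(1), metric)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with a single slice: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least two groups with two or more slices each")

  g <- factor(groups)
  fit <- aov(values ~ g)
  tab <- anova(fit)
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]

  lev <- levels(g)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  pairs <- utils::combn(lev, 2)
  lsd <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    row.names = NULL
  )
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  lsd$t <- as.numeric(lsd$diff / se)
  lsd$p <- 2 * pt(-abs(lsd$t), dfe)
  lsd$significant <- lsd$p < level
  list(fStatistic = tab["g", "F value"], pValue = tab["g", "Pr(>F)"],
       df = c(tab["g", "Df"], dfe), lsd = lsd)
}
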