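#' Build a two-lobed SCN lattice
#'
#' Each lobe is a disc-shaped subset of the integer grid (the
#' \code{cellsPerLobe} points closest to the lobe center) with 4-neighbour
#' adjacency. The two lobes face each other across the midline and are
#' connected by exactly \code{bridgeCount} symmetric inter-lobe edges
#' between medially adjacent boundary cells. The top-medial
#' \code{dorsomedialFraction} of each lobe is labelled dorsomedial.
#' Construction is deterministic; \code{seed} is accepted for interface
#' symmetry with the other builders.
#'
#' @param cellsPerLobe number of cells per lobe (>= 9).
#' @param bridgeCount number of inter-lobe bridge edges (>= 0).
#' @param dorsomedialFraction fraction of each lobe labelled dorsomedial,
#'   in [0, 1].
#' @param seed unused placeholder seed (construction is deterministic).
#' @return A [NetworkGeometry-class].
#' @examples
#' g <- buildGeometry(100, bridgeCount = 5, dorsomedialFraction = 0.1)
#' table(g@cells$lobe, g@cells$region)
#' @export
buildGeometry <- function(cellsPerLobe = 120, bridgeCount = 4,
                          dorsomedialFraction = 0.1, seed = 1L) {
  if (cellsPerLobe < 9) stop("cellsPerLobe must be >= 9")
  if (bridgeCount < 0) stop("bridgeCount must be >= 0")
  if (dorsomedialFraction < 0 || dorsomedialFraction > 1)
    stop("dorsomedialFraction must be in [0, 1]")

  discLobe <- function(n) {
    R <- ceiling(sqrt(n / pi)) + 2
    g <- expand.grid(gx = -R:R, gy = -R:R)
    d <- sqrt(g$gx^2 + g$gy^2)
    ang <- atan2(g$gy, g$gx)
    ord <- order(d, ang, g$gx)
    g[ord[seq_len(n)], ]
  }

  lobe <- discLobe(cellsPerLobe)
  span <- max(lobe$gx) - min(lobe$gx) + 3
  cells <- rbind(
    data.frame(lobe = "left", gx = lobe$gx - span, gy = lobe$gy),
    data.frame(lobe = "right", gx = lobe$gx + span, gy = lobe$gy)
  )
  cells$id <- seq_len(nrow(cells))

  # dorsomedial = toward the top and the midline
  medial <- ifelse(cells$lobe == "left", cells$gx, -cells$gx)
  score <- cells$gy + medial
  nDM <- round(dorsomedialFraction * cellsPerLobe)
  region <- rep("other", nrow(cells))
  for (lb in c("left", "right")) {
    idx <- which(cells$lobe == lb)
    top <- idx[order(-score[idx], cells$id[idx])][seq_len(nDM)]
    region[top] <- "dorsomedial"
  }

  # 4-neighbour intra-lobe edges
  key <- paste(cells$gx, cells$gy)
  lookup <- setNames(cells$id, key)
  from <- integer(0); to <- integer(0)
  for (shift in list(c(1, 0), c(0, 1))) {
    nb <- lookup[paste(cells$gx + shift[1], cells$gy + shift[2])]
    ok <- !is.na(nb) & cells$lobe == cells$lobe[nb] # same lobe by construction
    ok[is.na(ok)] <- FALSE
    from <- c(from, cells$id[ok]); to <- c(to, nb[ok])
  }
  edges <- data.frame(from = pmin(from, to), to = pmax(from, to),
                      bridge = FALSE)

  # bridges pair the medial boundary cells of the two lobes row by row,
  # innermost rows first
  if (bridgeCount > 0) {
    leftIdx <- which(cells$lobe == "left")
    rightIdx <- which(cells$lobe == "right")
    rows <- sort(unique(cells$gy), decreasing = FALSE)
    rows <- rows[order(abs(rows), rows)]
    bf <- integer(0); bt <- integer(0)
    for (gy in rows) {
      if (length(bf) >= bridgeCount) break
      lRow <- leftIdx[cells$gy[leftIdx] == gy]
      rRow <- rightIdx[cells$gy[rightIdx] == gy]
      if (!length(lRow) || !length(rRow)) next
      bf <- c(bf, lRow[which.max(cells$gx[lRow])])
      bt <- c(bt, rRow[which.min(cells$gx[rRow])])
    }
    if (length(bf) < bridgeCount)
      stop("lattice too small for the requested bridgeCount")
    edges <- rbind(edges, data.frame(
      from = pmin(bf, bt), to = pmax(bf, bt), bridge = TRUE))
  }

  new("NetworkGeometry",
      cells = data.frame(id = cells$id, lobe = cells$lobe,
                         region = region, x = cells$gx, y = cells$gy,
                         stringsAsFactors = FALSE),
      edges = edges)
}

#' Assign intrinsic periods across the lattice
#'
#' Draws per-cell intrinsic periods from a normal distribution and applies
#' regional mean shifts: dorsomedial cells get \code{dorsomedialOffset}
#' added to their mean (negative = shorter periods, as observed in the
#' innermost dorsomedial SCN), and right-lobe cells get
#' \code{rightLobeOffset} (positive values produce the left/right
#' "splitting" regime). Returned angular frequencies are
#' \eqn{\omega_i = 2\pi/\mathrm{period}_i}.
#'
#' @param geometry a [NetworkGeometry-class].
#' @param meanPeriod mean intrinsic period (h).
#' @param sdPeriod period scatter s.d. (h).
#' @param dorsomedialOffset mean shift (h) for dorsomedial cells.
#' @param rightLobeOffset additional mean shift (h) for right-lobe cells.
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{period}, \code{omega}.
#' @export
assignPeriods <- function(geometry, meanPeriod = 24, sdPeriod = 1.5,
                          dorsomedialOffset = 0, rightLobeOffset = 0,
                          seed = 1L) {
  stopifnot(is(geometry, "NetworkGeometry"))
  cells <- geometry@cells
  mu <- rep(meanPeriod, nrow(cells))
  mu[cells$region == "dorsomedial"] <- mu[cells$region == "dorsomedial"] +
    dorsomedialOffset
  mu[cells$lobe == "right"] <- mu[cells$lobe == "right"] + rightLobeOffset
  if (any(mu <= 0)) stop("offsets produce non-positive mean periods")
  per <- withSeed(deriveSeed(seed, "periods"),
                  rnorm(nrow(cells), mean = mu, sd = sdPeriod))
  per <- pmax(per, 5) # guard the far tail; periods must stay positive
  data.frame(id = cells$id, period = per, omega = 2 * pi / per)
}

# weighted sparse adjacency of the effective coupling; bridge edges are
# scaled by bridgeFactor
couplingMatrix <- function(scenario) {
  geom <- scenario@geometry
  n <- nrow(geom@cells)
  K <- scenario@aAvp * scenario@kAvp + scenario@aVip * scenario@kVip
  e <- geom@edges
  if (!nrow(e) || K == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  w <- ifelse(e$bridge, K * scenario@bridgeFactor, K)
  Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                       x = c(w, w), dims = c(n, n))
}
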