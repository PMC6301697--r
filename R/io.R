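#' Movie CSV input/output
#'
#' Movies travel as a wide CSV (first column \code{time} in hours, one
#' column per pixel) with a companion coordinates CSV (\code{id},
#' \code{x}, \code{y}).
#'
#' @param movie a [BiolumMovie-class].
#' @param path movie CSV path.
#' @param coordsPath coordinates CSV path; defaults to
#'   \code{<path>-coords.csv} next to the movie file.
#' @return \code{readMovieCSV} returns a [BiolumMovie-class];
#'   \code{writeMovieCSV} returns \code{path} invisibly.
#' @export
writeMovieCSV <- function(movie, path, coordsPath = defaultCoordsPath(path)) {
  stopifnot(is(movie, "BiolumMovie"))
  A <- movieMatrix(movie)
  df <- data.frame(time = sampleTimes(movie), A)
  names(df) <- c("time", rownames(SummarizedExperiment::assay(movie)))
  write.csv(df, path, row.names = FALSE)
  co <- pixelCoords(movie)
  write.csv(data.frame(id = rownames(SummarizedExperiment::assay(movie)),
                       x = co$x, y = co$y),
            coordsPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMovieCSV
#' @export
readMovieCSV <- function(path, coordsPath = defaultCoordsPath(path)) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column of a movie CSV must be 'time'")
  A <- as.matrix(df[, -1, drop = FALSE])
  if (file.exists(coordsPath)) {
    co <- read.csv(coordsPath)
    co <- co[match(colnames(A), co$id), ]
    coords <- data.frame(x = co$x, y = co$y)
  } else {
    coords <- data.frame(x = seq_len(ncol(A)), y = 0)
  }
  BiolumMovie(A, coords = coords, times = df$time)
}

defaultCoordsPath <- function(path) {
  sub("\\.csv$", "-coords.csv", path)
}

#' Read a movie from a multi-page TIFF stack
#'
#' One page per frame (hourly by default); an optional mask file (CSV of
#' 0/1 with image dimensions, or a threshold on the mean image) selects
#' the pixels that enter the movie.
#'
#' @param path TIFF file path.
#' @param maskPath optional CSV mask (0/1 matrix of image dimensions).
#' @param dt frame interval in hours.
#' @return A [BiolumMovie-class].
#' @export
readMovieTIFF <- function(path, maskPath = NULL, dt = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])[1:2]
  mask <- if (is.null(maskPath)) matrix(TRUE, dims[1], dims[2])
          else as.matrix(read.csv(maskPath, header = FALSE)) > 0
  keep <- which(mask)
  A <- vapply(pages, function(pg) as.vector(pg[, , drop = TRUE][keep]),
              numeric(length(keep)))
  rc <- arrayInd(keep, dims)
  BiolumMovie(t(A), coords = data.frame(x = rc[, 2], y = rc[, 1]), dt = dt)
}

#' Cell trace CSV input/output
#'
#' Two-column CSV (\code{time}, \code{value}) with a header line, times in
#' hours.
#'
#' @param trace a [CellTrace-class].
#' @param path file path.
#' @return \code{readCellTraceCSV} returns a [CellTrace-class].
#' @export
writeCellTraceCSV <- function(trace, path) {
  stopifnot(is(trace, "CellTrace"))
  write.csv(data.frame(time = trace@times, value = trace@x), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellTraceCSV
#' @export
readCellTraceCSV <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("trace CSV needs columns time, value")
  new("CellTrace", times = as.numeric(df[[1]]), x = as.numeric(df[[2]]),
      y = numeric(0))
}

#' Oscillator parameter JSON input/output
#'
#' Flat JSON with keys \code{alpha}, \code{omega}, \code{damping},
#' \code{d_r}, \code{d_phi}.
#'
#' @param params an [OscillatorParams-class].
#' @param path file path (.json or .yaml/.yml).
#' @return \code{readParamsFile} returns an [OscillatorParams-class].
#' @export
writeParamsFile <- function(params, path) {
  stopifnot(is(params, "OscillatorParams"))
  x <- list(alpha = params@alpha, omega = params@omega,
            damping = params@damping, d_r = params@dR, d_phi = params@dPhi)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParamsFile
#' @export
readParamsFile <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  OscillatorParams(alpha = x$alpha, omega = x$omega, damping = x$damping,
                   dR = x$d_r, dPhi = x$d_phi)
}

# flat list representation of a scenario (geometry regenerated on read)
scenarioToList <- function(scenario) {
  g <- scenario@geometry
  p <- scenario@params
  list(
    name = scenario@name,
    cellsPerLobe = sum(g@cells$lobe == "left"),
    bridgeCount = sum(g@edges$bridge),
    dorsomedialFraction = mean(g@cells$region == "dorsomedial"),
    params = list(alpha = p@alpha, omega = p@omega, damping = p@damping,
                  d_r = p@dR, d_phi = p@dPhi),
    omega = scenario@omega,
    aVip = scenario@aVip, aAvp = scenario@aAvp,
    kVip = scenario@kVip, kAvp = scenario@kAvp,
    bridgeFactor = scenario@bridgeFactor,
    iVip = scenario@iVip, iAvp = scenario@iAvp, phi = scenario@phi,
    antagonist = scenario@antagonist, vipReceptor = scenario@vipReceptor,
    duration = scenario@duration, burnin = scenario@burnin,
    dt = scenario@dt, sampleInterval = scenario@sampleInterval,
    initPhaseSd = scenario@initPhaseSd, seed = scenario@seed
  )
}

listToScenario <- function(x) {
  geom <- buildGeometry(cellsPerLobe = x$cellsPerLobe,
                        bridgeCount = x$bridgeCount,
                        dorsomedialFraction = x$dorsomedialFraction)
  p <- x$params
  NetworkScenario(
    geometry = geom,
    params = OscillatorParams(alpha = p$alpha, omega = p$omega,
                              damping = p$damping, dR = p$d_r,
                              dPhi = p$d_phi),
    omega = as.numeric(x$omega),
    aVip = x$aVip, aAvp = x$aAvp, kVip = x$kVip, kAvp = x$kAvp,
    bridgeFactor = x$bridgeFactor, iVip = x$iVip, iAvp = x$iAvp,
    phi = x$phi, antagonist = x$antagonist,
    antagonistBlocksCoupling = FALSE, # stored aAvp already reflects it
    vipReceptor = x$vipReceptor, duration = x$duration, burnin = x$burnin,
    dt = x$dt, sampleInterval = x$sampleInterval,
    initPhaseSd = {
      v <- suppressWarnings(as.numeric(x$initPhaseSd))
      if (length(v) != 1L || is.na(v)) NA_real_ else v
    },
    seed = x$seed, name = x$name)
}

#' Scenario file input/output
#'
#' Scenarios are stored as YAML or JSON (by file extension) mirroring the
#' [NetworkScenario-class] fields; the lattice itself is regenerated
#' deterministically from its construction parameters on read.
#'
#' @param scenario a [NetworkScenario-class].
#' @param path file path ending in .yaml/.yml or .json.
#' @return \code{readScenario} returns a [NetworkScenario-class].
#' @export
writeScenario <- function(scenario, path) {
  stopifnot(is(scenario, "NetworkScenario"))
  x <- scenarioToList(scenario)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path, precision = 15L)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  listToScenario(x)
}

#' Write a network run as CSV plus JSON sidecar
#'
#' The wide CSV holds the time column and one column per cell id; the
#' sidecar records the full scenario, the seed, the package version, and a
#' hash of the configuration.
#'
#' @param run a [NetworkRun-class].
#' @param path output CSV path; the sidecar is written to
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeNetworkRun <- function(run, path) {
  stopifnot(is(run, "NetworkRun"))
  df <- data.frame(time = run@times, run@traces)
  names(df) <- c("time", sprintf("cell%d", run@scenario@geometry@cells$id))
  write.csv(df, path, row.names = FALSE)
  cfg <- scenarioToList(run@scenario)
  cfgJSON <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  sidecar <- list(
    scenario = cfg, seed = run@seed,
    package = as.character(utils::packageVersion("scnCoupling")),
    configHash = configHash(as.character(cfgJSON)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the EOF analysis report bundle
#'
#' Writes \code{eigenvalues.csv} (eigenvalues and normalized percentages),
#' \code{loadings.csv}, \code{modes.csv}, \code{classification.csv}
#' (per-pixel labels and coordinates), \code{summary.json} (the
#' [SliceSummary-class] fields), and a PNG figure with the eigenvalue
#' spectrum, the classified pixel map, the per-class period histogram,
#' and the class-mean traces.
#'
#' @param movie the raw [BiolumMovie-class] that was analyzed.
#' @param outDir output directory (created if missing).
#' @param window,periods,alphaLevel,adjust analysis settings, see
#'   [summarizeSlice()].
#' @param figure logical, also write \code{report.png}.
#' @return \code{outDir}, invisibly.
#' @export
writeEOFReport <- function(movie, outDir, window = 24,
                           periods = seq(15, 40, by = 0.1),
                           alphaLevel = 0.01,
                           adjust = c("bonferroni", "none"),
                           figure = TRUE) {
  stopifnot(is(movie, "BiolumMovie"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pp <- preprocessMovie(movie, window = window)
  eof <- computeEOF(pp)
  cls <- classifyPixels(eof, movie = pp, periods = periods,
                        alphaLevel = alphaLevel)
  summ <- summarizeSlice(movie, window = window, periods = periods,
                         alphaLevel = alphaLevel, adjust = adjust)
  nz <- normalizedEigenvalues(eof)
  write.csv(data.frame(mode = seq_along(nz),
                       eigenvalue = eigenvalues(eof),
                       normalizedPercent = nz),
            file.path(outDir, "eigenvalues.csv"), row.names = FALSE)
  write.csv(data.frame(pixel = seq_len(nrow(eofVectors(eof))),
                       eofVectors(eof)[, seq_len(min(5, length(nz))),
                                       drop = FALSE]),
            file.path(outDir, "loadings.csv"), row.names = FALSE)
  write.csv(data.frame(time = sampleTimes(movie),
                       eofModes(eof)[, seq_len(min(5, length(nz))),
                                     drop = FALSE]),
            file.path(outDir, "modes.csv"), row.names = FALSE)
  co <- pixelCoords(movie)
  write.csv(data.frame(pixel = seq_len(nrow(co)), x = co$x, y = co$y,
                       component = cls@labels),
            file.path(outDir, "classification.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(periodMean = summ@periodMean, periodSd = summ@periodSd,
         nRhythmic = summ@nRhythmic, eig12Sum = summ@eig12Sum,
         syncMean = summ@syncMean, syncSd = summ@syncSd),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (figure) {
    grDevices::png(file.path(outDir, "report.png"), width = 1400,
                   height = 1000, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    plotEOFSummary(pp, eof, cls)
  }
  invisible(outDir)
}
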