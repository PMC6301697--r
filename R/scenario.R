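#' Construct a network scenario
#'
#' Low-level constructor; most users should start from [scenarioPreset()].
#' The antagonist flag forces \code{iAvp = 0} and, when
#' \code{antagonistBlocksCoupling} (default), also \code{aAvp = 0}: the
#' receptor blockade silences AVP signaling onto the slice cells
#' themselves, not only the graft input.
#'
#' @param geometry a [NetworkGeometry-class].
#' @param params base [OscillatorParams-class].
#' @param omega per-cell angular frequencies; defaults to the base omega.
#' @param aVip,aAvp attenuation factors in [0, 1].
#' @param kVip,kAvp channel coupling strengths.
#' @param bridgeFactor inter-lobe coupling multiplier.
#' @param iVip,iAvp forcing intensities (signal units/h).
#' @param phi VIP forcing phase delay (h in [0, 24)).
#' @param antagonist AVP receptor antagonist applied.
#' @param antagonistBlocksCoupling should the antagonist also zero
#'   \code{aAvp}.
#' @param vipReceptor VIP receptor present (FALSE for Vipr2 knockouts).
#' @param duration,burnin,dt,sampleInterval integration grid (h).
#' @param initPhaseSd initial phase spread s.d. (rad), NA = uniform.
#' @param seed integer root seed stored with the scenario.
#' @param name scenario label.
#' @return A [NetworkScenario-class].
#' @export
NetworkScenario <- function(geometry, params, omega = NULL,
                            aVip = 1, aAvp = 1, kVip = 0.5, kAvp = 0.5,
                            bridgeFactor = 0.1,
                            iVip = 0, iAvp = 0, phi = 0,
                            antagonist = FALSE,
                            antagonistBlocksCoupling = TRUE,
                            vipReceptor = TRUE,
                            duration = 144, burnin = 24, dt = 0.01,
                            sampleInterval = 1, initPhaseSd = NA_real_,
                            seed = 1L, name = "custom") {
  if (is.null(omega)) omega <- rep(params@omega, nrow(geometry@cells))
  if (antagonist) {
    iAvp <- 0
    if (antagonistBlocksCoupling) aAvp <- 0
  }
  new("NetworkScenario", name = name, geometry = geometry, params = params,
      omega = omega, aVip = aVip, aAvp = aAvp, kVip = kVip, kAvp = kAvp,
      bridgeFactor = bridgeFactor, iVip = iVip, iAvp = iAvp, phi = phi,
      antagonist = antagonist, vipReceptor = vipReceptor,
      duration = duration, burnin = burnin, dt = dt,
      sampleInterval = sampleInterval, initPhaseSd = initPhaseSd,
      seed = as.integer(seed))
}

#' Scenario presets for the genotype / age / co-culture conditions
#'
#' Returns a fully populated [NetworkScenario-class] for the named
#' experimental condition. The attenuation scheme follows the developmental
#' and knockout scenario: VIP coupling is attenuated in adults, AVP
#' coupling is attenuated in Cry1/Cry2 double knockouts
#' (\code{aVip = aAvp = 0.1}), and the triple knockout additionally
#' inactivates VIP coupling completely (\code{aVip = 0}) and removes the
#' VIP receptor, so external VIP forcing is ineffective. Co-culture presets
#' add 24-h sinusoidal forcing \code{iVip = iAvp = 0.01} with the VIP input
#' phase-delayed by \code{phi = 11} h; antagonist presets set
#' \code{iAvp = 0} (and \code{aAvp = 0}). Wild-type presets assign
#' dorsomedial cells a 1 h shorter mean period. The "split" double-knockout
#' preset represents the rhythmic minority of double-knockout slices that
#' de-synchronize into lobe-wise rhythms: "dko-rhythmic fit" cells on the
#' synchronized side of the critical coupling border
#' (\code{aVip = aAvp = 0.6}), weakened inter-lobe bridges, right-lobe
#' mean periods 5 h longer with broader scatter than the coherent left
#' lobe, and a phase-coherent start (the split then develops in culture as
#' the lobes drift apart).
#'
#' @param name preset name; one of "neonate-wt", "neonate-dko",
#'   "neonate-dko-split", "neonate-tko", "adult-wt", "adult-dko",
#'   "adult-tko", "coculture-dko", "coculture-dko-antagonist",
#'   "coculture-tko", "coculture-tko-antagonist".
#' @param seed integer root seed; geometry, period draws, and dynamics all
#'   derive their streams from it.
#' @param cellsPerLobe lattice size per lobe (default 120, ~240 cells).
#' @param duration recorded length (h, default 144 = 6 days of hourly
#'   frames).
#' @param ... overrides passed on to [NetworkScenario()].
#' @return A [NetworkScenario-class].
#' @examples
#' sc <- scenarioPreset("neonate-tko", seed = 1)
#' sc@aVip; sc@iAvp
#' @export
scenarioPreset <- function(name, seed = 1L, cellsPerLobe = 120,
                           duration = 144, ...) {
  presets <- c("neonate-wt", "neonate-dko", "neonate-dko-split",
               "neonate-tko", "adult-wt", "adult-dko", "adult-tko",
               "coculture-dko", "coculture-dko-antagonist",
               "coculture-tko", "coculture-tko-antagonist")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset; available: ", paste(presets, collapse = ", "))

  wt <- grepl("-wt$", name)
  tko <- grepl("tko", name)
  cocult <- grepl("^coculture", name)
  antag <- grepl("antagonist$", name)
  split <- grepl("split$", name)
  adult <- grepl("^adult|^coculture", name) # co-culture recipients are adult

  params <- oscillatorPreset(
    if (wt) "wild-type fit" else if (split) "dko-rhythmic fit" else "dko fit")

  aVip <- if (tko) 0 else if (wt) 1 else 0.1
  if (adult && wt) aVip <- 0.5 # developmental VIP attenuation
  aAvp <- if (wt) 1 else 0.1

  sdPeriod <- if (wt || split) 1.5 else 3
  dmOffset <- if (wt) -1 else 0
  rightOffset <- if (split) 5 else 0
  bridgeFactor <- if (split) 0.02 else 0.1
  if (split) { aVip <- 0.6; aAvp <- 0.6 }

  geom <- buildGeometry(cellsPerLobe = cellsPerLobe, bridgeCount = 4,
                        dorsomedialFraction = 0.1,
                        seed = deriveSeed(seed, "geometry"))
  per <- assignPeriods(geom, meanPeriod = 24, sdPeriod = sdPeriod,
                       dorsomedialOffset = dmOffset,
                       rightLobeOffset = rightOffset,
                       seed = deriveSeed(seed, "periods"))
  if (split) {
    # the long-period (right) lobe is broader-scattered than the coherent
    # short-period lobe, matching the variance asymmetry of split slices
    right <- geom@cells$lobe == "right"
    per$period[right] <- per$period[right] +
      withSeed(deriveSeed(seed, "split-extra"), rnorm(sum(right), 0, 2))
    per$omega <- 2 * pi / per$period
  }

  NetworkScenario(
    geometry = geom, params = params, omega = per$omega,
    aVip = aVip, aAvp = aAvp,
    bridgeFactor = bridgeFactor,
    iVip = if (cocult) 0.01 else 0,
    iAvp = if (cocult && !antag) 0.01 else 0,
    phi = if (cocult) 11 else 0,
    antagonist = antag,
    vipReceptor = !tko,
    duration = duration,
    burnin = if (cocult) 48 else 24,
    initPhaseSd = if (wt || split) 0.5 else NA_real_,
    seed = seed, name = name, ...)
}
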