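#' Construct single-cell oscillator parameters
#'
#' @param alpha limit-cycle amplitude (signal units, > 0).
#' @param omega angular frequency (rad/h, > 0); \code{period} may be given
#'   instead.
#' @param damping relaxation rate lambda (1/h, > 0).
#' @param dR radial noise intensity (signal units^2/h, >= 0).
#' @param dPhi phase noise intensity (rad^2/h, >= 0).
#' @param period convenience alternative to \code{omega}: intrinsic period
#'   in hours.
#' @return An [OscillatorParams-class] object.
#' @examples
#' p <- OscillatorParams(alpha = 1, period = 24, damping = 0.05,
#'                       dR = 0.0045, dPhi = 0.005)
#' computeCV(p)
#' @export
OscillatorParams <- function(alpha = 1, omega = 2 * pi / 24, damping = 0.05,
                             dR = 0, dPhi = 0, period = NULL) {
  if (!is.null(period)) omega <- 2 * pi / period
  new("OscillatorParams", alpha = alpha, omega = omega, damping = damping,
      dR = dR, dPhi = dPhi)
}

#' Reference single-cell parameter sets
#'
#' Anchor parameter sets for the two dispersed-cell populations the network
#' scenarios draw from. The "wild-type fit" describes a self-sustained
#' oscillator (CV well below 1, slow phase diffusion); the "dko fit"
#' describes the weakly rhythmic, noise-dominated cells of Cry1/Cry2
#' double-knockout cultures: a small-amplitude cycle close to the Hopf
#' bifurcation, CV = 1.5 (damped by the CV criterion) and fast phase
#' diffusion. Amplitudes are in arbitrary detrended-signal units with the
#' wild-type cycle as the unit.
#'
#' The "dko-rhythmic fit" represents the rhythmic minority of
#' double-knockout slices (the splitting preparations): intermediate
#' amplitude and noise, CV below 1, slow enough phase diffusion for
#' within-lobe synchronization near the critical coupling border.
#'
#' @param name "wild-type fit", "dko fit", or "dko-rhythmic fit".
#' @return An [OscillatorParams-class].
#' @export
oscillatorPreset <- function(name = c("wild-type fit", "dko fit",
                                      "dko-rhythmic fit")) {
  name <- match.arg(name)
  switch(name,
    "wild-type fit" = OscillatorParams(
      alpha = 1, period = 24, damping = 0.05, dR = 0.0045, dPhi = 0.005),
    "dko fit" = OscillatorParams(
      alpha = 0.008, period = 24, damping = 1093.75, dR = 1.008e-5,
      dPhi = 0.45),
    "dko-rhythmic fit" = OscillatorParams(
      alpha = 0.3, period = 24, damping = 0.5556, dR = 2.88e-3,
      dPhi = 0.02)
  )
}

#' @rdname OscillatorParams-class
#' @export
setMethod("alpha", "OscillatorParams", function(object) object@alpha)

#' @rdname OscillatorParams-class
#' @export
setMethod("omega", "OscillatorParams", function(object) object@omega)

#' @rdname OscillatorParams-class
#' @export
setMethod("damping", "OscillatorParams", function(object) object@damping)

#' @rdname OscillatorParams-class
#' @export
setMethod("noiseRadial", "OscillatorParams", function(object) object@dR)

#' @rdname OscillatorParams-class
#' @export
setMethod("noisePhase", "OscillatorParams", function(object) object@dPhi)

#' @rdname OscillatorParams-class
#' @export
setMethod("intrinsicPeriod", "OscillatorParams",
  function(object) 2 * pi / object@omega)

setMethod("show", "OscillatorParams", function(object) {
  cv <- computeCV(object)
  cat("OscillatorParams\n")
  cat(sprintf("  alpha: %.4g  period: %.3f h  damping: %.4g /h\n",
              object@alpha, intrinsicPeriod(object), object@damping))
  cat(sprintf("  D_r: %.4g  D_phi: %.4g  CV: %.3g (%s)\n",
              object@dR, object@dPhi, cv$cv, cv$label))
})

# Radial relaxation rate of small deviations from the limit cycle under a
# given convention. "linearized" is the exact linearization of
# dr/dt = -lambda r^2 (r - alpha) about r = alpha.
radialRelaxationRate <- function(params,
                                 rate = c("linearized", "lambda-alpha", "lambda")) {
  rate <- match.arg(rate)
  switch(rate,
    "linearized"   = params@damping * params@alpha^2,
    "lambda-alpha" = params@damping * params@alpha,
    "lambda"       = params@damping
  )
}

#' @describeIn computeCV Stationary amplitude-fluctuation s.d. relative to
#'   the limit-cycle amplitude. The radial deviation behaves as an
#'   Ornstein-Uhlenbeck process with relaxation rate gamma, so the
#'   stationary s.d. is \code{sqrt(dR / gamma)} and
#'   \code{cv = sqrt(dR / gamma) / alpha}. The default convention
#'   \code{rate = "linearized"} uses \eqn{\gamma = \lambda \alpha^2}, the
#'   exact linearization of the simulated radial dynamics; the
#'   alternatives \eqn{\lambda\alpha} and \eqn{\lambda} are provided for
#'   comparison (all coincide at \eqn{\alpha = 1}).
#' @param rate which relaxation-rate convention to use; see Details.
#' @export
setMethod("computeCV", "OscillatorParams",
  function(params, rate = c("linearized", "lambda-alpha", "lambda")) {
    if (params@damping <= 0)
      stop("stationary amplitude variance undefined: damping must be > 0")
    gamma <- radialRelaxationRate(params, rate)
    cv <- sqrt(params@dR / gamma) / params@alpha
    list(cv = cv, label = if (cv < 1) "self-sustained" else "damped")
  })
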