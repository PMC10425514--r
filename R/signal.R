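#' Construct a Look-Locker protocol
#'
#' Defaults reproduce the 3T scanner protocol the pipeline targets: first
#' inversion time 19.6 ms, 12 phases spaced 400.3 ms, total cycle 4815 ms.
#' The readout excitation angle is not part of the printed protocol; the 8
#' degree default is an explicit assumption (the value printed for the
#' accompanying 3D T1-weighted scan) and should be overridden when the true
#' angle is known.
#'
#' @param tiMinMs first inversion time (ms).
#' @param phaseIntervalMs spacing between phases (ms).
#' @param nPhases number of readout phases.
#' @param cycleDurationMs total cycle duration (ms; metadata only — the
#'   printed 4815 ms is shorter than 12 full intervals and is deliberately
#'   not reconciled against the schedule).
#' @param excitationAngleDeg readout flip angle in degrees, in (0, 90).
#' @return an [LLProtocol-class] object.
#' @examples
#' tiSchedule(llProtocol())
#' @export
llProtocol <- function(tiMinMs = 19.6, phaseIntervalMs = 400.3, nPhases = 12L,
                       cycleDurationMs = 4815, excitationAngleDeg = 8) {
  new("LLProtocol", tiMinMs = tiMinMs, phaseIntervalMs = phaseIntervalMs,
      nPhases = as.integer(nPhases), cycleDurationMs = cycleDurationMs,
      excitationAngleDeg = excitationAngleDeg)
}

#' Inversion-time schedule of a protocol
#'
#' @param protocol an [LLProtocol-class].
#' @return numeric vector `tiMin + k * phaseInterval`, k = 0 .. nPhases-1 (ms).
#' @export
setGeneric("tiSchedule", function(protocol) standardGeneric("tiSchedule"))

#' @rdname tiSchedule
#' @export
setMethod("tiSchedule", "LLProtocol", function(protocol) {
  protocol@tiMinMs + protocol@phaseIntervalMs * (seq_len(protocol@nPhases) - 1)
})

#' Signed three-parameter inversion-recovery model
#'
#' \eqn{S(TI) = A - B e^{-TI/T1^*}}: the signed longitudinal signal during an
#' inversion recovery sampled with a Look-Locker readout, with the apparent
#' relaxation time T1* and the asymptote A and amplitude B treated as free
#' parameters (B absorbs imperfect inversion).
#'
#' @param tiMs inversion time(s) in ms.
#' @param A asymptote.
#' @param B recovery amplitude.
#' @param t1StarMs apparent relaxation time in ms (> 0).
#' @return signed signal, same length as `tiMs`.
#' @examples
#' signedModel(500 * log(2), A = 1, B = 2, t1StarMs = 500)  # zero crossing
#' @export
signedModel <- function(tiMs, A, B, t1StarMs) {
  if (any(t1StarMs <= 0)) stop("t1StarMs must be > 0")
  A - B * exp(-tiMs / t1StarMs)
}

#' Apparent relaxation time under a Look-Locker readout
#'
#' Repeated small-flip-angle readout pulses every phase interval accelerate
#' the observed recovery: \eqn{1/T1^* = 1/T1 - \ln(\cos\alpha)/\tau} with
#' \eqn{\tau} the phase interval, so T1* < T1 for any positive angle.
#'
#' @param t1Ms true T1 in ms (> 0).
#' @param protocol an [LLProtocol-class] supplying the flip angle and phase
#'   interval.
#' @return apparent T1* in ms.
#' @seealso [correctApparentT1()] for the inverse mapping used after fitting.
#' @export
apparentT1 <- function(t1Ms, protocol) {
  if (any(t1Ms <= 0)) stop("t1Ms must be > 0")
  a <- protocol@excitationAngleDeg * pi / 180
  1 / (1 / t1Ms - log(cos(a)) / protocol@phaseIntervalMs)
}

#' Look-Locker correction of a fitted apparent T1
#'
#' Inverts [apparentT1()]: \eqn{1/T1 = 1/T1^* + \ln(\cos\alpha)/\tau}. For
#' very long apparent times the corrected rate can become non-positive; the
#' (unphysical) negative result is returned as-is and left to the validity
#' clamp. The alternative correction `T1 = T1* (B/A - 1)` is available for
#' cross-checks via [fitCurve()]'s `correction` argument.
#'
#' @param t1StarMs fitted apparent T1 in ms.
#' @param protocol an [LLProtocol-class].
#' @return corrected T1 in ms.
#' @export
correctApparentT1 <- function(t1StarMs, protocol) {
  a <- protocol@excitationAngleDeg * pi / 180
  1 / (1 / t1StarMs + log(cos(a)) / protocol@phaseIntervalMs)
}

#' Simulate a magnitude Look-Locker curve
#'
#' Builds the signed recovery via [signedModel()] with
#' \eqn{A = m_0}, \eqn{B = m_0 (1 + \epsilon)} (inversion efficiency
#' \eqn{\epsilon \in (0, 1]}) and T1* from [apparentT1()], then takes the
#' magnitude and applies noise: `"gaussian_magnitude"` adds Gaussian noise to
#' the magnitude (floored at 0), `"rician"` applies proper two-channel Rician
#' noise. `noiseSd` is expressed as a fraction of `m0`.
#'
#' @param t1Ms ground-truth T1 in ms.
#' @param protocol an [LLProtocol-class].
#' @param m0 equilibrium signal (> 0).
#' @param inversionEfficiency inversion efficiency in (0, 1]; 1 = perfect.
#' @param noiseSd noise SD as a fraction of `m0` (>= 0).
#' @param noiseModel `"gaussian_magnitude"` or `"rician"`.
#' @param seed integer seed (ignored when `noiseSd = 0`).
#' @return a [SignalCurve-class]; `trueParams` records A, B, T1* and T1.
#' @export
simulateCurve <- function(t1Ms, protocol = llProtocol(), m0 = 1,
                          inversionEfficiency = 1, noiseSd = 0,
                          noiseModel = c("gaussian_magnitude", "rician"),
                          seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  if (t1Ms <= 0) stop("t1Ms must be > 0")
  if (m0 <= 0) stop("m0 must be > 0")
  if (inversionEfficiency <= 0 || inversionEfficiency > 1)
    stop("inversionEfficiency must be in (0, 1]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  ti <- tiSchedule(protocol)
  t1Star <- apparentT1(t1Ms, protocol)
  A <- m0
  B <- m0 * (1 + inversionEfficiency)
  signed <- signedModel(ti, A, B, t1Star)
  mag <- applyMagnitudeNoise(signed, noiseSd * m0, noiseModel, seed)
  new("SignalCurve", tiMs = ti, magnitude = mag,
      trueParams = list(A = A, B = B, t1StarMs = t1Star, t1Ms = t1Ms))
}

applyMagnitudeNoise <- function(signed, sdAbs, noiseModel, seed) {
  if (sdAbs == 0) return(abs(signed))
  withSeed(seed, {
    if (noiseModel == "gaussian_magnitude") {
      mag <- pmax(abs(signed) + stats::rnorm(length(signed), 0, sdAbs), 0)
    } else {
      mag <- sqrt((signed + stats::rnorm(length(signed), 0, sdAbs))^2 +
                    stats::rnorm(length(signed), 0, sdAbs)^2)
    }
  })
  mag
}

#' Simulate a 4-D Look-Locker acquisition of a phantom
#'
#' Vectorizes the curve simulator over voxels: foreground voxels follow their
#' ground-truth T1, background voxels contain pure noise (the noise floor of
#' a magnitude image). Deterministic given the seed.
#'
#' @param phantom a [Phantom-class].
#' @param protocol an [LLProtocol-class].
#' @param noiseSd noise SD as a fraction of `m0`.
#' @param seed integer seed.
#' @param m0,inversionEfficiency,noiseModel as in [simulateCurve()].
#' @return an [LLAcquisition-class].
#' @export
simulateVolume <- function(phantom, protocol = llProtocol(), noiseSd = 0,
                           seed = 1L, m0 = 1, inversionEfficiency = 1,
                           noiseModel = c("gaussian_magnitude", "rician")) {
  noiseModel <- match.arg(noiseModel)
  ti <- tiSchedule(protocol)
  shp <- dim(phantom@t1Ms)
  nvox <- prod(shp)
  t1 <- as.vector(phantom@t1Ms)
  fg <- t1 > 0
  signed <- matrix(0, nvox, protocol@nPhases)
  if (any(fg)) {
    t1Star <- apparentT1(t1[fg], protocol)
    A <- m0
    B <- m0 * (1 + inversionEfficiency)
    for (k in seq_along(ti))
      signed[fg, k] <- A - B * exp(-ti[k] / t1Star)
  }
  mag <- applyMagnitudeNoise(signed, noiseSd * m0, noiseModel, seed)
  new("LLAcquisition",
      signal = array(mag, dim = c(shp, protocol@nPhases)),
      protocol = protocol, affine = phantom@affine)
}
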