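#' @import methods
NULL

#' Look-Locker acquisition protocol
#'
#' Timing and excitation parameters of a 3D inversion-recovery Look-Locker
#' readout: the first inversion time, the spacing between readout phases, the
#' number of phases sampled per inversion cycle, the total cycle duration and
#' the small readout flip angle that drives the apparent-T1 shortening.
#'
#' @slot tiMinMs first inversion time in ms.
#' @slot phaseIntervalMs spacing between successive inversion times in ms.
#' @slot nPhases number of readout phases per cycle.
#' @slot cycleDurationMs total inversion-cycle duration in ms (metadata; not
#'   used by the signal model).
#' @slot excitationAngleDeg readout excitation (flip) angle in degrees.
#'
#' @seealso [llProtocol()] for the user-facing constructor with the
#'   scanner-protocol defaults, [tiSchedule()], [apparentT1()].
#' @export
setClass("LLProtocol", representation(
  tiMinMs = "numeric",
  phaseIntervalMs = "numeric",
  nPhases = "integer",
  cycleDurationMs = "numeric",
  excitationAngleDeg = "numeric"
))

setValidity("LLProtocol", function(object) {
  msg <- character()
  if (length(object@tiMinMs) != 1 || !is.finite(object@tiMinMs) || object@tiMinMs <= 0)
    msg <- c(msg, "tiMinMs must be a single positive number")
  if (length(object@phaseIntervalMs) != 1 || !is.finite(object@phaseIntervalMs) ||
      object@phaseIntervalMs <= 0)
    msg <- c(msg, "phaseIntervalMs must be a single positive number")
  if (length(object@nPhases) != 1 || is.na(object@nPhases) || object@nPhases < 3L)
    msg <- c(msg, "nPhases must be >= 3")
  if (length(object@excitationAngleDeg) != 1 || !is.finite(object@excitationAngleDeg) ||
      object@excitationAngleDeg <= 0 || object@excitationAngleDeg >= 90)
    msg <- c(msg, "excitationAngleDeg must lie in (0, 90)")
  if (length(msg) == 0 &&
      object@tiMinMs + (object@nPhases - 1L) * object@phaseIntervalMs >
        object@cycleDurationMs)
    msg <- c(msg, "last inversion time exceeds cycleDurationMs")
  if (length(msg)) msg else TRUE
})

#' A single (possibly simulated) magnitude inversion-recovery curve
#'
#' @slot tiMs strictly increasing inversion-time schedule in ms.
#' @slot magnitude non-negative magnitude signal, one value per inversion time.
#' @slot trueParams for simulated curves, the generating parameters
#'   (list with elements `A`, `B`, `t1StarMs`, `t1Ms`); empty otherwise.
#' @export
setClass("SignalCurve", representation(
  tiMs = "numeric",
  magnitude = "numeric",
  trueParams = "list"
))

setValidity("SignalCurve", function(object) {
  msg <- character()
  if (length(object@tiMs) != length(object@magnitude))
    msg <- c(msg, "tiMs and magnitude must have equal length")
  if (length(object@tiMs) > 1 && any(diff(object@tiMs) <= 0))
    msg <- c(msg, "tiMs must be strictly increasing")
  if (any(object@magnitude < 0))
    msg <- c(msg, "magnitude must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Result of a three-parameter inversion-recovery fit on one voxel/curve
#'
#' Holds the fitted model \eqn{S(TI) = A - B e^{-TI/T1^*}} together with the
#' Look-Locker-corrected T1, the residual norm of the winning polarity
#' restoration, the chosen polarity index (number of leading magnitude samples
#' restored to negative sign) and a convergence flag.
#'
#' @slot A fitted asymptote.
#' @slot B fitted recovery amplitude.
#' @slot t1StarMs fitted apparent T1 in ms.
#' @slot t1Ms Look-Locker-corrected T1 in ms (may fall outside the plausible
#'   range; validity is decided downstream).
#' @slot residualNorm Euclidean norm of the residuals of the selected fit.
#' @slot polarityIndex number of leading samples negated before fitting.
#' @slot converged whether the nonlinear fit converged.
#' @export
setClass("FitResult", representation(
  A = "numeric",
  B = "numeric",
  t1StarMs = "numeric",
  t1Ms = "numeric",
  residualNorm = "numeric",
  polarityIndex = "integer",
  converged = "logical"
))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(object@residualNorm) == 1 && !is.na(object@residualNorm) &&
      object@residualNorm < 0)
    msg <- c(msg, "residualNorm must be >= 0")
  if (object@polarityIndex < 0L)
    msg <- c(msg, "polarityIndex must be >= 0")
  if (isTRUE(object@converged) && (is.na(object@t1StarMs) || object@t1StarMs <= 0))
    msg <- c(msg, "a converged fit must have t1StarMs > 0")
  if (length(msg)) msg else TRUE
})

#' Digital brain phantom
#'
#' A synthetic stand-in for a segmented brain: an integer label volume naming
#' the region of every voxel (0 = background), a ground-truth T1 volume in ms,
#' a 4x4 voxel-to-world affine (0-based voxel indices) and the region
#' dictionary the labels refer to.
#'
#' @slot labels 3-D integer array of region labels.
#' @slot t1Ms 3-D numeric array of ground-truth T1 (ms); positive wherever
#'   `labels > 0`, 0 in background.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot regions region dictionary, see [regionSpec()].
#' @slot subjectId subject identifier.
#' @slot session session label, `"Pre"` or `"Week4"`.
#' @slot trueTransform for misaligned phantoms, the 6-vector
#'   (3 rotations deg, 3 translations mm) that re-aligns this phantom to its
#'   source; `numeric(0)` otherwise. Used as ground truth in registration
#'   recovery tests.
#' @export
setClass("Phantom", representation(
  labels = "array",
  t1Ms = "array",
  affine = "matrix",
  regions = "data.frame",
  subjectId = "character",
  session = "character",
  trueTransform = "numeric"
))

setValidity("Phantom", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), dim(object@t1Ms)))
    msg <- c(msg, "labels and t1Ms must have identical shape")
  if (length(dim(object@labels)) != 3)
    msg <- c(msg, "volumes must be 3-D")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  lab <- unique(as.integer(object@labels))
  lab <- lab[lab != 0L]
  if (!all(lab %in% object@regions$label_id))
    msg <- c(msg, "every nonzero label must appear in the region dictionary")
  fg <- object@labels > 0L
  if (any(fg) && any(object@t1Ms[fg] <= 0))
    msg <- c(msg, "t1Ms must be positive wherever labels > 0")
  if (!object@session %in% c("Pre", "Week4"))
    msg <- c(msg, "session must be 'Pre' or 'Week4'")
  if (length(msg)) msg else TRUE
})

#' Gadolinium concentration field
#'
#' A voxelwise gadolinium concentration map (mmol/L) together with the
#' longitudinal relaxivity r1 linking concentration to the increase in the
#' relaxation rate 1/T1.
#'
#' @slot concentrationMM 3-D non-negative array of concentration in mmol/L.
#' @slot relaxivityR1 longitudinal relaxivity in L mmol^-1 s^-1.
#' @export
setClass("GadoliniumField", representation(
  concentrationMM = "array",
  relaxivityR1 = "numeric"
))

setValidity("GadoliniumField", function(object) {
  msg <- character()
  if (any(object@concentrationMM < 0))
    msg <- c(msg, "concentration must be non-negative everywhere")
  if (length(object@relaxivityR1) != 1 || object@relaxivityR1 <= 0)
    msg <- c(msg, "relaxivityR1 must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' 4-D Look-Locker magnitude acquisition
#'
#' @slot signal 4-D array (x, y, z, phase) of non-negative magnitude signal.
#' @slot protocol the [LLProtocol-class] the volume was acquired/simulated with.
#' @slot affine 4x4 voxel-to-world transform of the spatial grid.
#' @export
setClass("LLAcquisition", representation(
  signal = "array",
  protocol = "LLProtocol",
  affine = "matrix"
))

setValidity("LLAcquisition", function(object) {
  msg <- character()
  if (length(dim(object@signal)) != 4)
    msg <- c(msg, "signal must be 4-D")
  else if (dim(object@signal)[4] != object@protocol@nPhases)
    msg <- c(msg, "4th dimension must equal the protocol's nPhases")
  if (any(object@signal < 0))
    msg <- c(msg, "magnitude signal must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Voxelwise T1 map with validity mask
#'
#' Fitted T1 times in ms plus a mask flagging voxels whose fit converged and
#' whose T1 lies in the physically plausible interval (0, 10000) ms; values
#' outside that interval are treated as artifacts and excluded from all
#' region statistics rather than clipped.
#'
#' @slot t1Ms 3-D numeric array of fitted T1 (ms); NA where unfitted.
#' @slot valid 3-D logical array; TRUE only where `0 < t1Ms < 10000` and the
#'   fit converged.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot protocol acquisition protocol used for the fit.
#' @export
setClass("T1Map", representation(
  t1Ms = "array",
  valid = "array",
  affine = "matrix",
  protocol = "LLProtocol"
))

setValidity("T1Map", function(object) {
  msg <- character()
  if (!identical(dim(object@t1Ms), dim(object@valid)))
    msg <- c(msg, "t1Ms and valid must have identical shape")
  v <- object@valid & !is.na(object@t1Ms)
  ok <- object@t1Ms[v]
  if (any(object@valid & is.na(object@t1Ms)))
    msg <- c(msg, "valid voxels must carry a T1 value")
  if (length(ok) && (any(ok <= 0) || any(ok >= 10000)))
    msg <- c(msg, "valid voxels must satisfy 0 < t1Ms < 10000")
  if (length(msg)) msg else TRUE
})

#' Rigid (6 degree-of-freedom) spatial transform
#'
#' Rotations are extrinsic Euler angles in degrees applied in x, y, z order
#' about a stated world-space centre, followed by a translation in mm.
#'
#' @slot rotationsDeg 3 rotations in degrees.
#' @slot translationsMm 3 translations in mm.
#' @export
setClass("RigidTransform", representation(
  rotationsDeg = "numeric",
  translationsMm = "numeric"
))

setValidity("RigidTransform", function(object) {
  msg <- character()
  if (length(object@rotationsDeg) != 3 || any(!is.finite(object@rotationsDeg)))
    msg <- c(msg, "rotationsDeg must be 3 finite numbers")
  if (length(object@translationsMm) != 3 || any(!is.finite(object@translationsMm)))
    msg <- c(msg, "translationsMm must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' Plasma concentration model for an intravenously injected contrast agent
#'
#' Dose-scaled biexponential plasma decay (the classic two-compartment
#' clearance description), optionally max-blended with an early gamma-variate
#' bolus peak. With amplitudes in kg/L and the dose in mmol/kg the curve is in
#' mmol/L (mM).
#'
#' @slot doseMmolPerKg injected dose in mmol per kg body weight.
#' @slot amplitudes two positive biexponential amplitudes (kg/L).
#' @slot decayRates two positive, distinct decay rates (1/min).
#' @slot bolus optional early-bolus description: a list with `peakMM`,
#'   `peakTimeMin` and `widthMin`, or an empty list for no bolus.
#' @export
setClass("PlasmaModel", representation(
  doseMmolPerKg = "numeric",
  amplitudes = "numeric",
  decayRates = "numeric",
  bolus = "list"
))

setValidity("PlasmaModel", function(object) {
  msg <- character()
  if (length(object@doseMmolPerKg) != 1 || object@doseMmolPerKg <= 0)
    msg <- c(msg, "doseMmolPerKg must be a single positive number")
  if (length(object@amplitudes) != 2 || any(object@amplitudes <= 0))
    msg <- c(msg, "amplitudes must be 2 positive numbers")
  if (length(object@decayRates) != 2 || any(object@decayRates <= 0))
    msg <- c(msg, "decayRates must be 2 positive numbers")
  if (length(object@decayRates) == 2 &&
      object@decayRates[1] == object@decayRates[2])
    msg <- c(msg, "decayRates must be distinct")
  if (length(object@bolus) &&
      !all(c("peakMM", "peakTimeMin", "widthMin") %in% names(object@bolus)))
    msg <- c(msg, "bolus must have peakMM, peakTimeMin, widthMin")
  if (length(msg)) msg else TRUE
})
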