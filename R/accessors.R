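#' @rdname accessors
#' @name accessors
#' @title Accessors for the imaging containers
#'
#' @description Slot accessors for the S4 containers: use these rather than
#' `@` access.
#'
#' @param x an object of one of the package's classes.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("t1Values", function(x) standardGeneric("t1Values"))
#' @rdname accessors
#' @export
setMethod("t1Values", "T1Map", function(x) x@t1Ms)
#' @rdname accessors
#' @export
setMethod("t1Values", "Phantom", function(x) x@t1Ms)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "T1Map", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setMethod("labelVolume", "Phantom", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setMethod("regionTable", "Phantom", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("voxelToWorld", function(x) standardGeneric("voxelToWorld"))
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "Phantom", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "T1Map", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelToWorld", "LLAcquisition", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("acquisitionProtocol", function(x) standardGeneric("acquisitionProtocol"))
#' @rdname accessors
#' @export
setMethod("acquisitionProtocol", "LLAcquisition", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("acquisitionProtocol", "T1Map", function(x) x@protocol)

#' @rdname accessors
#' @export
setGeneric("signalArray", function(x) standardGeneric("signalArray"))
#' @rdname accessors
#' @export
setMethod("signalArray", "LLAcquisition", function(x) x@signal)

#' @rdname accessors
#' @export
setGeneric("trueTransform", function(x) standardGeneric("trueTransform"))
#' @rdname accessors
#' @export
setMethod("trueTransform", "Phantom", function(x) x@trueTransform)

#' @rdname accessors
#' @export
setGeneric("transformParams", function(x) standardGeneric("transformParams"))
#' @rdname accessors
#' @export
setMethod("transformParams", "RigidTransform",
          function(x) c(x@rotationsDeg, x@translationsMm))

setMethod("show", "LLProtocol", function(object) {
  cat("LLProtocol:", object@nPhases, "phases, TI", object@tiMinMs, "+ k *",
      object@phaseIntervalMs, "ms, cycle", object@cycleDurationMs,
      "ms, flip", object@excitationAngleDeg, "deg\n")
})

setMethod("show", "SignalCurve", function(object) {
  cat("SignalCurve with", length(object@tiMs), "inversion times (",
      min(object@tiMs), "-", max(object@tiMs), "ms )\n")
  if (length(object@trueParams))
    cat("  simulated from T1 =", object@trueParams$t1Ms, "ms\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: T1 = %.1f ms (T1* = %.1f), polarity index %d, residual %.3g, %s\n",
    object@t1Ms, object@t1StarMs, object@polarityIndex, object@residualNorm,
    if (isTRUE(object@converged)) "converged" else "NOT converged"))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@labels)
  cat("Phantom", object@subjectId, "/", object@session, ":",
      paste(d, collapse = " x "), "voxels,",
      nrow(object@regions), "regions,",
      sum(object@labels > 0), "foreground voxels\n")
  if (length(object@trueTransform))
    cat("  misaligned; true realigning transform:",
        paste(signif(object@trueTransform, 3), collapse = ", "), "\n")
})

setMethod("show", "T1Map", function(object) {
  d <- dim(object@t1Ms)
  cat("T1Map:", paste(d, collapse = " x "), "voxels;",
      sum(object@valid), "valid\n")
})

setMethod("show", "LLAcquisition", function(object) {
  d <- dim(object@signal)
  cat("LLAcquisition:", paste(d[1:3], collapse = " x "), "voxels x",
      d[4], "phases\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: rot(deg) =",
      paste(signif(object@rotationsDeg, 4), collapse = ", "),
      "; trans(mm) =",
      paste(signif(object@translationsMm, 4), collapse = ", "), "\n")
})

setMethod("show", "PlasmaModel", function(object) {
  cat("PlasmaModel: dose", object@doseMmolPerKg, "mmol/kg; amplitudes",
      paste(object@amplitudes, collapse = ", "), "kg/L; rates",
      paste(object@decayRates, collapse = ", "), "/min;",
      if (length(object@bolus)) "with early bolus" else "no early bolus", "\n")
})
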