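#' @importFrom RNifti readNifti writeNifti asNifti
#' @importFrom jsonlite write_json read_json
NULL

niftiWithAffine <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

readAffine <- function(img) {
  m <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(m) <- list(dim = dim(m))
  m
}

#' Write / read a phantom as NIfTI + JSON sidecar
#'
#' The label volume is written as an integer NIfTI, the ground-truth T1 as a
#' float NIfTI, and the region dictionary, metadata and (if present) the
#' true misalignment transform as a JSON sidecar.
#'
#' @param phantom a [Phantom-class].
#' @param prefix output path prefix; writes `<prefix>_labels.nii.gz`,
#'   `<prefix>_t1.nii.gz`, `<prefix>.json`.
#' @return (`writePhantom`) the three paths, invisibly;
#'   (`readPhantom`) the reconstructed [Phantom-class].
#' @export
writePhantom <- function(phantom, prefix) {
  pl <- paste0(prefix, "_labels.nii.gz")
  pt <- paste0(prefix, "_t1.nii.gz")
  pj <- paste0(prefix, ".json")
  lab <- phantom@labels
  storage.mode(lab) <- "integer"
  RNifti::writeNifti(niftiWithAffine(lab, phantom@affine), pl,
                     datatype = "int32")
  RNifti::writeNifti(niftiWithAffine(phantom@t1Ms, phantom@affine), pt,
                     datatype = "double")
  jsonlite::write_json(
    list(subject_id = phantom@subjectId, session = phantom@session,
         regions = phantom@regions,
         true_transform = phantom@trueTransform),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(labels = pl, t1 = pt, sidecar = pj))
}

#' @rdname writePhantom
#' @export
readPhantom <- function(prefix) {
  lab <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  t1 <- RNifti::readNifti(paste0(prefix, "_t1.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  affine <- readAffine(lab)
  labArr <- array(as.integer(round(lab)), dim = dim(lab))
  regions <- as.data.frame(meta$regions)
  new("Phantom", labels = labArr, t1Ms = array(as.numeric(t1), dim = dim(t1)),
      affine = affine, regions = regions,
      subjectId = meta$subject_id, session = meta$session,
      trueTransform = as.numeric(meta$true_transform))
}

#' Write / read a 4-D Look-Locker acquisition
#'
#' The magnitude signal goes to a 4-D NIfTI and the protocol (inversion-time
#' schedule included) to a JSON sidecar.
#'
#' @param acq an [LLAcquisition-class].
#' @param prefix path prefix; writes `<prefix>.nii.gz` + `<prefix>.json`.
#' @return (`writeAcquisition`) paths invisibly; (`readAcquisition`) the
#'   [LLAcquisition-class].
#' @export
writeAcquisition <- function(acq, prefix) {
  pn <- paste0(prefix, ".nii.gz")
  pj <- paste0(prefix, ".json")
  RNifti::writeNifti(niftiWithAffine(acq@signal, acq@affine), pn,
                     datatype = "double")
  p <- acq@protocol
  jsonlite::write_json(
    list(ti_min_ms = p@tiMinMs, phase_interval_ms = p@phaseIntervalMs,
         n_phases = p@nPhases, cycle_duration_ms = p@cycleDurationMs,
         excitation_angle_deg = p@excitationAngleDeg,
         ti_schedule_ms = tiSchedule(p)),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(signal = pn, sidecar = pj))
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  proto <- llProtocol(meta$ti_min_ms, meta$phase_interval_ms, meta$n_phases,
                      meta$cycle_duration_ms, meta$excitation_angle_deg)
  new("LLAcquisition", signal = array(as.numeric(img), dim = dim(img)),
      protocol = proto, affine = readAffine(img))
}

#' Write / read a T1 map (value volume + validity mask)
#'
#' @param t1Map a [T1Map-class].
#' @param prefix path prefix; writes `<prefix>_t1map.nii.gz`,
#'   `<prefix>_valid.nii.gz`, `<prefix>.json`.
#' @return (`writeT1Map`) paths invisibly; (`readT1Map`) the [T1Map-class].
#' @export
writeT1Map <- function(t1Map, prefix) {
  pt <- paste0(prefix, "_t1map.nii.gz")
  pv <- paste0(prefix, "_valid.nii.gz")
  pj <- paste0(prefix, ".json")
  t1 <- t1Map@t1Ms
  t1[is.na(t1)] <- -1  # NIfTI has no NA; invalid voxels are masked anyway
  RNifti::writeNifti(niftiWithAffine(t1, t1Map@affine), pt,
                     datatype = "double")
  v <- array(as.integer(t1Map@valid), dim = dim(t1Map@valid))
  RNifti::writeNifti(niftiWithAffine(v, t1Map@affine), pv, datatype = "uint8")
  p <- t1Map@protocol
  jsonlite::write_json(
    list(ti_min_ms = p@tiMinMs, phase_interval_ms = p@phaseIntervalMs,
         n_phases = p@nPhases, cycle_duration_ms = p@cycleDurationMs,
         excitation_angle_deg = p@excitationAngleDeg),
    pj, auto_unbox = TRUE, digits = NA)
  invisible(c(t1 = pt, valid = pv, sidecar = pj))
}

#' @rdname writeT1Map
#' @export
readT1Map <- function(prefix) {
  t1 <- RNifti::readNifti(paste0(prefix, "_t1map.nii.gz"))
  v <- RNifti::readNifti(paste0(prefix, "_valid.nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  proto <- llProtocol(meta$ti_min_ms, meta$phase_interval_ms, meta$n_phases,
                      meta$cycle_duration_ms, meta$excitation_angle_deg)
  t1Arr <- array(as.numeric(t1), dim = dim(t1))
  valid <- array(as.numeric(v) > 0, dim = dim(v))
  t1Arr[!valid & t1Arr < 0] <- NA_real_
  new("T1Map", t1Ms = t1Arr, valid = valid, affine = readAffine(t1),
      protocol = proto)
}

#' Write / read a rigid transform as JSON
#'
#' Stored as rotations in degrees and translations in mm, world coordinates.
#'
#' @param transform a [RigidTransform-class].
#' @param path JSON file path.
#' @return (`writeTransform`) path invisibly; (`readTransform`) the
#'   [RigidTransform-class].
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(rotations_deg = transform@rotationsDeg,
         translations_mm = transform@translationsMm),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(m$rotations_deg, m$translations_mm)
}

#' Write a tab-separated report table
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @param ... passed to [utils::read.delim()].
#' @export
readTsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
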