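#' Generate a digital brain phantom
#'
#' Builds a 3-D label volume plus a ground-truth T1 volume for a set of
#' regions. Geometry `"nested_spheres"` places the regions as concentric
#' ellipsoidal shells in world coordinates (first region outermost — with the
#' default dictionary a cortical shell enclosing a white-matter shell with
#' basal-ganglia and pallidum cores); `"slab_stack"` stacks the regions as
#' axial slabs. Voxel T1 is the region mean plus Gaussian within-region noise
#' truncated at 1 ms. Anatomical realism is not attempted: the phantom exists
#' to exercise aggregation, registration and fitting.
#'
#' @param regions a `region_spec` data.frame ([regionSpec()],
#'   [defaultRegionTable()]). Its `t1_mean_ms` column is used as-is; draw
#'   subject-level means first with [sampleSubjectRegions()] if between-subject
#'   variation is wanted.
#' @param shape integer 3-vector of voxel dimensions, each >= 16.
#' @param geometry `"nested_spheres"` or `"slab_stack"`.
#' @param seed integer seed for the within-region noise.
#' @param voxelSizeMm voxel edge lengths in mm; the default matches a
#'   1.39 x 1.39 mm in-plane reconstruction with 4 mm slices.
#' @param subjectId,session metadata stored on the phantom.
#' @param shadingAmp amplitude (fractional, e.g. 0.05) of a smooth
#'   world-coordinate T1 modulation emulating the gentle spatial variation of
#'   real tissue (cortical-depth gradients, receive-field shading). Default 0
#'   keeps region means exactly at their dictionary values; switch it on for
#'   registration experiments, where the smooth structure anchors rotation.
#' @param shadingWavelengthsMm the three modulation wavelengths in mm.
#' @param pose optional rigid motion of the object (6-vector: 3 rotations
#'   deg, 3 translations mm, about the volume centre in world coordinates).
#'   The analytic geometry and shading are evaluated at the moved pose, as
#'   if the head had moved and been re-scanned — unlike [misalignPhantom()],
#'   no resampling is involved, so the second session is as crisp as the
#'   first. Stored as `trueTransform` (the transform registration should
#'   recover against the unmoved phantom). `nested_spheres` only.
#' @param psfBlurVox sigma (in voxels) of a Gaussian applied to the T1
#'   volume, emulating the acquisition point-spread function. Default 0
#'   (crisp regions, exact means); switch on (around 0.7) to band-limit the
#'   scene, as real images are — resampling a non-band-limited volume is
#'   what makes sharp-edged phantoms misbehave under registration. Labels
#'   stay crisp.
#' @return a [Phantom-class] object.
#' @examples
#' ph <- makePhantom(defaultRegionTable("phantom"), shape = c(24, 24, 16), seed = 1)
#' table(labelVolume(ph))
#' @export
makePhantom <- function(regions, shape = c(48, 48, 24),
                        geometry = c("nested_spheres", "slab_stack"),
                        seed = 1L,
                        voxelSizeMm = c(1.39, 1.39, 4),
                        subjectId = "sim", session = "Pre",
                        shadingAmp = 0,
                        shadingWavelengthsMm = c(23, 31, 41),
                        pose = NULL,
                        psfBlurVox = 0) {
  geometry <- match.arg(geometry)
  validateRegions(regions)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16L))
    stop("shape must be 3 integers, each >= 16")
  affine <- diag(c(voxelSizeMm, 1))
  Minv <- NULL
  if (!is.null(pose) && any(pose != 0)) {
    if (geometry != "nested_spheres")
      stop("pose is supported for the nested_spheres geometry only")
    p <- asRigidParams(pose)
    Minv <- solve(rigidMatrix(p, worldCentre(shape, affine)))
  }
  labels <- phantomLabels(regions, shape, geometry, voxelSizeMm, Minv)
  counts <- tabulate(labels[labels > 0L], nbins = max(regions$label_id))
  bad <- regions$label_id[counts[regions$label_id] < 50L]
  if (length(bad))
    stop("shape too small to host region(s): ",
         paste(regions$name[match(bad, regions$label_id)], collapse = ", "),
         " (< 50 voxels)")
  t1 <- array(0, dim = shape)
  withSeed(seed, {
    for (i in seq_len(nrow(regions))) {
      idx <- which(labels == regions$label_id[i])
      t1[idx] <- pmax(
        regions$t1_mean_ms[i] +
          stats::rnorm(length(idx), 0, regions$t1_within_region_sd_ms[i]),
        1)
    }
  })
  if (shadingAmp > 0) {
    fg <- which(labels > 0L)
    sub <- arrayInd(fg, shape) - 1L
    w <- cbind(sub, 1) %*% t(affine)
    if (!is.null(Minv)) w <- w %*% t(Minv)  # shading moves with the tissue
    mod <- 1 + shadingAmp / 3 *
      (sin(2 * pi * w[, 1] / shadingWavelengthsMm[1]) +
         sin(2 * pi * w[, 2] / shadingWavelengthsMm[2]) +
         sin(2 * pi * w[, 3] / shadingWavelengthsMm[3]))
    t1[fg] <- pmax(t1[fg] * mod, 1)
  }
  if (psfBlurVox > 0) {
    t1 <- gaussSmooth3d(t1, psfBlurVox)
    t1[labels > 0L] <- pmax(t1[labels > 0L], 1)
    t1[labels == 0L & t1 < 1e-6] <- 0
  }
  new("Phantom", labels = labels, t1Ms = t1, affine = affine,
      regions = as.data.frame(regions), subjectId = subjectId,
      session = session,
      trueTransform = if (is.null(Minv)) numeric(0) else asRigidParams(pose))
}

# Label geometry: world-coordinate concentric ellipsoids or axial slabs.
# `Minv` (optional 4x4) maps evaluation points back into the unmoved scene,
# implementing a rigid pose without any resampling.
phantomLabels <- function(regions, shape, geometry, voxelSizeMm,
                          Minv = NULL) {
  n <- nrow(regions)
  labels <- array(0L, dim = shape)
  if (geometry == "nested_spheres") {
    # normalized coordinates of voxel centres relative to the volume centre
    half <- (shape - 1) / 2
    idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1,
                                 y = seq_len(shape[2]) - 1,
                                 z = seq_len(shape[3]) - 1))
    W <- t(t(idx) * voxelSizeMm)
    if (!is.null(Minv))
      W <- cbind(W, 1) %*% t(Minv[1:3, , drop = FALSE])
    centreW <- half * voxelSizeMm
    extW <- half * voxelSizeMm
    G <- data.frame(x = (W[, 1] - centreW[1]) / extW[1],
                    y = (W[, 2] - centreW[2]) / extW[2],
                    z = (W[, 3] - centreW[3]) / extW[3])
    # three distinct half-axes, as in a real head (and so that every
    # rotation axis is anchored by the smooth geometry during registration)
    r <- sqrt(G$x^2 + (G$y / 0.82)^2 + (G$z / 0.9)^2)
    if (n == 1L) {
      labels[r <= 0.9] <- regions$label_id[1]
    } else {
      # outer shell (cortex-like) enclosing a core (white-matter-like);
      # remaining regions become off-centre blobs embedded in the core
      labels[r <= 0.9 & r > 0.7] <- regions$label_id[1]
      labels[r <= 0.7] <- regions$label_id[2]
      nb <- n - 2L
      for (k in seq_len(max(nb, 0L))) {
        th <- 2 * pi * k / max(nb, 1L) + 0.5
        ctr <- c(0.33 * cos(th), 0.27 * sin(th), 0.18 * (-1)^k)
        d <- sqrt((G$x - ctr[1])^2 + ((G$y - ctr[2]) / 0.82)^2 +
                    (G$z - ctr[3])^2)
        labels[d <= 0.3] <- regions$label_id[k + 2L]
      }
    }
  } else {
    margin <- pmax(2L, shape %/% 8L)
    z0 <- margin[3] + 1L
    z1 <- shape[3] - margin[3]
    cuts <- round(seq(z0 - 1L, z1, length.out = n + 1L))
    for (i in seq_len(n)) {
      zsel <- (cuts[i] + 1L):cuts[i + 1L]
      labels[(margin[1] + 1L):(shape[1] - margin[1]),
             (margin[2] + 1L):(shape[2] - margin[2]),
             zsel] <- regions$label_id[i]
    }
  }
  labels
}

#' Shorten T1 according to a gadolinium concentration
#'
#' Applies relaxation-rate additivity 1/T1_post = 1/T1_pre + r1 * C, with T1
#' in seconds during the computation and C in mmol/L, so T1_post <= T1_pre
#' everywhere and T1 is unchanged where C = 0.
#'
#' @param t1Ms T1 before contrast, in ms (vector or array).
#' @param concentrationMM gadolinium concentration in mmol/L, same shape.
#' @param relaxivityR1 longitudinal relaxivity in L mmol^-1 s^-1.
#' @return shortened T1 in ms, same shape as `t1Ms`.
#' @examples
#' gadShortenT1(1000, 0.1, 4)  # 1/(1/1.0 + 0.4) s = 714.3 ms
#' @export
gadShortenT1 <- function(t1Ms, concentrationMM, relaxivityR1) {
  if (any(concentrationMM < 0)) stop("concentration must be non-negative")
  if (relaxivityR1 <= 0) stop("relaxivityR1 must be positive")
  t1s <- t1Ms / 1000
  out <- 1 / (1 / t1s + relaxivityR1 * concentrationMM) * 1000
  out[t1Ms <= 0] <- t1Ms[t1Ms <= 0]   # background stays untouched
  out
}

#' Apply a gadolinium field to a phantom
#'
#' Returns a new phantom whose ground-truth T1 is shortened voxelwise by the
#' concentration field via [gadShortenT1()]; labels, affine and metadata are
#' preserved.
#'
#' @param phantom a [Phantom-class].
#' @param field a [GadoliniumField-class] whose concentration volume matches
#'   the phantom shape.
#' @return a new [Phantom-class].
#' @export
setGeneric("applyGadolinium", function(phantom, field)
  standardGeneric("applyGadolinium"))

#' @rdname applyGadolinium
#' @export
setMethod("applyGadolinium", signature("Phantom", "GadoliniumField"),
  function(phantom, field) {
    if (!identical(dim(field@concentrationMM), dim(phantom@t1Ms)))
      stop("concentration field shape must match the phantom")
    t1 <- phantom@t1Ms
    fg <- phantom@labels > 0L
    t1[fg] <- gadShortenT1(t1[fg], field@concentrationMM[fg], field@relaxivityR1)
    initialize(phantom, t1Ms = t1)
  })

#' Build a uniform gadolinium field over selected regions
#'
#' Convenience constructor: constant concentration inside the named regions,
#' zero elsewhere.
#'
#' @param phantom a [Phantom-class].
#' @param concentrationMM concentration (mmol/L) inside the regions.
#' @param regions character vector of region names (default: all regions).
#' @param relaxivityR1 longitudinal relaxivity (L mmol^-1 s^-1); the default
#'   4.0 is typical for a macrocyclic agent in tissue at 3T.
#' @return a [GadoliniumField-class].
#' @export
uniformGadoliniumField <- function(phantom, concentrationMM,
                                   regions = phantom@regions$name,
                                   relaxivityR1 = 4.0) {
  ids <- phantom@regions$label_id[phantom@regions$name %in% regions]
  conc <- array(0, dim = dim(phantom@labels))
  conc[phantom@labels %in% ids] <- concentrationMM
  new("GadoliniumField", concentrationMM = conc, relaxivityR1 = relaxivityR1)
}

#' Misalign a phantom by a known rigid transform
#'
#' Moves the phantom by the given rigid body motion (rotation about the volume
#' centre, then translation), resampling the label volume nearest-neighbour
#' and the T1 volume trilinearly onto the original grid. The transform that
#' re-aligns the result to its source is stored on the returned phantom as
#' ground truth for registration-recovery tests.
#'
#' @param phantom a [Phantom-class].
#' @param rigid a [RigidTransform-class] or numeric 6-vector
#'   (3 rotations deg, 3 translations mm); rotations within +/-15 deg,
#'   translations within +/-10 mm.
#' @return a misaligned [Phantom-class] with `trueTransform` set.
#' @export
misalignPhantom <- function(phantom, rigid) {
  p <- asRigidParams(rigid)
  if (any(abs(p[1:3]) > 15)) stop("rotations must be within +/-15 degrees")
  if (any(abs(p[4:6]) > 10)) stop("translations must be within +/-10 mm")
  centre <- worldCentre(dim(phantom@labels), phantom@affine)
  M <- rigidMatrix(p, centre)
  # object moved by M: out(x) = in(M^-1 x); resampling samples in() at (Minv x)
  Minv <- solve(M)
  t1 <- resampleVolume(phantom@t1Ms, phantom@affine,
                       dim(phantom@labels), phantom@affine,
                       sampleMatrix = Minv, method = "linear", fill = 0)
  labels <- resampleVolume(phantom@labels, phantom@affine,
                           dim(phantom@labels), phantom@affine,
                           sampleMatrix = Minv, method = "nearest", fill = 0L)
  storage.mode(labels) <- "integer"
  # edge voxels can interpolate against background zeros; keep foreground > 0
  fg <- labels > 0L
  t1[fg] <- pmax(t1[fg], 1)
  initialize(phantom, labels = labels, t1Ms = t1, trueTransform = p)
}

asRigidParams <- function(rigid) {
  if (is(rigid, "RigidTransform")) return(transformParams(rigid))
  rigid <- as.numeric(rigid)
  if (length(rigid) != 6 || any(!is.finite(rigid)))
    stop("rigid must be a RigidTransform or 6 finite numbers")
  rigid
}
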