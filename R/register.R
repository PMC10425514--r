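#' Construct a rigid transform
#'
#' @param rotationsDeg 3 rotations in degrees (applied about x, y, z in that
#'   order, about the registration centre).
#' @param translationsMm 3 translations in mm.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotationsDeg = c(0, 0, 0),
                           translationsMm = c(0, 0, 0)) {
  new("RigidTransform", rotationsDeg = as.numeric(rotationsDeg),
      translationsMm = as.numeric(translationsMm))
}

# 4x4 world-space matrix of a 6-parameter rigid motion about `centre`:
# x -> Rz Ry Rx (x - c) + c + t
rigidMatrix <- function(params, centre) {
  r <- params[1:3] * pi / 180
  t <- params[4:6]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- centre - R %*% centre + t
  M
}

worldCentre <- function(shape, affine) {
  as.vector((affine %*% c((shape - 1) / 2, 1))[1:3])
}

# Resample `vol` (with voxel-to-world `affineSrc`) onto the grid defined by
# `targetShape`/`affineTarget`. Each target voxel's world position x is mapped
# to sampleMatrix %*% x and the source volume interpolated there.
resampleVolume <- function(vol, affineSrc, targetShape, affineTarget,
                           sampleMatrix = diag(4),
                           method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  targetShape <- as.integer(targetShape)
  idx <- as.matrix(expand.grid(
    x = seq_len(targetShape[1]) - 1,
    y = seq_len(targetShape[2]) - 1,
    z = seq_len(targetShape[3]) - 1))
  M <- solve(affineSrc) %*% sampleMatrix %*% affineTarget
  src <- cbind(idx, 1) %*% t(M)    # source voxel coords, 0-based
  out <- interpolate3d(vol, src[, 1], src[, 2], src[, 3], method, fill)
  array(out, dim = targetShape)
}

# Trilinear / nearest-neighbour interpolation at fractional 0-based voxel
# coordinates; outside the volume returns `fill`.
interpolate3d <- function(vol, x, y, z, method, fill = 0) {
  d <- dim(vol)
  if (method == "nearest") {
    i <- round(x); j <- round(y); k <- round(z)
    inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
      k >= 0 & k <= d[3] - 1
    out <- rep(fill, length(x))
    lin <- 1 + i[inside] + d[1] * (j[inside] + d[2] * k[inside])
    out[inside] <- vol[lin]
    return(out)
  }
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  inside <- i0 >= 0 & i0 <= d[1] - 2 & j0 >= 0 & j0 <= d[2] - 2 &
    k0 >= 0 & k0 <= d[3] - 2
  # points exactly on the upper face are pulled onto the last cell
  hi <- x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1 &
    x >= 0 & y >= 0 & z >= 0 & !inside
  if (any(hi)) {
    i0[hi] <- pmin(i0[hi], d[1] - 2); j0[hi] <- pmin(j0[hi], d[2] - 2)
    k0[hi] <- pmin(k0[hi], d[3] - 2)
    fx[hi] <- x[hi] - i0[hi]; fy[hi] <- y[hi] - j0[hi]; fz[hi] <- z[hi] - k0[hi]
    inside <- inside | hi
  }
  out <- rep(as.numeric(fill), length(x))
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  base <- function(ii, jj, kk) vol[1 + ii + d[1] * (jj + d[2] * kk)]
  v000 <- base(i0, j0, k0);     v100 <- base(i0 + 1, j0, k0)
  v010 <- base(i0, j0 + 1, k0); v110 <- base(i0 + 1, j0 + 1, k0)
  v001 <- base(i0, j0, k0 + 1); v101 <- base(i0 + 1, j0, k0 + 1)
  v011 <- base(i0, j0 + 1, k0 + 1); v111 <- base(i0 + 1, j0 + 1, k0 + 1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Separable Gaussian smoothing with per-axis sigma in voxels (0 = skip axis).
gaussSmooth3d <- function(vol, sigmaVox) {
  d <- dim(vol)
  sigmaVox <- rep_len(sigmaVox, 3)
  kernelMat <- function(n, s) {
    if (s <= 0) return(NULL)
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
      K[i, ] <- K[i, ] / sum(K[i, ])
    }
    K
  }
  for (ax in 1:3) {
    K <- kernelMat(d[ax], sigmaVox[ax])
    if (is.null(K)) next
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    v <- array(K %*% matrix(v, d[ax]), dim = d[perm])
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Rigid intensity-based registration
#'
#' Estimates the 6-parameter rigid transform aligning `moving` to `fixed` by
#' minimizing the mean squared intensity difference over the fixed grid, with
#' 3-level coarse-to-fine Gaussian smoothing and multi-start Nelder-Mead
#' local optimization. Deterministic given the inputs and `init`. The
#' returned transform `T` is the one under which the resampled moving image
#' `moving(T x)` matches `fixed(x)`; for a phantom misaligned with
#' [misalignPhantom()] it equals the stored `trueTransform`.
#'
#' @param moving,fixed 3-D numeric arrays.
#' @param movingAffine,fixedAffine voxel-to-world transforms.
#' @param init a [RigidTransform-class] or 6-vector starting estimate.
#' @param smoothSigmasMm Gaussian smoothing levels (mm), coarse to fine.
#' @param nStarts number of additional perturbed starts at the coarsest level.
#' @param balanceBlurVox extra Gaussian blur (sigma in voxels) applied to the
#'   fixed image only, compensating a resampling the moving image has already
#'   been through. Default 0 (exact self-registration); useful around 0.4 when
#'   the moving image is known to be a resampled copy of a sharp-edged scene.
#' @return a [RigidTransform-class]; attribute `"costTrace"` records the cost
#'   of each accepted (improving) step and attribute `"mse"` the final cost.
#' @export
registerRigid <- function(moving, fixed, movingAffine = diag(4),
                          fixedAffine = movingAffine,
                          init = rigidTransform(),
                          smoothSigmasMm = c(6, 3, 0), nStarts = 4L,
                          balanceBlurVox = 0) {
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("registration error: constant image has no intensity gradient")
  centre <- worldCentre(dim(fixed), fixedAffine)
  voxF <- sqrt(colSums(fixedAffine[1:3, 1:3]^2))
  voxM <- sqrt(colSums(movingAffine[1:3, 1:3]^2))
  d <- dim(fixed)
  gridIdx <- function(stride) {
    cbind(as.matrix(expand.grid(seq(1, d[1], by = stride) - 1,
                                seq(1, d[2], by = stride) - 1,
                                seq(1, d[3], by = stride) - 1)), 1)
  }
  idx <- gridIdx(1L)
  # Halfway-space metric: moving is resampled by M(p/2), fixed by M(-p/2),
  # so both images are interpolated exactly once and the interpolation blur
  # is symmetric; an asymmetric metric biases the optimum near sharp edges.
  # Half-parameterisation is exact to second order in the angles, ample for
  # the +/-15 degree rigid range.
  cost <- function(p, mv, fx) {
    srcM <- idx %*% t(solve(movingAffine) %*% rigidMatrix(p / 2, centre) %*%
                        fixedAffine)
    srcF <- idx %*% t(solve(fixedAffine) %*% rigidMatrix(-p / 2, centre) %*%
                        fixedAffine)
    vm <- interpolate3d(mv, srcM[, 1], srcM[, 2], srcM[, 3], "linear",
                        fill = NA_real_)
    vf <- interpolate3d(fx, srcF[, 1], srcF[, 2], srcF[, 3], "linear",
                        fill = NA_real_)
    ok <- !is.na(vm) & !is.na(vf)
    # heavy but finite penalty keeps the optimizer inside the overlap
    if (sum(ok) < length(vm) * 0.25) return(1e12)
    mean((vm[ok] - vf[ok])^2)
  }
  p <- asRigidParams(init)
  if (cost(p, moving, fixed) >= 1e12)
    stop("registration error: insufficient overlap between volumes at init")
  traces <- vector("list", length(smoothSigmasMm))
  bestVal <- Inf
  for (lev in seq_along(smoothSigmasMm)) {
    s <- smoothSigmasMm[lev]
    # the moving image has typically been resampled once already (its
    # acquisition grid is not the fixed grid); trilinear resampling blurs by
    # roughly a 0.41-voxel-sigma kernel on average, so the fixed image gets
    # that much extra smoothing to keep the metric's blur budget symmetric
    sF <- sqrt((s / voxF)^2 + balanceBlurVox^2)
    fx <- gaussSmooth3d(fixed, sF)
    mv <- if (s > 0) gaussSmooth3d(moving, s / voxM) else moving
    # coarse levels are evaluated on a decimated grid
    idx <- gridIdx(if (s >= 4) 2L else 1L)
    starts <- list(p)
    if (lev == 1L && nStarts > 0L) {
      # deterministic perturbation lattice around the initial estimate
      for (k in seq_len(nStarts)) {
        ang <- 2 * pi * k / nStarts
        starts[[k + 1L]] <- p + c(3 * cos(ang), 3 * sin(ang), 3 * cos(2 * ang),
                                  2 * sin(ang), 2 * cos(ang), 2 * sin(2 * ang))
      }
    }
    bestVal <- Inf
    trace <- numeric(0)
    for (st in starts) {
      opt <- stats::optim(st, cost, mv = mv, fx = fx, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
      # restart from the collapsed simplex until no further improvement;
      # plain Nelder-Mead routinely stalls in 6 dimensions
      for (r in 1:3) {
        opt2 <- stats::optim(opt$par, cost, mv = mv, fx = fx,
                             method = "Nelder-Mead",
                             control = list(maxit = 400, reltol = 1e-10))
        if (opt2$value >= opt$value * (1 - 1e-6)) { opt <- opt2; break }
        opt <- opt2
      }
      if (opt$value < bestVal) {
        bestVal <- opt$value
        p <- opt$par
        trace <- c(trace, opt$value)
      }
    }
    traces[[lev]] <- trace
  }
  out <- rigidTransform(p[1:3], p[4:6])
  attr(out, "mse") <- bestVal
  attr(out, "costTrace") <- traces
  out
}

#' Resample a label volume onto a target grid
#'
#' Nearest-neighbour resampling of an integer label volume under a rigid
#' transform (the convention of [registerRigid()]): the output at world
#' position x carries the input label at T(x). Nearest-neighbour assignment
#' never invents labels, but voxel counts of thin structures can change —
#' each output voxel can carry only one label — so between-session volume
#' changes are largely a by-product of resampling, which is exactly why
#' region volumes serve as a co-registration diagnostic.
#'
#' @param labels 3-D integer array.
#' @param labelsAffine its voxel-to-world transform.
#' @param transform a [RigidTransform-class] or 6-vector.
#' @param targetShape,targetAffine output grid (defaults: input grid).
#' @param centre rotation centre; defaults to the target volume centre.
#' @return 3-D integer array on the target grid (background 0 outside).
#' @export
resampleLabels <- function(labels, labelsAffine = diag(4),
                           transform = rigidTransform(),
                           targetShape = dim(labels),
                           targetAffine = labelsAffine,
                           centre = worldCentre(targetShape, targetAffine)) {
  p <- asRigidParams(transform)
  M <- rigidMatrix(p, centre)
  out <- resampleVolume(labels, labelsAffine, targetShape, targetAffine,
                        sampleMatrix = M, method = "nearest", fill = 0L)
  storage.mode(out) <- "integer"
  out
}
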