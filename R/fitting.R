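#' Restore the sign of leading magnitude samples
#'
#' Magnitude inversion-recovery data lose the sign of the early
#' (negative-magnetization) samples; polarity restoration negates the first
#' `candidateIndex` samples and leaves the rest unchanged.
#'
#' @param curve a [SignalCurve-class] or numeric magnitude vector.
#' @param candidateIndex number of leading samples to negate, in
#'   `0..length(curve)`.
#' @return signed numeric vector.
#' @examples
#' restorePolarity(c(5, 1, 3, 6), 2)  # -5 -1  3  6
#' @export
restorePolarity <- function(curve, candidateIndex) {
  mag <- if (is(curve, "SignalCurve")) curve@magnitude else as.numeric(curve)
  candidateIndex <- as.integer(candidateIndex)
  if (candidateIndex < 0L || candidateIndex > length(mag))
    stop("candidateIndex out of range [0, ", length(mag), "]")
  if (candidateIndex > 0L)
    mag[seq_len(candidateIndex)] <- -mag[seq_len(candidateIndex)]
  mag
}

#' Fit one inversion-recovery curve
#'
#' For every polarity index 0..n, restores the sign of the leading samples,
#' fits \eqn{S(TI) = A - B e^{-TI/T1^*}} by Levenberg-Marquardt least
#' squares, and keeps the (index, fit) pair with the smallest residual norm
#' (ties broken toward the smaller index). The fitted apparent T1* is then
#' corrected to T1, by default with the excitation-angle formula
#' ([correctApparentT1()]); `correction = "b_over_a"` instead applies the
#' classical \eqn{T1 = T1^* (B/A - 1)}.
#'
#' Starting values: \eqn{A_0} = last-sample magnitude, \eqn{B_0 = A_0 +}
#' first-sample magnitude, \eqn{T1^*_0} = TI at the magnitude minimum divided
#' by \eqn{\ln(B_0/A_0)}, floored at 50 ms. If the optimizer lands above the
#' optimum of a coarse grid search (linear least squares in A, B over a small
#' T1* grid), it is restarted once from the grid optimum. Non-convergence is
#' flagged, never raised.
#'
#' @param curve a [SignalCurve-class] with at least 4 samples.
#' @param protocol the [LLProtocol-class] used for the correction.
#' @param correction `"flip_angle"` (primary) or `"b_over_a"`.
#' @return a [FitResult-class].
#' @export
fitCurve <- function(curve, protocol = llProtocol(),
                     correction = c("flip_angle", "b_over_a")) {
  correction <- match.arg(correction)
  stopifnot(is(curve, "SignalCurve"))
  n <- length(curve@magnitude)
  if (n < 4L) stop("need at least 4 samples to fit 3 parameters")
  if (all(curve@magnitude == 0))
    return(new("FitResult", A = NA_real_, B = NA_real_, t1StarMs = NA_real_,
               t1Ms = NA_real_, residualNorm = 0, polarityIndex = 0L,
               converged = FALSE))
  ti <- curve@tiMs
  best <- NULL
  for (idx in 0:n) {
    signed <- restorePolarity(curve, idx)
    fit <- fitSignedCurve(ti, signed)
    # strict improvement only: equal residuals keep the smaller index
    if (is.null(best) || fit$rss < best$rss) {
      fit$idx <- idx
      best <- fit
    }
  }
  t1 <- if (!best$converged) NA_real_
  else if (correction == "flip_angle") correctApparentT1(best$par[3], protocol)
  else best$par[3] * (best$par[2] / best$par[1] - 1)
  new("FitResult",
      A = best$par[1], B = best$par[2], t1StarMs = best$par[3], t1Ms = t1,
      residualNorm = sqrt(best$rss), polarityIndex = as.integer(best$idx),
      converged = best$converged)
}

# Damped least squares of the signed three-parameter model, with the
# heuristic start and a coarse grid fallback restart.
fitSignedCurve <- function(ti, signed) {
  n <- length(signed)
  A0 <- abs(signed[n])
  B0 <- A0 + abs(signed[1])
  if (A0 <= 0) A0 <- max(abs(signed))
  if (B0 <= A0) B0 <- A0 * 1.5
  tMin <- ti[which.min(abs(signed))]
  T0 <- if (B0 > A0 && A0 > 0) max(tMin / log(B0 / A0), 50) else max(tMin, 50)
  fit1 <- runLM(ti, signed, c(A0, B0, T0))
  # coarse grid safeguard: exact linear LS in (A, B) on a log-spaced T1* grid
  grid <- gridSignedLS(ti, signed,
                       t1StarGrid = exp(seq(log(40), log(8000), length.out = 12)))
  out <- fit1
  if (!is.null(grid) && (is.null(out) || grid$rss < out$rss * (1 - 1e-12))) {
    fit2 <- runLM(ti, signed, grid$par)
    out <- if (!is.null(fit2) && fit2$rss <= grid$rss) fit2 else
      list(par = grid$par, rss = grid$rss, converged = TRUE)
    if (!is.null(fit1) && fit1$rss < out$rss) out <- fit1
  }
  if (is.null(out))
    out <- list(par = c(NA_real_, NA_real_, NA_real_),
                rss = sum(signed^2), converged = FALSE)
  out
}

runLM <- function(ti, signed, start) {
  res <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) signed - (p[1] - p[2] * exp(-ti / max(p[3], 1e-6))),
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-8,
                                         ftol = 1e-12)
  ), silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  conv <- res$info %in% 1:4 && is.finite(res$deviance) && res$par[3] > 0
  if (!conv) return(NULL)
  list(par = res$par, rss = res$deviance, converged = TRUE)
}

# For each T1* on a grid the model is linear in (A, B); solve exactly and
# return the grid point with minimal residual sum of squares.
gridSignedLS <- function(ti, signed, t1StarGrid) {
  best <- NULL
  for (ts in t1StarGrid) {
    e <- exp(-ti / ts)
    X <- cbind(1, -e)
    cf <- tryCatch(qr.coef(qr(X), signed), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    rss <- sum((signed - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = c(cf[1], cf[2], ts), rss = rss)
  }
  best
}

#' Fit a 4-D Look-Locker acquisition voxelwise
#'
#' Runs [fitCurve()] at every voxel (optionally restricted to a mask) and
#' assembles a [T1Map-class]. A voxel is valid only when its fit converged
#' and the corrected T1 lies strictly inside (0, 10000) ms; values outside
#' that interval are artifacts (aliasing can produce negative or absurdly
#' long times) and are excluded from statistics rather than clipped.
#'
#' @param acq an [LLAcquisition-class], or a 4-D magnitude array.
#' @param protocol required when `acq` is a bare array.
#' @param mask optional 3-D logical array; voxels outside are left NA/invalid.
#' @param correction passed to [fitCurve()].
#' @param affine spatial transform when `acq` is a bare array.
#' @return a [T1Map-class].
#' @export
fitVolume <- function(acq, protocol = NULL, mask = NULL,
                      correction = c("flip_angle", "b_over_a"),
                      affine = diag(4)) {
  correction <- match.arg(correction)
  if (is(acq, "LLAcquisition")) {
    signal <- acq@signal
    protocol <- acq@protocol
    affine <- acq@affine
  } else {
    signal <- acq
    if (is.null(protocol)) stop("protocol required for a bare signal array")
  }
  d <- dim(signal)
  if (length(d) != 4 || d[4] != protocol@nPhases)
    stop("signal must be 4-D with 4th dimension matching the protocol")
  shp <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = shp)
  if (!identical(dim(mask), shp)) stop("mask shape must match the volume")
  ti <- tiSchedule(protocol)
  nvox <- prod(shp)
  sigMat <- matrix(signal, nvox, d[4])
  t1 <- array(NA_real_, dim = shp)
  valid <- array(FALSE, dim = shp)
  for (v in which(as.vector(mask))) {
    cv <- new("SignalCurve", tiMs = ti, magnitude = sigMat[v, ],
              trueParams = list())
    fr <- fitCurve(cv, protocol, correction)
    t1[v] <- fr@t1Ms
    valid[v] <- isTRUE(fr@converged) && is.finite(fr@t1Ms) &&
      fr@t1Ms > 0 && fr@t1Ms < 10000
  }
  new("T1Map", t1Ms = t1, valid = valid, affine = affine, protocol = protocol)
}

#' Synthesize a T1-weighted image from a T1 map
#'
#' Maps T1 to a strictly decreasing intensity so that short-T1 tissue (white
#' matter) appears bright, as in a clinical T1-weighted scan; the synthetic
#' image is the registration target of the alignment stage. `"inverse_t1"`
#' uses `referenceT1Ms / T1`; `"spgr_like"` evaluates the spoiled
#' gradient-echo signal equation at the given flip angle and repetition time.
#' Invalid voxels map to 0.
#'
#' @param t1Map a [T1Map-class].
#' @param referenceT1Ms scaling constant for `"inverse_t1"`.
#' @param contrast `"inverse_t1"` or `"spgr_like"`.
#' @param flipAngleDeg,trMs spoiled gradient-echo parameters for
#'   `"spgr_like"` (defaults 8 deg / 5.1 ms, a typical 3D T1w protocol).
#' @return 3-D numeric intensity array.
#' @export
synthesizeT1w <- function(t1Map, referenceT1Ms = 1000,
                          contrast = c("inverse_t1", "spgr_like"),
                          flipAngleDeg = 8, trMs = 5.1) {
  contrast <- match.arg(contrast)
  stopifnot(is(t1Map, "T1Map"))
  t1 <- t1Map@t1Ms
  out <- array(0, dim = dim(t1))
  ok <- t1Map@valid & is.finite(t1) & t1 > 0
  if (contrast == "inverse_t1") {
    out[ok] <- referenceT1Ms / t1[ok]
  } else {
    a <- flipAngleDeg * pi / 180
    E <- exp(-trMs / t1[ok])
    out[ok] <- sin(a) * (1 - E) / (1 - cos(a) * E)
  }
  out
}
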