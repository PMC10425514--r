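# Brute-force oracle for the inversion-recovery fit, independent of the
# package's Levenberg-Marquardt path: for every polarity index, scan a dense
# T1* grid and solve A, B exactly by linear least squares (the model is
# linear in A and B at fixed T1*), refining once on a finer local grid.
oracleFitCurve <- function(curve, nGrid = 600) {
  mag <- curve@magnitude
  ti <- curve@tiMs
  n <- length(mag)
  bestAll <- NULL
  scan <- function(signed, grid) {
    best <- NULL
    for (ts in grid) {
      X <- cbind(1, -exp(-ti / ts))
      cf <- tryCatch(qr.coef(qr(X), signed), error = function(e) NULL)
      if (is.null(cf) || any(!is.finite(cf))) next
      rss <- sum((signed - X %*% cf)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(par = c(cf[1], cf[2], ts), rss = rss)
    }
    best
  }
  for (idx in 0:n) {
    signed <- mag
    if (idx > 0) signed[seq_len(idx)] <- -signed[seq_len(idx)]
    coarse <- scan(signed, exp(seq(log(20), log(20000), length.out = nGrid)))
    if (is.null(coarse)) next
    ts0 <- coarse$par[3]
    fine <- scan(signed, seq(ts0 * 0.9, ts0 * 1.1, length.out = 200))
    cand <- if (!is.null(fine) && fine$rss < coarse$rss) fine else coarse
    if (is.null(bestAll) || cand$rss < bestAll$rss) {
      cand$idx <- idx
      bestAll <- cand
    }
  }
  bestAll
}
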