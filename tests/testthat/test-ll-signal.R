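proto <- llProtocol()

test_that("inversion-time schedule follows the protocol arithmetic", {
  ti <- tiSchedule(proto)
  expect_length(ti, 12)
  expect_equal(ti[1], 19.6)
  expect_equal(ti[12], 19.6 + 11 * 400.3)
  expect_equal(tiSchedule(llProtocol(10, 100, 3, 4815)), c(10, 110, 210))
  expect_error(llProtocol(nPhases = 2), "nPhases")
  expect_error(llProtocol(excitationAngleDeg = 95), "excitationAngleDeg")
  expect_error(llProtocol(tiMinMs = 500, phaseIntervalMs = 400.3,
                          nPhases = 12, cycleDurationMs = 4815),
               "cycleDurationMs")
})

test_that("signed model has the textbook asymptote, intercept and root", {
  expect_equal(signedModel(1e9, 1, 2, 500), 1)
  expect_equal(signedModel(0, 1, 2, 500), -1)
  expect_equal(signedModel(500 * log(2), 1, 2, 500), 0, tolerance = 1e-12)
  expect_error(signedModel(100, 1, 2, -5), "t1StarMs")
  # strictly increasing for B > 0
  ti <- seq(0, 5000, by = 50)
  expect_true(all(diff(signedModel(ti, 1, 2, 800)) > 0))
})

test_that("apparent T1 shortens with flip angle and inverts exactly", {
  # closed form at 8 deg, 400.3 ms interval
  expect_equal(apparentT1(1000, proto),
               1 / (1 / 1000 - log(cos(8 * pi / 180)) / 400.3))
  expect_lt(apparentT1(1000, proto), 1000)
  # alpha -> 0 limit
  expect_equal(apparentT1(1000, llProtocol(excitationAngleDeg = 1e-6)), 1000,
               tolerance = 1e-9)
  # monotone decrease in alpha
  t1s <- vapply(c(2, 5, 8, 15, 30, 60), function(a)
    apparentT1(1000, llProtocol(excitationAngleDeg = a)), numeric(1))
  expect_true(all(diff(t1s) < 0))
  # round trip through the correction
  for (t1 in c(300, 600, 1000, 1500, 2000, 4000))
    expect_equal(correctApparentT1(apparentT1(t1, proto), proto), t1,
                 tolerance = 1e-9)
})

test_that("simulated curves are magnitude data with the expected shape", {
  cv <- simulateCurve(1000, proto, m0 = 1, noiseSd = 0)
  expect_s4_class(cv, "SignalCurve")
  expect_true(all(cv@magnitude >= 0))
  # |A - B| at TI = 0 with perfect inversion is A; first TI is near 0
  expect_equal(cv@magnitude[1],
               abs(signedModel(19.6, 1, 2, apparentT1(1000, proto))))
  # exactly one local minimum (the zero crossing of the signed curve)
  m <- cv@magnitude
  localMin <- which(diff(sign(diff(m))) > 0)
  expect_length(localMin, 1)
  # determinism under a fixed seed
  n1 <- simulateCurve(1000, proto, noiseSd = 0.02, seed = 11)
  n2 <- simulateCurve(1000, proto, noiseSd = 0.02, seed = 11)
  expect_identical(n1@magnitude, n2@magnitude)
  expect_false(identical(
    n1@magnitude, simulateCurve(1000, proto, noiseSd = 0.02, seed = 12)@magnitude))
  expect_error(simulateCurve(-5, proto), "t1Ms")
})

test_that("rician and gaussian magnitude noise agree at high SNR", {
  # mean signal across many replicates, compared where |signal|/sd > 10
  t1 <- 1000
  sd <- 0.02
  ref <- abs(signedModel(tiSchedule(proto), 1, 2, apparentT1(t1, proto)))
  keep <- ref / sd > 10
  nrep <- 4000
  acc <- matrix(0, nrep, sum(keep))
  for (model in c("gaussian_magnitude", "rician")) {
    for (r in seq_len(nrep))
      acc[r, ] <- simulateCurve(t1, proto, noiseSd = sd, noiseModel = model,
                                seed = r)@magnitude[keep]
    expect_lt(max(abs(colMeans(acc) - ref[keep]) / ref[keep]), 0.01)
    expect_true(all(acc >= 0))
  }
})

test_that("volume simulation reduces to the single-curve simulator", {
  regs <- regionSpec("r", 1, 1200)
  ph <- makePhantom(regs, shape = c(16, 16, 16), seed = 1)
  acq <- simulateVolume(ph, proto, noiseSd = 0, seed = 1)
  expect_s4_class(acq, "LLAcquisition")
  v <- which(labelVolume(ph) == 1L, arr.ind = TRUE)[1, ]
  curve <- signalArray(acq)[v[1], v[2], v[3], ]
  expect_equal(curve, simulateCurve(1200, proto, noiseSd = 0)@magnitude)
  # all foreground voxels share the same noiseless curve
  sig <- matrix(signalArray(acq), ncol = 12)
  fg <- which(as.vector(labelVolume(ph) > 0))
  expect_equal(max(apply(sig[fg, ], 2, function(x) diff(range(x)))), 0)
  # background is at the noise floor (zero, noiseless)
  expect_equal(max(sig[-fg, ]), 0)
})
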