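regions4 <- defaultRegionTable("phantom")

test_that("self-registration returns identity and rejects degenerate input", {
  ph <- makePhantom(regions4, shape = c(24, 24, 16), seed = 4)
  reg <- registerRigid(t1Values(ph), t1Values(ph), voxelToWorld(ph),
                       nStarts = 2L)
  p <- transformParams(reg)
  expect_lt(max(abs(p[1:3])), 1e-3)
  expect_lt(max(abs(p[4:6])), 1e-3)
  flat <- array(1, dim = c(20, 20, 20))
  expect_error(registerRigid(flat, flat), "constant")
  # accepted steps within each pyramid level never increase the error
  for (tr in attr(reg, "costTrace"))
    if (length(tr) > 1) expect_true(all(diff(tr) <= 0))
})

test_that("a known misalignment is recovered within tolerance", {
  # band-limited scene with smooth internal structure, as acquired images are
  ph <- makePhantom(regions4, shape = c(32, 32, 20), seed = 2,
                    shadingAmp = 0.06, psfBlurVox = 0.7)
  true <- c(3, 0, 0, 2, 0, 0)
  mis <- misalignPhantom(ph, true)
  reg <- registerRigid(t1Values(mis), t1Values(ph), voxelToWorld(ph))
  p <- transformParams(reg)
  expect_lt(max(abs(p[1:3] - true[1:3])), 0.5)
  expect_lt(max(abs(p[4:6] - true[4:6])), 0.5)
})

test_that("label resampling is conservative and exact under identity", {
  ph <- makePhantom(regions4, shape = c(24, 24, 16), seed = 5)
  lab <- labelVolume(ph)
  same <- resampleLabels(lab, voxelToWorld(ph))
  expect_identical(same, lab)
  out <- resampleLabels(lab, voxelToWorld(ph), c(2, -1, 1, 1, 0.5, -1))
  # never invents labels, conserves the voxel budget
  expect_true(all(unique(as.vector(out)) %in% c(0L, regions4$label_id)))
  expect_equal(length(out), length(lab))
  # downsampling onto a coarser grid changes voxel counts of thin structures
  coarseAff <- voxelToWorld(ph) %*% diag(c(2, 2, 1, 1))
  down <- resampleLabels(lab, voxelToWorld(ph),
                         targetShape = c(12, 12, 16),
                         targetAffine = coarseAff)
  expect_true(all(unique(as.vector(down)) %in% c(0L, regions4$label_id)))
})

test_that("region statistics aggregate valid voxels and full volumes", {
  # constructed map: a 10 x 10 x 10 region at exactly 1030.6 ms with one
  # artifact voxel excluded from the mean but counted in the volume
  t1 <- array(1030.6, dim = c(10, 10, 10))
  valid <- array(TRUE, dim = dim(t1))
  t1[1, 1, 1] <- NA; valid[1, 1, 1] <- FALSE  # fit said 12000 -> masked
  aff <- diag(c(1.39, 1.39, 4, 1))
  tm <- new("T1Map", t1Ms = t1, valid = valid, affine = aff,
            protocol = llProtocol())
  lab <- array(1L, dim = dim(t1))
  regs <- regionSpec("pallidum", 1, 1030.6)
  st <- regionStats(tm, lab, regs)
  expect_equal(st$mean_t1_ms, 1030.6)
  expect_equal(st$n_valid_voxels, 999)
  expect_equal(st$n_voxels, 1000)
  expect_equal(st$volume_ml, 1000 * 1.39 * 1.39 * 4 / 1000)  # 7.7284 ml
  # empty region flagged rather than erroring
  regs2 <- regionSpec(c("pallidum", "ghost"), c(1, 2), c(1030.6, 1000))
  st2 <- regionStats(tm, lab, regs2)
  expect_equal(st2$n_valid_voxels[2], 0)
  expect_true(is.na(st2$mean_t1_ms[2]))
  expect_error(regionStats(tm, lab[1:5, , ], regs), "grid")
})

test_that("composite regions take voxel-weighted means and summed volumes", {
  rows <- data.frame(
    subject_id = "s", session = "Pre",
    region_name = c("a", "b"),
    mean_t1_ms = c(1000, 1200), sd_t1_ms = c(0, 0),
    n_valid_voxels = c(100L, 300L), n_voxels = c(100L, 300L),
    volume_ml = c(0.5, 1.5), stringsAsFactors = FALSE
  )
  comp <- compositeRegions(rows, list(both = c("a", "b")))
  expect_equal(comp$mean_t1_ms, 1150)  # (100*1000 + 300*1200) / 400
  expect_equal(comp$volume_ml, 2.0)
  expect_equal(comp$n_valid_voxels, 400L)
  # equal-weight case and identity composite
  rows$n_valid_voxels <- c(200L, 200L)
  expect_equal(compositeRegions(rows, list(both = c("a", "b")))$mean_t1_ms,
               1100)
  one <- compositeRegions(rows, list(solo = "a"))
  expect_equal(one$mean_t1_ms, rows$mean_t1_ms[1])
  expect_equal(one$volume_ml, rows$volume_ml[1])
  expect_error(compositeRegions(rows, list(bad = c("a", "zzz"))), "zzz")
})

test_that("identity alignment gives exactly zero volume change per region", {
  ph <- makePhantom(regions4, shape = c(24, 24, 16), seed = 6)
  t1 <- t1Values(ph)
  tm <- new("T1Map", t1Ms = t1, valid = labelVolume(ph) > 0,
            affine = voxelToWorld(ph), protocol = llProtocol())
  pre <- regionStats(tm, labelVolume(ph), regions4, "s1", "Pre")
  lab2 <- resampleLabels(labelVolume(ph), voxelToWorld(ph))
  wk4 <- regionStats(tm, lab2, regions4, "s1", "Week4")
  expect_equal(percentChange(pre$volume_ml, wk4$volume_ml),
               rep(0, nrow(pre)))
})
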