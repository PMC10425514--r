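regions4 <- defaultRegionTable("phantom")

test_that("phantom generation is deterministic and respects region T1 means", {
  regs0 <- defaultRegionTable("phantom", t1_within_region_sd_ms = 0)
  ph <- makePhantom(regs0, shape = c(24, 24, 16), seed = 7)
  ph2 <- makePhantom(regs0, shape = c(24, 24, 16), seed = 7)
  expect_identical(t1Values(ph), t1Values(ph2))
  expect_identical(labelVolume(ph), labelVolume(ph2))
  # zero within-region noise: each region constant at its mean
  for (i in seq_len(nrow(regs0))) {
    vals <- t1Values(ph)[labelVolume(ph) == regs0$label_id[i]]
    expect_gte(length(vals), 50)
    expect_equal(unique(vals), regs0$t1_mean_ms[i])
  }
  # white matter averages its dictionary mean exactly in the noiseless case
  wm <- t1Values(ph)[labelVolume(ph) == 2L]
  expect_equal(mean(wm), 1082.1)
})

test_that("phantom generator validates its inputs", {
  expect_error(makePhantom(regions4, shape = c(8, 8, 8)), "shape")
  # a shape too small to host the deep blobs names the failing region
  expect_error(makePhantom(regions4, shape = c(16, 16, 16)),
               "basal_ganglia|pallidum")
  expect_error(regionSpec("a", 1, t1_mean_ms = -5), "t1_mean_ms")
  expect_error(regionSpec(c("a", "b"), c(1, 1), c(1000, 1200)), "unique")
})

test_that("slab geometry hosts every region too", {
  ph <- makePhantom(regions4, shape = c(20, 20, 24), geometry = "slab_stack",
                    seed = 1)
  counts <- table(labelVolume(ph))
  expect_true(all(as.character(regions4$label_id) %in% names(counts)))
  expect_true(all(counts[as.character(regions4$label_id)] >= 50))
})

test_that("gadolinium shortens T1 by relaxation-rate additivity", {
  # closed form: 1 s at r1 = 4, C = 0.1 mM -> 1/(1 + 0.4) s
  expect_equal(gadShortenT1(1000, 0.1, 4), 1000 / 1.4, tolerance = 1e-12)
  ph <- makePhantom(regions4, shape = c(24, 24, 16), seed = 3)
  zero <- uniformGadoliniumField(ph, 0)
  expect_equal(t1Values(applyGadolinium(ph, zero)), t1Values(ph))
  f1 <- uniformGadoliniumField(ph, 0.05)
  f2 <- uniformGadoliniumField(ph, 0.10)
  p1 <- applyGadolinium(ph, f1)
  p2 <- applyGadolinium(ph, f2)
  fg <- labelVolume(ph) > 0
  expect_true(all(t1Values(p1)[fg] < t1Values(ph)[fg]))
  expect_true(all(t1Values(p2)[fg] < t1Values(p1)[fg]))
  expect_error(new("GadoliniumField",
                   concentrationMM = array(-1, dim = dim(labelVolume(ph))),
                   relaxivityR1 = 4), "non-negative")
  # algebraic round trip: C recovered from the rate difference
  C <- (1 / (t1Values(p1)[fg] / 1000) - 1 / (t1Values(ph)[fg] / 1000)) / 4
  expect_lt(max(abs(C - 0.05) / 0.05), 1e-9)
})

test_that("cohort manifest accounting and determinism", {
  m <- makeCohort(88, 12, seed = 5)
  expect_equal(nrow(m), 88)
  expect_equal(sum(!m$excluded), 76)
  expect_true(all(nzchar(m$exclusion_reason[m$excluded])))
  expect_identical(m, makeCohort(88, 12, seed = 5))
  expect_false(identical(m, makeCohort(88, 12, seed = 6)))
  expect_true(all(m$age_years >= 18 & m$age_years <= 80))
  m0 <- makeCohort(10, 0, seed = 1)
  expect_true(all(!m0$excluded))
  expect_error(makeCohort(10, 11), "nExcluded")
})

test_that("misalignment stores recoverable ground truth and preserves labels", {
  ph <- makePhantom(regions4, shape = c(24, 24, 16), seed = 2)
  ident <- misalignPhantom(ph, c(0, 0, 0, 0, 0, 0))
  expect_equal(t1Values(ident), t1Values(ph), tolerance = 1e-12)
  expect_identical(labelVolume(ident), labelVolume(ph))
  # pure translation by whole voxels shifts labels losslessly in the interior
  mis <- misalignPhantom(ph, c(0, 0, 0, 1.39, 0, 0))
  expect_equal(trueTransform(mis), c(0, 0, 0, 1.39, 0, 0))
  inner <- labelVolume(ph)[2:23, , ]
  shifted <- labelVolume(mis)[3:24, , ]
  expect_identical(shifted, inner)
  expect_error(misalignPhantom(ph, c(20, 0, 0, 0, 0, 0)), "rotations")
  expect_error(misalignPhantom(ph, c(0, 0, 0, 11, 0, 0)), "translations")
  # foreground T1 stays positive after interpolation
  mis2 <- misalignPhantom(ph, c(3, -2, 1, 2, -1, 1.5))
  expect_true(all(t1Values(mis2)[labelVolume(mis2) > 0] > 0))
})

test_that("subject-level means follow the between-subject model", {
  regs <- defaultRegionTable("all")
  draws <- vapply(seq_len(1000), function(i) {
    sampleSubjectRegions(regs, seed = i)$t1_mean_ms[
      regs$name == "subcortical_white_matter"]
  }, numeric(1))
  se <- 46.7 / sqrt(1000)
  expect_lt(abs(mean(draws) - 1082.1), 3 * se)
  # degenerate case: no between-subject spread reproduces the dictionary
  regsFixed <- defaultRegionTable("all")
  regsFixed$t1_between_subject_sd_ms <- 0
  expect_equal(sampleSubjectRegions(regsFixed, seed = 1)$t1_mean_ms,
               regsFixed$t1_mean_ms)
})
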