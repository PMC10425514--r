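test_that("cohort filtering removes flagged subjects and logs the count", {
  m <- makeCohort(88, 12, seed = 3)
  expect_message(kept <- filterCohort(m), "76 analyzable")
  expect_equal(nrow(kept), 76)
  m0 <- makeCohort(5, 0, seed = 1)
  expect_identical(suppressMessages(filterCohort(m0))$subject_id,
                   m0$subject_id)
  mAll <- makeCohort(5, 5, seed = 1)
  expect_error(suppressMessages(filterCohort(mAll)), "all subjects excluded")
})

test_that("percent change is exact and guards its domain", {
  expect_equal(percentChange(1000, 1000), 0)
  expect_equal(percentChange(1000, 1030), 3)
  expect_equal(percentChange(1082.1, 1070.6), 100 * (1070.6 - 1082.1) / 1082.1)
  expect_equal(percentChange(c(100, 200), c(110, 180)), c(10, -10))
  expect_error(percentChange(0, 10), "pre")
})

test_that("t-tests match the closed-form statistic", {
  # differences 1, 2, 3: t = 2 / (1/sqrt(3))
  pre <- c(10, 20, 30)
  wk4 <- pre + c(1, 2, 3)
  r <- pairedTTest(pre, wk4)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-r$t, 2), tolerance = 1e-12)
  expect_equal(r$mean_diff, 2)
  expect_error(pairedTTest(pre, pre), "zero-variance")
  expect_error(pairedTTest(pre, wk4[1:2]), "equal length")
  # antisymmetric differences: t = 0, p = 1
  r0 <- pairedTTest(c(10, 20, 30, 40), c(11, 19, 31, 39))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  o <- oneSamplePctTest(c(-1, -2, -3))
  expect_equal(o$t, -2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(o$p, 2 * stats::pt(-abs(o$t), 2), tolerance = 1e-12)
  expect_true(o$ci95[1] < o$mean && o$mean < o$ci95[2])
  expect_error(oneSamplePctTest(rep(0, 5)), "zero-variance")
  expect_equal(oneSamplePctTest(c(-2, 0, 2))$t, 0)
})

test_that("safety-margin classification is boundary-inclusive", {
  expect_equal(classifyMargin(-0.98), "within_margin")
  expect_equal(classifyMargin(-3.0), "within_margin")
  expect_equal(classifyMargin(3.0), "within_margin")
  expect_equal(classifyMargin(-4.2), "exceeds_margin_shortening")
  expect_equal(classifyMargin(3.1), "exceeds_margin_lengthening")
  expect_equal(classifyMargin(c(-5, 0, 5)),
               c("exceeds_margin_shortening", "within_margin",
                 "exceeds_margin_lengthening"))
  expect_error(classifyMargin(1, margin = -1), "margin")
})

test_that("age correlation handles exact and null relationships", {
  ages <- seq(20, 80, length.out = 30)
  expect_equal(ageCorrelation(ages, 2 * ages + 1)$r, 1)
  expect_equal(ageCorrelation(ages, -ages)$r, -1)
  expect_error(ageCorrelation(ages, rep(1, 30)), "zero variance")
  # independent values: |r| small in most seeds at n = 1000
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(ageCorrelation(stats::rnorm(1000), stats::rnorm(1000))$r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("region inference reports both percent-change aggregations", {
  # constructed case: equal pre values make the two aggregations agree
  ch <- data.frame(
    subject_id = rep(sprintf("s%d", 1:4), 2),
    region_name = rep(c("a", "b"), each = 4),
    group = rep(c("main", "other"), each = 4),
    pre_value = c(rep(1000, 4), c(900, 1000, 1100, 1200)),
    week4_value = c(990, 1010, 980, 1020, 890, 1010, 1080, 1210),
    stringsAsFactors = FALSE
  )
  inf <- regionInference(ch)
  a <- inf[inf$region_name == "a", ]
  expect_equal(a$mean_pct, a$pct_of_means, tolerance = 1e-12)
  b <- inf[inf$region_name == "b", ]
  expect_false(isTRUE(all.equal(b$mean_pct, b$pct_of_means)))
  expect_true(all(inf$pct_p >= 0 & inf$pct_p <= 1))
  expect_true(all(inf$ci95_lo <= inf$mean_pct & inf$mean_pct <= inf$ci95_hi))
  expect_true(all(inf$pct_p_holm >= inf$pct_p))
})

test_that("forest table orders main regions first and flags the margin band", {
  m <- suppressMessages(filterCohort(makeCohort(76, 0, seed = 9)))
  regs <- defaultRegionTable("all")
  ch <- simulateCohortMeans(m, regs)
  inf <- regionInference(ch)
  f <- forestTable(inf, regs)
  expect_equal(f$region_name, regs$name)
  expect_equal(unique(f$group), c("main", "other"))
  expect_true(all(c("mean_pct", "ci95_lo", "ci95_hi",
                    "ci_within_margin") %in% names(f)))
  one <- forestTable(inf[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  # a CI fully inside the band is flagged as within
  narrow <- inf[1, , drop = FALSE]
  narrow$ci95_lo <- -1; narrow$ci95_hi <- 1
  expect_true(forestTable(narrow)$ci_within_margin)
})

test_that("null cohorts keep main regions inside the margin", {
  regs <- defaultRegionTable("all")
  inside <- vapply(1:50, function(s) {
    m <- suppressMessages(filterCohort(makeCohort(76, 0, seed = s)))
    ch <- simulateCohortMeans(m, regs)
    inf <- regionInference(ch)
    all(abs(inf$mean_pct) <= 3)
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("gadolinium exposure drives the cortex outside the margin", {
  regs <- defaultRegionTable("all")
  m <- suppressMessages(filterCohort(makeCohort(76, 0, seed = 21)))
  ch <- simulateCohortMeans(
    m, regs, gadolinium = list(regions = "cerebral_cortex",
                               concentrationMM = 0.05, relaxivityR1 = 4))
  inf <- regionInference(ch)
  cx <- inf[inf$region_name == "cerebral_cortex", ]
  expect_equal(cx$margin_class, "exceeds_margin_shortening")
  # unexposed regions stay within
  expect_true(all(inf$margin_class[inf$region_name != "cerebral_cortex"] ==
                    "within_margin"))
})
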