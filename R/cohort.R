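#' Generate a longitudinal cohort manifest
#'
#' One row per subject with age, sex, an exclusion flag (exclusions model
#' registration/segmentation failures), and a per-subject seed derived
#' deterministically from the global seed.
#'
#' @param nTotal total number of imaged subjects.
#' @param nExcluded number flagged excluded (`<= nTotal`); excluded rows carry
#'   reason `"registration_segmentation_error"`.
#' @param ageRange ages are drawn uniformly over this interval (years).
#' @param seed integer seed; the manifest is deterministic given the seed.
#' @return data.frame with columns `subject_id`, `age_years`, `sex`,
#'   `excluded`, `exclusion_reason`, `seed`.
#' @examples
#' m <- makeCohort(88, 12, seed = 1)
#' sum(!m$excluded)  # 76 analyzable
#' @export
makeCohort <- function(nTotal, nExcluded = 0L, ageRange = c(18, 80), seed = 1L) {
  nTotal <- as.integer(nTotal)
  nExcluded <- as.integer(nExcluded)
  if (nTotal < 1L) stop("nTotal must be positive")
  if (nExcluded < 0L || nExcluded > nTotal)
    stop("nExcluded must lie in [0, nTotal]")
  withSeed(seed, {
    age <- stats::runif(nTotal, ageRange[1], ageRange[2])
    sex <- sample(c("F", "M"), nTotal, replace = TRUE)
    excl <- sample.int(nTotal) <= nExcluded
    seeds <- sample.int(.Machine$integer.max - 1L, nTotal)
  })
  data.frame(
    subject_id = sprintf("S%03d", seq_len(nTotal)),
    age_years = age,
    sex = sex,
    excluded = excl,
    exclusion_reason = ifelse(excl, "registration_segmentation_error", ""),
    seed = seeds,
    stringsAsFactors = FALSE
  )
}

#' Drop excluded subjects from a manifest
#'
#' @param manifest a cohort manifest from [makeCohort()].
#' @return the manifest restricted to `excluded == FALSE`; errors if no
#'   subject survives.
#' @export
filterCohort <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("subject_id", "excluded") %in% names(manifest)))
  if (any(manifest$excluded & !nzchar(manifest$exclusion_reason)))
    stop("excluded subjects must carry an exclusion reason")
  kept <- manifest[!manifest$excluded, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all subjects excluded; nothing to analyze")
  message(sprintf("excluded %d of %d subjects; %d analyzable",
                  sum(manifest$excluded), nrow(manifest), nrow(kept)))
  rownames(kept) <- NULL
  kept
}

#' Simulate region-level T1 means for a two-session cohort
#'
#' The fast, region-level counterpart of the full image chain: each subject's
#' pre-session region mean is drawn from the region's between-subject
#' distribution, and the 4-week value is the pre value perturbed by Gaussian
#' between-session measurement noise on the percent scale (the region's
#' `pct_change_sd_pct`) around a true percent drift (0 under the null).
#' Optionally a uniform gadolinium concentration shortens selected regions'
#' 4-week T1 via relaxation-rate additivity before the noise is applied.
#'
#' @param manifest analyzable cohort manifest (see [filterCohort()]); its
#'   per-subject seeds drive the draws.
#' @param regions a `region_spec` data.frame.
#' @param truePctChange true percent T1 drift between sessions (scalar or one
#'   per region); 0 is the null of no retention.
#' @param gadolinium optional list
#'   `list(regions =, concentrationMM =, relaxivityR1 =)` applying a uniform
#'   concentration to the named regions at 4 weeks.
#' @return long data.frame: `subject_id`, `region_name`, `group`, `pre_value`,
#'   `week4_value`, `percent_change`.
#' @export
simulateCohortMeans <- function(manifest, regions = defaultRegionTable("all"),
                                truePctChange = 0, gadolinium = NULL) {
  validateRegions(regions)
  nr <- nrow(regions)
  truePctChange <- rep_len(truePctChange, nr)
  gadConc <- rep(0, nr)
  gadR1 <- 4.0
  if (!is.null(gadolinium)) {
    stopifnot(all(gadolinium$regions %in% regions$name))
    gadConc[regions$name %in% gadolinium$regions] <- gadolinium$concentrationMM
    if (!is.null(gadolinium$relaxivityR1)) gadR1 <- gadolinium$relaxivityR1
  }
  ns <- nrow(manifest)
  preM <- matrix(NA_real_, ns, nr)
  wk4M <- matrix(NA_real_, ns, nr)
  shorten <- gadConc > 0
  for (i in seq_len(ns)) {
    withSeed(manifest$seed[i], {
      pre <- pmax(stats::rnorm(nr, regions$t1_mean_ms,
                               regions$t1_between_subject_sd_ms), 1)
      wk4 <- pre
      if (any(shorten))
        wk4[shorten] <- gadShortenT1(wk4[shorten], gadConc[shorten], gadR1)
      noisePct <- stats::rnorm(nr, truePctChange, regions$pct_change_sd_pct)
      wk4 <- wk4 * (1 + noisePct / 100)
    })
    preM[i, ] <- pre
    wk4M[i, ] <- wk4
  }
  out <- data.frame(
    subject_id = rep(manifest$subject_id, each = nr),
    region_name = rep(regions$name, ns),
    group = rep(regions$group, ns),
    pre_value = as.vector(t(preM)),
    week4_value = as.vector(t(wk4M)),
    stringsAsFactors = FALSE
  )
  out$percent_change <- percentChange(out$pre_value, out$week4_value)
  out
}
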