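#' Build a region dictionary
#'
#' A region dictionary is a data.frame with one row per named brain region and
#' the parameters the phantom generator and the regional cohort simulator
#' need: the population mean T1, the between-subject spread of subject-level
#' region means, the voxel-level spread within a region, and the
#' between-session noise scale on percent change.
#'
#' @param name character vector of region names.
#' @param label_id positive integer labels; 0 is reserved for background.
#' @param t1_mean_ms mean T1 in ms (> 0).
#' @param t1_between_subject_sd_ms between-subject SD of the region mean (ms).
#' @param t1_within_region_sd_ms voxel-level SD within the region (ms).
#' @param pct_change_sd_pct SD (in percent points) of the per-subject percent
#'   change between sessions under the null, i.e. measurement noise of the
#'   longitudinal pipeline.
#' @param group `"main"` or `"other"`, controlling report ordering.
#' @return data.frame of class `region_spec`.
#' @export
regionSpec <- function(name, label_id, t1_mean_ms,
                       t1_between_subject_sd_ms = 0,
                       t1_within_region_sd_ms = 0,
                       pct_change_sd_pct = 0,
                       group = "main") {
  df <- data.frame(
    name = as.character(name),
    label_id = as.integer(label_id),
    t1_mean_ms = as.numeric(t1_mean_ms),
    t1_between_subject_sd_ms = as.numeric(t1_between_subject_sd_ms),
    t1_within_region_sd_ms = as.numeric(t1_within_region_sd_ms),
    pct_change_sd_pct = as.numeric(pct_change_sd_pct),
    group = as.character(group),
    stringsAsFactors = FALSE
  )
  validateRegions(df)
  class(df) <- c("region_spec", "data.frame")
  df
}

validateRegions <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1)
  if (any(df$t1_mean_ms <= 0)) stop("t1_mean_ms must be > 0")
  if (any(df$t1_between_subject_sd_ms < 0) || any(df$t1_within_region_sd_ms < 0))
    stop("standard deviations must be >= 0")
  if (any(df$label_id <= 0L)) stop("label_id must be positive (0 is background)")
  if (anyDuplicated(df$label_id)) stop("label_id must be unique")
  if (anyDuplicated(df$name)) stop("region names must be unique")
  invisible(df)
}

#' Default brain region dictionary
#'
#' Region means and between-subject SDs of the pre-contrast T1 times of a
#' 76-participant 3T cohort, for the three composite main regions
#' (cerebral cortex, subcortical white matter, basal ganglia), the pallidum,
#' and ten lobar sub-regions; the `pct_change_sd_pct` column carries the
#' observed between-session percent-change SD of the same cohort, which the
#' regional simulator uses as its measurement-noise scale. Voxel-level
#' within-region SD defaults to 60 ms, a typical single-tissue spread at 3T.
#'
#' @param which `"phantom"` returns the four regions the default phantom
#'   hosts (the three main regions plus pallidum); `"main"` the three main
#'   regions; `"all"` all fourteen.
#' @param t1_within_region_sd_ms voxel-level SD applied to every region.
#' @return a `region_spec` data.frame, see [regionSpec()].
#' @examples
#' defaultRegionTable("phantom")
#' @export
defaultRegionTable <- function(which = c("phantom", "main", "all"),
                               t1_within_region_sd_ms = 60) {
  which <- match.arg(which)
  tab <- data.frame(
    name = c("cerebral_cortex", "subcortical_white_matter", "basal_ganglia",
             "frontal_gray_matter", "frontal_white_matter",
             "temporal_gray_matter", "temporal_white_matter",
             "parietal_gray_matter", "parietal_white_matter",
             "occipital_gray_matter", "occipital_white_matter",
             "insular_cortex", "subinsular_white_matter", "pallidum"),
    mean = c(1479.3, 1082.1, 1274.3,
             1493.1, 1085.2, 1478.7, 1115.4, 1485.8, 1032.2,
             1417.3, 1104.3, 1555.5, 1037.3, 1030.6),
    sd = c(61.2, 46.7, 55.0,
           67.5, 50.2, 63.4, 55.3, 66.1, 51.2,
           67.6, 59.9, 81.6, 47.1, 60.6),
    pct_sd = c(4.6, 2.9, 3.3,
               5.0, 3.1, 4.7, 4.2, 4.8, 3.3,
               4.5, 4.1, 6.3, 3.6, 6.9),
    group = c("main", "main", "main", rep("other", 11)),
    stringsAsFactors = FALSE
  )
  keep <- switch(which,
    phantom = c("cerebral_cortex", "subcortical_white_matter",
                "basal_ganglia", "pallidum"),
    main = c("cerebral_cortex", "subcortical_white_matter", "basal_ganglia"),
    all = tab$name
  )
  tab <- tab[match(keep, tab$name), , drop = FALSE]
  regionSpec(
    name = tab$name,
    label_id = seq_len(nrow(tab)),
    t1_mean_ms = tab$mean,
    t1_between_subject_sd_ms = tab$sd,
    t1_within_region_sd_ms = t1_within_region_sd_ms,
    pct_change_sd_pct = tab$pct_sd,
    group = tab$group
  )
}

#' Draw subject-specific region means
#'
#' Perturbs each region's mean T1 by a Gaussian between-subject effect with
#' the region's `t1_between_subject_sd_ms`, truncated at 1 ms, giving the
#' region dictionary of one simulated subject. With all between-subject SDs 0
#' the input is returned unchanged.
#'
#' @param regions a `region_spec` data.frame.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `region_spec` data.frame with subject-level `t1_mean_ms`.
#' @export
sampleSubjectRegions <- function(regions, seed) {
  validateRegions(regions)
  withSeed(seed, {
    shift <- stats::rnorm(nrow(regions), 0, regions$t1_between_subject_sd_ms)
  })
  out <- regions
  out$t1_mean_ms <- pmax(regions$t1_mean_ms + shift, 1)
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  eval.parent(substitute(expr))
}
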