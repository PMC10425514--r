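#' Region-wise T1 statistics and volumes
#'
#' Aggregates a fitted T1 map over a label volume on the same grid: the mean
#' and SD of T1 over the region's *valid* voxels, the valid-voxel count, and
#' the region volume in ml computed from *all* labelled voxels regardless of
#' fit validity (volume is a property of the segmentation, and its
#' between-session change is the co-registration accuracy diagnostic).
#'
#' @param t1Map a [T1Map-class].
#' @param labels 3-D integer array on the T1-map grid.
#' @param regions a `region_spec` data.frame naming the labels.
#' @param subjectId,session metadata columns for the output rows.
#' @return data.frame with one row per region: `subject_id`, `session`,
#'   `region_name`, `mean_t1_ms`, `sd_t1_ms`, `n_valid_voxels`,
#'   `n_voxels`, `volume_ml`. Regions with no valid voxel carry `NA` means.
#' @export
regionStats <- function(t1Map, labels, regions,
                        subjectId = NA_character_, session = NA_character_) {
  stopifnot(is(t1Map, "T1Map"))
  if (!identical(dim(labels), dim(t1Map@t1Ms)))
    stop("labels must be on the T1-map grid")
  validateRegions(regions)
  voxMl <- abs(det(t1Map@affine[1:3, 1:3])) / 1000  # mm^3 -> ml
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    sel <- labels == regions$label_id[i]
    nAll <- sum(sel)
    ok <- sel & t1Map@valid
    vals <- t1Map@t1Ms[ok]
    data.frame(
      subject_id = subjectId, session = session,
      region_name = regions$name[i],
      mean_t1_ms = if (length(vals)) mean(vals) else NA_real_,
      sd_t1_ms = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      n_valid_voxels = length(vals),
      n_voxels = nAll,
      volume_ml = nAll * voxMl,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Combine region statistics into composites
#'
#' Builds composite regions (e.g. cerebral cortex from the lobar
#' gray-matter rows) from member rows: the composite mean is the
#' valid-voxel-weighted mean of the member means, its SD the pooled SD, the
#' volume the sum of member volumes.
#'
#' @param rows output of [regionStats()] (a single subject/session).
#' @param recipe named list mapping composite name to member region names.
#' @return data.frame in the [regionStats()] layout, one row per composite.
#' @examples
#' \dontrun{
#' compositeRegions(rows, list(cerebral_cortex = c("frontal_gray_matter",
#'                                                 "temporal_gray_matter")))
#' }
#' @export
compositeRegions <- function(rows, recipe) {
  stopifnot(is.list(recipe), length(names(recipe)) == length(recipe))
  out <- lapply(names(recipe), function(cn) {
    members <- recipe[[cn]]
    missing <- setdiff(members, rows$region_name)
    if (length(missing))
      stop("composite '", cn, "' missing member region(s): ",
           paste(missing, collapse = ", "))
    m <- rows[match(members, rows$region_name), , drop = FALSE]
    n <- m$n_valid_voxels
    if (sum(n) == 0) {
      mu <- NA_real_; sdv <- NA_real_
    } else {
      mu <- sum(m$mean_t1_ms * n) / sum(n)
      # pooled second moment across members
      ss <- sum((n - 1) * ifelse(is.na(m$sd_t1_ms), 0, m$sd_t1_ms)^2 +
                  n * (m$mean_t1_ms - mu)^2, na.rm = TRUE)
      sdv <- if (sum(n) > 1) sqrt(ss / (sum(n) - 1)) else NA_real_
    }
    data.frame(
      subject_id = m$subject_id[1], session = m$session[1],
      region_name = cn, mean_t1_ms = mu, sd_t1_ms = sdv,
      n_valid_voxels = sum(n), n_voxels = sum(m$n_voxels),
      volume_ml = sum(m$volume_ml), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
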