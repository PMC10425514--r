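#' Default run configuration
#'
#' Assembles the configuration of an end-to-end run: cohort size, protocol,
#' region dictionary, optional gadolinium exposure, safety margin, phantom
#' geometry and the execution mode. Mode `"regional"` (default) draws
#' region-level session means directly from the cohort model — the scalable
#' path used for large simulation studies; mode `"voxel"` runs the full
#' image chain per subject (phantom, 4-D signal, voxelwise fit, synthetic
#' T1w registration, label resampling, aggregation) and is intended for
#' small cohorts.
#'
#' @param seed global integer seed; all per-subject seeds derive from it.
#' @param nSubjects total imaged subjects.
#' @param nExcluded subjects flagged excluded.
#' @param regions a `region_spec` data.frame; mode `"voxel"` requires it to
#'   fit the phantom geometry (use [defaultRegionTable()]`("phantom")`).
#' @param protocol an [LLProtocol-class].
#' @param gadolinium `NULL` for the null study, or
#'   `list(regions =, concentrationMM =, relaxivityR1 =)`.
#' @param marginPct safety margin in percent points.
#' @param mode `"regional"` or `"voxel"`.
#' @param shape,noiseSd,misalignMaxDeg,misalignMaxMm voxel-mode controls:
#'   phantom shape, magnitude noise (fraction of m0) and the amplitude of
#'   the random session-2 misalignment.
#' @param outputDir directory for reports, or `NULL` to skip writing.
#' @return list of class `run_config`.
#' @export
runConfig <- function(seed = 1L, nSubjects = 88L, nExcluded = 12L,
                      regions = defaultRegionTable("all"),
                      protocol = llProtocol(),
                      gadolinium = NULL, marginPct = 3.0,
                      mode = c("regional", "voxel"),
                      shape = c(24, 24, 16), noiseSd = 0.005,
                      misalignMaxDeg = 3, misalignMaxMm = 2,
                      outputDir = NULL) {
  cfg <- list(seed = as.integer(seed), nSubjects = as.integer(nSubjects),
              nExcluded = as.integer(nExcluded), regions = regions,
              protocol = protocol, gadolinium = gadolinium,
              marginPct = marginPct, mode = match.arg(mode),
              shape = as.integer(shape), noiseSd = noiseSd,
              misalignMaxDeg = misalignMaxDeg, misalignMaxMm = misalignMaxMm,
              outputDir = outputDir)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks the configuration without mutating anything and returns all
#' violations found (empty character vector when valid).
#'
#' @param config a [runConfig()] list.
#' @return character vector of violation messages.
#' @export
validateConfig <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(inherits(config, "run_config"), "config must come from runConfig()")
  chk(is.numeric(config$marginPct) && config$marginPct > 0,
      "marginPct must be > 0")
  chk(config$nSubjects >= 1L, "nSubjects must be positive")
  chk(config$nExcluded >= 0L && config$nExcluded <= config$nSubjects,
      "nExcluded must lie in [0, nSubjects]")
  chk(config$nSubjects - config$nExcluded >= 3L,
      "need at least 3 analyzable subjects for the t-tests")
  ok <- tryCatch({ validateRegions(config$regions); TRUE },
                 error = function(e) FALSE)
  chk(ok, "regions is not a valid region dictionary")
  chk(is(config$protocol, "LLProtocol"), "protocol must be an LLProtocol")
  if (is(config$protocol, "LLProtocol"))
    chk(config$protocol@nPhases >= 4L,
        "protocol must sample at least 4 phases: the three-parameter fit needs >= 4 points")
  if (!is.null(config$gadolinium)) {
    chk(all(config$gadolinium$regions %in% config$regions$name),
        "gadolinium regions must appear in the region dictionary")
    chk(is.numeric(config$gadolinium$concentrationMM) &&
          all(config$gadolinium$concentrationMM >= 0),
        "gadolinium concentration must be >= 0")
  }
  if (!is.null(config$outputDir))
    chk(dir.exists(dirname(config$outputDir)),
        "parent of outputDir must exist")
  if (config$mode == "voxel")
    chk(all(config$shape >= 16L), "voxel-mode shape must be >= 16 per axis")
  v
}

#' Run the two-session study end to end
#'
#' Simulates a Pre and a 4-week session for every analyzable subject, fits
#' and aligns (voxel mode), aggregates per region, and produces the report
#' set: region-wise T1 inference with safety-margin classification,
#' region-volume inference (voxel mode; the co-registration diagnostic),
#' age correlations, and forest-plot data. Fully deterministic given the
#' configuration, including its seed.
#'
#' @param config a validated [runConfig()].
#' @return list with `manifest` (cohort), `changes` (long per-subject region
#'   values), `t1Inference`, `volumeInference` (voxel mode only),
#'   `ageCorrelations`, `forest`, `files` (written paths with md5 checksums,
#'   when `outputDir` is set) and `timings` (seconds per stage).
#' @export
runNullStudy <- function(config = runConfig()) {
  viol <- validateConfig(config)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  manifest <- tick("cohort", makeCohort(config$nSubjects, config$nExcluded,
                                        seed = config$seed))
  analyzable <- suppressMessages(filterCohort(manifest))
  changes <- tick("simulate_measure", if (config$mode == "regional") {
    simulateCohortMeans(analyzable, config$regions,
                        gadolinium = config$gadolinium)
  } else {
    voxelModeChanges(analyzable, config)
  })
  t1Inf <- tick("stats", regionInference(changes, config$marginPct))
  volInf <- NULL
  if (config$mode == "voxel") {
    volChanges <- changes
    volChanges$pre_value <- changes$pre_volume_ml
    volChanges$week4_value <- changes$week4_volume_ml
    volInf <- regionInference(volChanges, config$marginPct)
  }
  ages <- analyzable$age_years[match(unique(changes$subject_id),
                                     analyzable$subject_id)]
  ageCor <- do.call(rbind, lapply(unique(changes$region_name), function(rn) {
    d <- changes[changes$region_name == rn, ]
    d <- d[match(unique(changes$subject_id), d$subject_id), ]
    pre <- ageCorrelation(ages, d$pre_value)
    wk4 <- ageCorrelation(ages, d$week4_value)
    pct <- ageCorrelation(ages, percentChange(d$pre_value, d$week4_value))
    data.frame(region_name = rn, r_pre = pre$r, p_pre = pre$p,
               r_week4 = wk4$r, p_week4 = wk4$p,
               r_pct = pct$r, p_pct = pct$p, stringsAsFactors = FALSE)
  }))
  forest <- forestTable(t1Inf, config$regions, config$marginPct)
  files <- NULL
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      manifest = writeTsv(manifest, file.path(config$outputDir, "cohort_manifest.tsv")),
      changes = writeTsv(changes, file.path(config$outputDir, "region_changes.tsv")),
      t1 = writeTsv(t1Inf, file.path(config$outputDir, "t1_inference.tsv")),
      age = writeTsv(ageCor, file.path(config$outputDir, "age_correlations.tsv")),
      forest = file.path(config$outputDir, "forest.json")
    )
    jsonlite::write_json(forest, paths[["forest"]], auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(volInf))
      paths <- c(paths, volume = writeTsv(
        volInf, file.path(config$outputDir, "volume_inference.tsv")))
    files <- data.frame(stage = names(paths), path = unname(paths),
                        md5 = unname(tools::md5sum(unname(paths))),
                        stringsAsFactors = FALSE)
    cfgSnap <- config
    cfgSnap$regions <- as.data.frame(config$regions)
    cfgSnap$protocol <- list(
      ti_min_ms = config$protocol@tiMinMs,
      phase_interval_ms = config$protocol@phaseIntervalMs,
      n_phases = config$protocol@nPhases,
      cycle_duration_ms = config$protocol@cycleDurationMs,
      excitation_angle_deg = config$protocol@excitationAngleDeg)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("t1retain")),
           config = unclass(cfgSnap), files = files,
           timings_sec = as.list(unlist(timings))),
      file.path(config$outputDir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(manifest = manifest, changes = changes, t1Inference = t1Inf,
       volumeInference = volInf, ageCorrelations = ageCor, forest = forest,
       files = files, timings = unlist(timings))
}

# Full image chain for one cohort: per subject simulate both sessions,
# fit voxelwise, register the week-4 synthetic T1w to the pre one, bring the
# week-4 map and labels onto the pre grid, and aggregate per region.
voxelModeChanges <- function(analyzable, config) {
  phRegions <- config$regions
  rows <- lapply(seq_len(nrow(analyzable)), function(i) {
    sid <- analyzable$subject_id[i]
    sseed <- analyzable$seed[i]
    subjRegions <- sampleSubjectRegions(phRegions, sseed)
    pre <- makePhantom(subjRegions, shape = config$shape, seed = sseed + 1L,
                       subjectId = sid, session = "Pre")
    withSeed(sseed + 2L, {
      mis <- c(stats::runif(3, -config$misalignMaxDeg, config$misalignMaxDeg),
               stats::runif(3, -config$misalignMaxMm, config$misalignMaxMm))
    })
    # the week-4 session is acquired afresh at a moved head pose: the scene
    # is regenerated analytically there, never resampled
    wk4 <- makePhantom(subjRegions, shape = config$shape, seed = sseed + 10L,
                       subjectId = sid, session = "Week4", pose = mis)
    if (!is.null(config$gadolinium)) {
      g <- config$gadolinium
      wk4 <- applyGadolinium(wk4, uniformGadoliniumField(
        wk4, g$concentrationMM, g$regions,
        if (is.null(g$relaxivityR1)) 4.0 else g$relaxivityR1))
    }
    fitOne <- function(ph, seedOff) {
      acq <- simulateVolume(ph, config$protocol, noiseSd = config$noiseSd,
                            seed = sseed + seedOff)
      fitVolume(acq, mask = ph@labels > 0L)
    }
    mapPre <- fitOne(pre, 3L)
    mapWk4 <- fitOne(wk4, 4L)
    # T1 statistics are native per session: each session's labels already
    # live on its own T1-map grid, so no intensity is ever resampled
    statPre <- regionStats(mapPre, pre@labels, subjRegions, sid, "Pre")
    statWk4 <- regionStats(mapWk4, wk4@labels, subjRegions, sid, "Week4")
    # registration of the synthetic T1w images brings the week-4 labels onto
    # the pre grid; the resulting volume change is the alignment diagnostic
    reg <- registerRigid(synthesizeT1w(mapWk4), synthesizeT1w(mapPre),
                         movingAffine = wk4@affine, fixedAffine = pre@affine)
    labWk4 <- resampleLabels(wk4@labels, wk4@affine, reg,
                             dim(pre@labels), pre@affine)
    voxMl <- abs(det(pre@affine[1:3, 1:3])) / 1000
    volWk4 <- vapply(subjRegions$label_id,
                     function(id) sum(labWk4 == id) * voxMl, numeric(1))
    data.frame(
      subject_id = sid,
      region_name = statPre$region_name,
      group = phRegions$group[match(statPre$region_name, phRegions$name)],
      pre_value = statPre$mean_t1_ms,
      week4_value = statWk4$mean_t1_ms,
      pre_volume_ml = statPre$volume_ml,
      week4_volume_ml = volWk4,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$percent_change <- percentChange(out$pre_value, out$week4_value)
  out
}
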