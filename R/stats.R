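#' Percent change between sessions
#'
#' @param pre pre-session value(s), > 0.
#' @param week4 follow-up value(s).
#' @return `100 * (week4 - pre) / pre`, vectorized.
#' @export
percentChange <- function(pre, week4) {
  if (any(pre <= 0)) stop("pre must be > 0")
  100 * (week4 - pre) / pre
}

#' Paired t-test on pre/follow-up values
#'
#' Two-tailed paired t-test (n - 1 degrees of freedom) of the
#' session difference; identical-by-construction sessions (zero-variance
#' differences) are an error rather than a p-value.
#'
#' @param pre,week4 equal-length numeric vectors, length >= 3.
#' @return list with `t`, `p`, `mean_diff`, `df`, `n`.
#' @export
pairedTTest <- function(pre, week4) {
  if (length(pre) != length(week4)) stop("pre and week4 must have equal length")
  if (length(pre) < 3) stop("need at least 3 pairs")
  d <- week4 - pre
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t statistic undefined")
  ht <- stats::t.test(week4, pre, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_diff = unname(ht$estimate), df = unname(ht$parameter),
       n = length(pre))
}

#' One-sample t-test of percent change
#'
#' Two-tailed test of the mean per-subject percent change against
#' `nullValue`, with the 95% confidence interval from t quantiles.
#'
#' @param pct numeric vector of percent changes, length >= 3.
#' @param nullValue null hypothesis value (default 0, no change).
#' @return list with `t`, `p`, `mean`, `sd`, `ci95` (length-2), `n`.
#' @export
oneSamplePctTest <- function(pct, nullValue = 0) {
  if (length(pct) < 3) stop("need at least 3 values")
  if (stats::sd(pct) == 0)
    stop("zero-variance percent changes: t statistic undefined")
  ht <- stats::t.test(pct, mu = nullValue)
  list(t = unname(ht$statistic), p = ht$p.value, mean = mean(pct),
       sd = stats::sd(pct), ci95 = as.numeric(ht$conf.int), n = length(pct))
}

#' Classify a mean percent change against the safety margin
#'
#' Changes within the pre-defined margin (default 3%, boundary inclusive)
#' are attributed to methodological variability rather than contrast
#' retention; shortening beyond the margin is the signature retention would
#' produce.
#'
#' @param meanPct mean percent change(s).
#' @param margin positive margin in percent points (default 3).
#' @return character vector: `"within_margin"`,
#'   `"exceeds_margin_shortening"` or `"exceeds_margin_lengthening"`.
#' @examples
#' classifyMargin(c(-0.98, -3.0, -4.2))
#' @export
classifyMargin <- function(meanPct, margin = 3.0) {
  if (margin <= 0) stop("margin must be > 0")
  ifelse(abs(meanPct) <= margin, "within_margin",
         ifelse(meanPct < 0, "exceeds_margin_shortening",
                "exceeds_margin_lengthening"))
}

#' Pearson correlation between age and a value
#'
#' @param ages,values equal-length numeric vectors, length >= 3.
#' @return list with `r`, `p` (two-tailed via the t transform), `n`.
#' @export
ageCorrelation <- function(ages, values) {
  if (length(ages) != length(values)) stop("lengths must match")
  if (length(ages) < 3) stop("need at least 3 observations")
  if (stats::sd(ages) == 0 || stats::sd(values) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(ages, values, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(ages))
}

#' Region-wise longitudinal inference
#'
#' The inferential core of the longitudinal analysis: per region, summary
#' statistics of both sessions, the paired t-test of the raw session
#' difference, the one-sample t-test of per-subject percent change with its
#' 95% CI, the safety-margin classification of the mean percent change, and
#' — as a diagnostic — the percent change of the session means (ratio of
#' means), which in general differs from the mean of per-subject percents
#' (the primary statistic). A Holm-adjusted percent-change p-value column is
#' appended as optional extra output; the primary analysis applies no
#' multiple-testing correction.
#'
#' @param changes long data.frame with columns `subject_id`, `region_name`,
#'   `pre_value`, `week4_value` (and optionally `group`), e.g. from
#'   [simulateCohortMeans()].
#' @param margin safety margin in percent points.
#' @return data.frame with one row per region: n, session means/SDs,
#'   `paired_p`, `mean_pct`, `sd_pct`, `pct_p`, `ci95_lo`, `ci95_hi`,
#'   `pct_of_means`, `margin_class`, `within_margin`, `pct_p_holm`.
#' @export
regionInference <- function(changes, margin = 3.0) {
  need <- c("subject_id", "region_name", "pre_value", "week4_value")
  stopifnot(all(need %in% names(changes)))
  regions <- unique(changes$region_name)
  rows <- lapply(regions, function(rn) {
    d <- changes[changes$region_name == rn, , drop = FALSE]
    pct <- percentChange(d$pre_value, d$week4_value)
    # zero-variance differences (e.g. identical region volumes across
    # sessions) leave the t statistic undefined; report NA rather than fail
    pt <- tryCatch(pairedTTest(d$pre_value, d$week4_value),
                   error = function(e) list(
                     t = NA_real_, p = NA_real_,
                     mean_diff = mean(d$week4_value - d$pre_value),
                     df = NA_real_, n = nrow(d)))
    ot <- tryCatch(oneSamplePctTest(pct),
                   error = function(e) list(
                     t = NA_real_, p = NA_real_, mean = mean(pct),
                     sd = stats::sd(pct), ci95 = c(NA_real_, NA_real_),
                     n = length(pct)))
    data.frame(
      region_name = rn,
      group = if ("group" %in% names(d)) d$group[1] else NA_character_,
      n = nrow(d),
      mean_pre = mean(d$pre_value), sd_pre = stats::sd(d$pre_value),
      mean_week4 = mean(d$week4_value), sd_week4 = stats::sd(d$week4_value),
      paired_t = pt$t, paired_p = pt$p,
      mean_pct = ot$mean, sd_pct = ot$sd, pct_t = ot$t, pct_p = ot$p,
      ci95_lo = ot$ci95[1], ci95_hi = ot$ci95[2],
      pct_of_means = percentChange(mean(d$pre_value), mean(d$week4_value)),
      margin_class = classifyMargin(ot$mean, margin),
      within_margin = abs(ot$mean) <= margin,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pct_p_holm <- stats::p.adjust(out$pct_p, method = "holm")
  out
}

#' Forest-plot table of region-wise percent change
#'
#' Orders the inference rows for reporting (main regions first, then the
#' sub-regions, in dictionary order when a region dictionary is supplied)
#' and returns the columns a forest plot needs: mean percent change, 95% CI
#' and the margin flags, including whether the whole CI lies inside the
#' margin band.
#'
#' @param inference output of [regionInference()].
#' @param regions optional `region_spec` table fixing the display order.
#' @param margin safety margin in percent points.
#' @return data.frame: `region_name`, `group`, `n`, `mean_pct`, `ci95_lo`,
#'   `ci95_hi`, `pct_p`, `margin_class`, `ci_within_margin`.
#' @export
forestTable <- function(inference, regions = NULL, margin = 3.0) {
  stopifnot(nrow(inference) >= 1)
  ord <- if (!is.null(regions)) {
    match(intersect(regions$name, inference$region_name),
          inference$region_name)
  } else {
    order(factor(inference$group, levels = c("main", "other")))
  }
  f <- inference[ord, c("region_name", "group", "n", "mean_pct",
                        "ci95_lo", "ci95_hi", "pct_p", "margin_class"),
                 drop = FALSE]
  f$ci_within_margin <- f$ci95_lo >= -margin & f$ci95_hi <= margin
  rownames(f) <- NULL
  f
}
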