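#' Baseline measurement variability (delta L/F)
#'
#' Percent deviation of a neuron's baseline (pre-stimulation) L/F points
#' from their mean. The default metric is the mean absolute percent
#' deviation, `100 * mean(|x - m|) / m`; the percent coefficient of
#' variation (`100 * sd(x) / m`, sample SD) is available as an alternative.
#' Both are invariant to rescaling the trace.
#'
#' @param baseline_lfs Numeric vector of at least two baseline L/F values
#'   with positive mean.
#' @param metric `"mad_pct"` (default) or `"cv_pct"`.
#' @return Variability in percent (>= 0).
#' @examples
#' baseline_variability(c(0.9, 1.0, 1.1))  # 6.667
#' @export
baseline_variability <- function(baseline_lfs,
                                 metric = c("mad_pct", "cv_pct")) {
  metric <- match.arg(metric)
  x <- as.double(baseline_lfs)
  if (length(x) < 2L) stop("need at least 2 baseline points", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("baseline values must be finite", call. = FALSE)
  }
  m <- mean(x)
  if (m <= 0) stop("baseline mean must be positive", call. = FALSE)
  switch(metric,
         mad_pct = 100 * mean(abs(x - m)) / m,
         cv_pct = 100 * stats::sd(x) / m)
}

#' Combined-population z-scores of baseline L/F
#'
#' To compare genotypes (e.g. control vs a mitochondrial mutant) the groups
#' are pooled, the combined mean and sample standard deviation (n - 1) of
#' the per-neuron baseline L/F means are computed, and each neuron's
#' standard score is `(x - mean) / sd`. Group labels are retained so the
#' groups' z-score distributions can be compared downstream.
#'
#' @param values_by_group Named list of numeric vectors (one per group) of
#'   per-neuron baseline L/F means; combined length >= 2 with nonzero
#'   spread.
#' @return Data frame with columns `group`, `value`, `z`. The z-scores of
#'   the combined set have mean 0 and sample SD 1.
#' @export
population_zscores <- function(values_by_group) {
  if (!is.list(values_by_group) || is.null(names(values_by_group)) ||
      any(names(values_by_group) == "")) {
    stop("`values_by_group` must be a named list of numeric vectors",
         call. = FALSE)
  }
  all_v <- unlist(values_by_group, use.names = FALSE)
  if (length(all_v) < 2L) stop("combined population needs >= 2 neurons",
                               call. = FALSE)
  if (anyNA(all_v) || any(!is.finite(all_v))) {
    stop("baseline values must be finite", call. = FALSE)
  }
  s <- stats::sd(all_v)
  if (s == 0) stop("combined population has zero spread", call. = FALSE)
  mu <- mean(all_v)
  data.frame(
    group = rep(names(values_by_group),
                vapply(values_by_group, length, integer(1))),
    value = all_v,
    z = (all_v - mu) / s
  )
}

#' Across-neuron average trace
#'
#' Per-timepoint arithmetic mean and standard error (sample SD / sqrt(n)) of
#' L/F over a list of traces sharing the same timepoint structure. Points
#' that failed QC or are invalid are excluded pointwise, so each timepoint
#' has its own contributor count; a timepoint with no valid contributor is
#' reported as `NA`.
#'
#' @param traces List of `synatp_trace` objects with identical timepoints.
#' @param use_ph_corrected Average `lf_ph_corrected` instead of raw `lf`.
#' @return Data frame: `timepoint`, `time_s`, `mean`, `sem`, `n`.
#' @export
average_trace <- function(traces, use_ph_corrected = FALSE) {
  stopifnot(length(traces) >= 1L)
  ok <- vapply(traces, inherits, logical(1), what = "synatp_trace")
  if (!all(ok)) stop("`traces` must be synatp_trace objects", call. = FALSE)
  tp <- traces[[1]]$points$timepoint
  for (tr in traces) {
    if (!identical(tr$points$timepoint, tp)) {
      stop("traces do not share a timepoint structure", call. = FALSE)
    }
  }
  col <- if (use_ph_corrected) "lf_ph_corrected" else "lf"
  vals <- sapply(traces, function(tr) {
    v <- tr$points[[col]]
    v[!(tr$points$qc_pass & tr$points$valid)] <- NA_real_
    v
  })
  vals <- matrix(vals, nrow = length(tp))
  n <- rowSums(is.finite(vals))
  mu <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  sdv <- apply(vals, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) >= 2L) stats::sd(r) else if (length(r) == 1L) 0 else NA_real_
  })
  data.frame(timepoint = tp, time_s = traces[[1]]$points$time_s,
             mean = mu, sem = ifelse(n > 0, sdv / sqrt(n), NA_real_), n = n)
}

#' Summarize one neuron's baseline
#'
#' Mean and variability of the L/F values of the first `baseline_n`
#' timepoints (valid, QC-passing points only).
#'
#' @param trace A `synatp_trace`.
#' @param config An [acquisition_config()] (baseline window and metric).
#' @return One-row data frame: `neuron_id`, `baseline_lf_mean`,
#'   `delta_lf_pct`, `n_baseline`.
#' @export
neuron_summary <- function(trace, config = acquisition_config()) {
  stopifnot(inherits(trace, "synatp_trace"))
  pts <- utils::head(trace$points, config$baseline_n)
  x <- pts$lf[pts$valid & pts$qc_pass]
  if (length(x) < 2L) {
    stop("neuron '", trace$neuron_id, "': fewer than 2 usable baseline points",
         call. = FALSE)
  }
  data.frame(
    neuron_id = trace$neuron_id,
    baseline_lf_mean = mean(x),
    delta_lf_pct = baseline_variability(x, config$delta_lf_metric),
    n_baseline = length(x)
  )
}

#' Cohort statistics over groups of neurons
#'
#' Computes, per neuron, the baseline L/F mean and variability (delta L/F),
#' then pools all groups for combined-population z-scores, and averages the
#' traces within each group. With a single group the z-scores are still
#' computed and the between-group comparison is omitted.
#'
#' @param traces List of `synatp_trace` objects.
#' @param groups Character vector of group labels, one per trace.
#' @param config An [acquisition_config()].
#' @param use_ph_corrected Average pH-corrected traces instead of raw.
#' @return A `synatp_cohort`: `summaries` (per-neuron data frame with
#'   `group` and `z`), `group_stats` (per-group mean/SD of z and delta L/F),
#'   `trace_mean` (named list of per-group [average_trace()] frames).
#' @export
cohort_stats <- function(traces, groups, config = acquisition_config(),
                         use_ph_corrected = FALSE) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != length(traces)) {
    stop("need one group label per trace", call. = FALSE)
  }
  summ <- do.call(rbind, lapply(traces, neuron_summary, config = config))
  summ$group <- groups
  # pooled scoring: a single combined population, group labels kept aside
  summ$z <- population_zscores(list(combined = summ$baseline_lf_mean))$z
  gs <- do.call(rbind, lapply(split(summ, summ$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_z = mean(d$z), sd_z = stats::sd(d$z),
               mean_delta_lf_pct = mean(d$delta_lf_pct),
               mean_baseline_lf = mean(d$baseline_lf_mean))
  }))
  rownames(gs) <- NULL
  tm <- lapply(split(traces, groups), average_trace,
               use_ph_corrected = use_ph_corrected)
  structure(list(summaries = summ, group_stats = gs, trace_mean = tm),
            class = "synatp_cohort")
}

#' @export
print.synatp_cohort <- function(x, ...) {
  cat(sprintf("<synatp_cohort> %d neurons in %d group(s)\n",
              nrow(x$summaries), nrow(x$group_stats)))
  print(x$group_stats)
  invisible(x)
}

#' Write a cohort report
#'
#' Writes the per-neuron summaries (with z-scores) as CSV and the per-group
#' average traces as JSON.
#'
#' @param cohort A `synatp_cohort`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort_report <- function(cohort, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cohort, "synatp_cohort"))
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(cohort$summaries, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(cohort$trace_mean, json_path, dataframe = "columns",
                         digits = NA, na = "null")
    written <- c(written, json_path)
  }
  invisible(written)
}
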