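#' Background-corrected total signal of one channel
#'
#' Sums the full-resolution intensities over the signal pixels (everything
#' that is neither background nor cell body, via the nearest-neighbour
#' upsampled masks) and subtracts `count x background level` for that
#' channel. This equals summing per-pixel background-corrected intensities
#' over the signal region, so a constant offset added to every pixel of a
#' channel cancels exactly.
#'
#' @param frame Full-resolution `synatp_frame` (or matrix) of the channel.
#' @param seg A `synatp_segmentation` for the same timepoint.
#' @param channel `"luminescence"` or `"fluorescence"` (selects which
#'   background level to subtract).
#' @return Net summed intensity (may be negative in pathological frames).
#' @export
compute_net_signal <- function(frame, seg,
                               channel = c("luminescence", "fluorescence")) {
  channel <- match.arg(channel)
  m <- if (is_frame(frame)) frame$pixels else frame
  stopifnot(inherits(seg, "synatp_segmentation"))
  sig <- upsample_mask(segmentation_masks(seg)$signal, seg$factor)
  if (!identical(dim(sig), dim(m))) {
    stop("segmentation geometry does not match the frame", call. = FALSE)
  }
  n <- sum(sig)
  if (n == 0L) stop("no signal pixels remain after masking", call. = FALSE)
  bg_level <- if (channel == "luminescence") seg$bg_level_lum else seg$bg_level_fluor
  sum(m[sig]) - n * bg_level
}

#' Luminescence-to-fluorescence ratio
#'
#' `L/F = (luminescence - background) / (fluorescence - background)`, the
#' expression-normalized ATP readout. A nonpositive net fluorescence makes
#' the ratio meaningless; the point is flagged invalid (`NA`) rather than
#' raising an error so a trace keeps its alignment with the stimulation
#' protocol.
#'
#' @param net_lum,net_fluor Background-corrected summed intensities.
#' @return The ratio, or `NA_real_` when `net_fluor <= 0`.
#' @examples
#' compute_lf(100, 200)
#' @export
compute_lf <- function(net_lum, net_fluor) {
  if (!is.finite(net_fluor) || net_fluor <= 0) return(NA_real_)
  net_lum / net_fluor
}

#' Dark-current quality control
#'
#' Signals near the EMCCD detection floor are unreliable. The check passes
#' when the mean intensity attributed to signal by the clustering step is at
#' least `qc_factor` (default 3) times the dark-current variance of the
#' camera; the boundary is inclusive. Camera-specific, so both the factor
#' and the variance are configurable.
#'
#' @param signal_cluster_mean Mean intensity of the signal cluster / region
#'   for the channel being checked (camera units).
#' @param config An [acquisition_config()] supplying `qc_factor` and
#'   `dark_current_variance`.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
quality_check <- function(signal_cluster_mean, config = acquisition_config()) {
  if (config$dark_current_variance < 0) {
    stop("dark-current variance must be nonnegative", call. = FALSE)
  }
  is.finite(signal_cluster_mean) &&
    signal_cluster_mean >= config$qc_factor * config$dark_current_variance
}

#' EM-gain adjustment of an L/F value
#'
#' Changing the camera's electron-multiplying gain rescales intensities
#' linearly; when `gain_enabled` the final L/F is multiplied by
#' `gain_coefficient` so ATP estimates stay comparable across sessions.
#'
#' @param lf L/F value(s).
#' @param config An [acquisition_config()].
#' @return Adjusted (or unchanged) L/F.
#' @export
apply_gain_adjustment <- function(lf, config = acquisition_config()) {
  if (config$gain_enabled) lf * config$gain_coefficient else lf
}

#' pH correction of an L/F trace
#'
#' Electrical stimulation acidifies the cytosol, which lowers luciferase
#' activity (pKa 7.03, close to cytosolic pH); the drop in L/F during
#' stimulation is corrected by per-timepoint multiplicative factors taken
#' from independent calibration. The raw trace is retained alongside.
#'
#' @param trace A `synatp_trace` from [build_trace()].
#' @param ph_factors Positive numeric vector, one factor per timepoint.
#' @return The trace with `lf_ph_corrected` filled in.
#' @export
apply_ph_correction <- function(trace, ph_factors) {
  stopifnot(inherits(trace, "synatp_trace"))
  n <- nrow(trace$points)
  if (length(ph_factors) != n) {
    stop("need one pH factor per timepoint (", n, "), got ",
         length(ph_factors), call. = FALSE)
  }
  if (any(ph_factors <= 0)) stop("pH factors must be positive", call. = FALSE)
  trace$points$lf_ph_corrected <- trace$points$lf * as.double(ph_factors)
  trace
}

#' Build the per-neuron L/F trace
#'
#' Runs segmentation (unless supplied) and quantification for every
#' timepoint of a series: net luminescence, net fluorescence, their ratio,
#' per-channel dark-current QC, optional gain adjustment and pH correction.
#' A timepoint whose segmentation degenerates (e.g. a featureless
#' luminescence frame) is flagged invalid, not dropped, so the trace stays
#' aligned with the stimulation protocol; the error is recorded in the
#' trace's `notes`.
#'
#' QC is evaluated per channel: luminescence uses the signal-cluster mean of
#' the clustered (downsampled) image, fluorescence the mean full-resolution
#' fluorescence intensity over the signal region; the point passes only if
#' both do.
#'
#' @param series A `synatp_series`.
#' @param segs Optional list of `synatp_segmentation`, one per timepoint
#'   (computed with [segment_timepoint()] otherwise).
#' @param config An [acquisition_config()]; defaults to the series' own.
#' @param cell_body_override Passed to [segment_timepoint()] when `segs` is
#'   not supplied; a user box applies to all timepoints.
#' @param stim_window Optional `c(start, end)` timepoint interval of
#'   electrical stimulation, carried in the trace for downstream plotting.
#' @return A `synatp_trace`: `neuron_id`, `points` data frame (one row per
#'   timepoint: `timepoint`, `time_s`, `net_lum`, `net_fluor`, `lf`,
#'   `lf_gain_adjusted`, `lf_ph_corrected`, `qc_pass`, `valid`),
#'   `stim_window`, `notes`.
#' @export
build_trace <- function(series, segs = NULL, config = NULL,
                        cell_body_override = "auto", stim_window = NULL) {
  stopifnot(inherits(series, "synatp_series"))
  if (is.null(config)) config <- series$config
  n <- length(series$timepoints)
  if (!is.null(segs) && length(segs) != n) {
    stop("need one segmentation per timepoint", call. = FALSE)
  }
  rows <- vector("list", n)
  notes <- character(0)
  for (i in seq_len(n)) {
    tp <- series$timepoints[[i]]
    row <- data.frame(
      timepoint = tp$index, time_s = tp$time_s,
      net_lum = NA_real_, net_fluor = NA_real_, lf = NA_real_,
      lf_gain_adjusted = NA_real_, lf_ph_corrected = NA_real_,
      qc_pass = FALSE, valid = FALSE
    )
    res <- tryCatch({
      seg <- if (is.null(segs)) {
        segment_timepoint(tp, config, cell_body_override)
      } else {
        segs[[i]]
      }
      # a pre-computed segmentation may itself be a captured failure
      if (inherits(seg, "error")) stop(conditionMessage(seg))
      net_l <- compute_net_signal(tp$luminescence, seg, "luminescence")
      net_f <- compute_net_signal(tp$fluorescence, seg, "fluorescence")
      lf <- compute_lf(net_l, net_f)
      sig_up <- upsample_mask(segmentation_masks(seg)$signal, seg$factor)
      qc_lum <- quality_check(seg$background$signal_cluster_mean, config)
      qc_fluor <- quality_check(mean(tp$fluorescence$pixels[sig_up]), config)
      list(net_l = net_l, net_f = net_f, lf = lf,
           qc = qc_lum && qc_fluor)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      notes <- c(notes, sprintf("timepoint %d: %s", tp$index,
                                conditionMessage(res)))
    } else {
      row$net_lum <- res$net_l
      row$net_fluor <- res$net_f
      row$lf <- res$lf
      row$valid <- is.finite(res$lf)
      row$qc_pass <- res$qc && row$valid
      if (config$gain_enabled) {
        row$lf_gain_adjusted <- apply_gain_adjustment(res$lf, config)
      }
    }
    rows[[i]] <- row
  }
  trace <- structure(
    list(neuron_id = series$neuron_id, points = do.call(rbind, rows),
         stim_window = stim_window, notes = notes),
    class = "synatp_trace"
  )
  if (!is.null(config$ph_factors)) {
    trace <- apply_ph_correction(trace, config$ph_factors)
  }
  trace
}

#' @export
print.synatp_trace <- function(x, ...) {
  cat(sprintf("<synatp_trace> neuron '%s', %d timepoints (%d valid, %d QC pass)\n",
              x$neuron_id, nrow(x$points), sum(x$points$valid),
              sum(x$points$qc_pass)))
  print(utils::head(x$points, 10))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.synatp_trace <- function(x, ...) {
  cbind(neuron_id = x$neuron_id, x$points)
}

#' Write a trace as CSV
#'
#' One row per timepoint with columns `neuron_id`, `timepoint`, `time_s`,
#' `net_lum`, `net_fluor`, `lf`, `lf_gain_adjusted`, `lf_ph_corrected`,
#' `qc_pass`. Identical traces serialize to byte-identical files.
#'
#' @param trace A `synatp_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$valid <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A `synatp_trace` (the `valid` flag is reconstructed as
#'   `is.finite(lf)`).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("neuron_id", "timepoint", "time_s", "net_lum", "net_fluor",
            "lf", "lf_gain_adjusted", "lf_ph_corrected", "qc_pass")
  if (!all(need %in% names(df))) {
    stop("not a trace CSV (missing columns): ", path, call. = FALSE)
  }
  pts <- df[setdiff(names(df), "neuron_id")]
  pts$valid <- is.finite(pts$lf)
  structure(
    list(neuron_id = as.character(df$neuron_id[1]), points = pts,
         stim_window = NULL, notes = character(0)),
    class = "synatp_trace"
  )
}
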