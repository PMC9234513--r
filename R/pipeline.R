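#' Analyze one neuron end to end
#'
#' Runs the full pipeline on an imaging series: per-timepoint segmentation
#' (background clustering + cell-body search on the luminescence channel),
#' quantification, QC, and corrections. Optionally writes the trace CSV, a
#' QC/log JSON (configuration hash, seed, package version, per-timepoint QC
#' outcomes) and per-timepoint overlay PNGs for the human review step of the
#' semiautomated workflow. Identical inputs, configuration and seed produce
#' byte-identical CSV output.
#'
#' @param input A `synatp_series`, or a directory containing TIFFs named
#'   `<neuron_id>_t<index>_<channel>.tif` (requires `neuron_id`).
#' @param config An [acquisition_config()].
#' @param cell_body_override `"auto"`, `"none"`, or a [cell_body_box()]
#'   applied to all timepoints (recorded with `source = "user"`).
#' @param output_dir Directory for outputs; `NULL` writes nothing.
#' @param write_overlays Also write `overlay_t<index>.png` review images.
#' @param neuron_id Needed when `input` is a directory.
#' @param stim_window Optional stimulation interval, carried in the trace.
#' @return Invisibly, a list with `trace` (a `synatp_trace`),
#'   `segmentations`, and `files` written.
#' @export
run_analyze <- function(input, config = acquisition_config(),
                        cell_body_override = "auto", output_dir = NULL,
                        write_overlays = FALSE, neuron_id = NULL,
                        stim_window = NULL) {
  series <- if (inherits(input, "synatp_series")) {
    input
  } else if (is.character(input) && dir.exists(input)) {
    if (is.null(neuron_id)) {
      stop("`neuron_id` is required when `input` is a directory", call. = FALSE)
    }
    read_series(input, neuron_id, config)
  } else {
    stop("`input` must be a synatp_series or an existing directory",
         call. = FALSE)
  }
  segs <- vector("list", length(series$timepoints))
  for (i in seq_along(segs)) {
    segs[[i]] <- tryCatch(
      segment_timepoint(series$timepoints[[i]], config, cell_body_override),
      error = function(e) e
    )
  }
  usable <- !vapply(segs, inherits, logical(1), what = "error")
  trace <- build_trace(series, segs = segs, config = config,
                       stim_window = stim_window)
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(output_dir, paste0(series$neuron_id, "_trace.csv"))
    write_trace_csv(trace, csv)
    log_path <- file.path(output_dir, paste0(series$neuron_id, "_log.json"))
    write_run_log(trace, config, log_path)
    files <- c(csv, log_path)
    if (write_overlays) {
      for (i in which(usable)) {
        p <- file.path(output_dir,
                       sprintf("%s_overlay_t%d.png", series$neuron_id,
                               series$timepoints[[i]]$index))
        overlay_png(segs[[i]], series$timepoints[[i]]$luminescence, p)
        files <- c(files, p)
      }
    }
  }
  invisible(list(trace = trace, segmentations = segs, files = files))
}

write_run_log <- function(trace, config, path) {
  cfg <- unclass(config)
  cfg$ph_factors <- if (is.null(cfg$ph_factors)) NULL else cfg$ph_factors
  log <- list(
    package = "synatp",
    version = as.character(utils::packageVersion("synatp")),
    seed = config$seed,
    config = cfg,
    config_hash = config_hash(config),
    neuron_id = trace$neuron_id,
    qc = data.frame(timepoint = trace$points$timepoint,
                    qc_pass = trace$points$qc_pass,
                    valid = trace$points$valid),
    notes = trace$notes
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(unclass(config))),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a segmentation review overlay
#'
#' PNG of the downsampled luminescence image (grey, contrast-stretched)
#' with non-background pixels tinted green and the cell-body box drawn in
#' red, for the user checkpoint that accepts or overrides the detected cell
#' body.
#'
#' @param seg A `synatp_segmentation`.
#' @param lum_frame The luminescence `synatp_frame` of that timepoint
#'   (used only for scaling context; the overlay is drawn at downsampled
#'   geometry).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
overlay_png <- function(seg, lum_frame, path) {
  stopifnot(inherits(seg, "synatp_segmentation"))
  m <- seg$downsampled$pixels
  rng <- range(m)
  g <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  img <- array(rep(g, 3L), dim = c(nrow(m), ncol(m), 3L))
  sig <- !seg$background$grid
  img[, , 2L][sig] <- pmin(1, img[, , 2L][sig] + 0.35)
  if (!is.null(seg$cell_body)) {
    b <- seg$cell_body
    rr <- b$row + c(1L, b$width_px)
    cc <- b$col + c(1L, b$width_px)
    rows <- b$row + seq_len(b$width_px)
    cols <- b$col + seq_len(b$width_px)
    img[rr, cols, 1L] <- 1; img[rr, cols, 2L] <- 0; img[rr, cols, 3L] <- 0
    img[rows, cc, 1L] <- 1; img[rows, cc, 2L] <- 0; img[rows, cc, 3L] <- 0
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Cohort analysis over trace files or traces
#'
#' Wraps [cohort_stats()] for batch use: accepts `synatp_trace` objects or
#' paths to trace CSVs, attaches group labels, and optionally writes the
#' cohort report (per-neuron CSV incl. z-scores, per-group average-trace
#' JSON).
#'
#' @param traces List of `synatp_trace` objects and/or CSV paths.
#' @param groups Character vector, one label per trace.
#' @param config An [acquisition_config()].
#' @param output_dir Directory for `cohort_summary.csv` and
#'   `cohort_traces.json`; `NULL` writes nothing.
#' @param use_ph_corrected Average pH-corrected traces.
#' @return Invisibly, the `synatp_cohort`.
#' @export
run_cohort <- function(traces, groups, config = acquisition_config(),
                       output_dir = NULL, use_ph_corrected = FALSE) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  traces <- lapply(traces, function(tr) {
    if (inherits(tr, "synatp_trace")) tr
    else if (is.character(tr)) read_trace_csv(tr)
    else stop("each trace must be a synatp_trace or a CSV path", call. = FALSE)
  })
  ch <- cohort_stats(traces, groups, config, use_ph_corrected)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_report(ch,
                        csv_path = file.path(output_dir, "cohort_summary.csv"),
                        json_path = file.path(output_dir, "cohort_traces.json"))
  }
  invisible(ch)
}
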