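#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page grayscale TIFF and returns one frame per
#' page, in page order, with intensities preserved bit-exactly (8/16-bit
#' unsigned integer or 32-bit float samples; values are held as doubles so
#' downstream arithmetic keeps fractional precision).
#'
#' @param path TIFF file path.
#' @param channel Channel tag to stamp on every frame.
#' @param exposure_s Optional exposure time recorded on the frames.
#' @return List of [new_frame()] objects, one per page.
#' @export
read_stack <- function(path, channel = c("luminescence", "fluorescence"),
                       exposure_s = NA_real_) {
  channel <- match.arg(channel)
  if (!file.exists(path)) {
    stop("cannot read TIFF, file not found: ", path, call. = FALSE)
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L]
      else stop("page ", i, " of '", path,
                "' is not grayscale (", dim(p)[3], " samples per pixel)",
                call. = FALSE)
    }
    storage.mode(p) <- "double"
    new_frame(p, channel, exposure_s)
  })
}

#' Write frames as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are rounded to the nearest integer and must fit the unsigned
#' 16-bit range; integer-valued data therefore round-trips bit-exactly
#' through [read_stack()].
#'
#' @param frames A `synatp_frame`, a matrix, or a list of either.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is_frame(frames) || is.matrix(frames)) frames <- list(frames)
  mats <- lapply(frames, function(f) {
    m <- if (is_frame(f)) f$pixels else f
    m <- round(m)
    if (any(m < 0) || any(m > 65535)) {
      stop("intensities outside the unsigned 16-bit range cannot be written",
           call. = FALSE)
    }
    m / 65535
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Average a fluorescence movie into a single image
#'
#' The 2 Hz / 10 s fluorescence acquisition yields a 20-frame movie that is
#' collapsed to its per-pixel arithmetic mean before any further analysis;
#' frame-to-frame read noise shrinks by sqrt(n).
#'
#' @param frames Nonempty list of `synatp_frame` objects sharing dimensions
#'   and channel.
#' @return A single `synatp_frame` holding the per-pixel mean (fractional
#'   values retained).
#' @examples
#' movie <- replicate(4, new_frame(matrix(5, 8, 8), "fluorescence"),
#'                    simplify = FALSE)
#' average_movie(movie)$pixels[1, 1]
#' @export
average_movie <- function(frames) {
  if (!is.list(frames) || !length(frames)) {
    stop("`frames` must be a nonempty list of frames", call. = FALSE)
  }
  frames <- lapply(frames, as_frame)
  h <- vapply(frames, `[[`, integer(1), "height")
  w <- vapply(frames, `[[`, integer(1), "width")
  ch <- vapply(frames, `[[`, character(1), "channel")
  if (length(unique(h)) != 1L || length(unique(w)) != 1L) {
    stop("frames in a movie must share dimensions", call. = FALSE)
  }
  if (length(unique(ch)) != 1L) {
    stop("frames in a movie must share one channel", call. = FALSE)
  }
  mean_px <- Reduce(`+`, lapply(frames, `[[`, "pixels")) / length(frames)
  new_frame(mean_px, ch[1], frames[[1]]$exposure_s)
}

#' Assemble a per-neuron imaging series from raw acquisitions
#'
#' Each timepoint of the reference protocol is a fluorescence movie (averaged
#' here via [average_movie()]) followed by one 60-s luminescence exposure.
#' Timestamps default to `index * 60` seconds, the 1-minute cadence of the
#' standard experiment.
#'
#' @param fluor_movies List of fluorescence movies (each a list of frames).
#' @param lum_frames List of luminescence frames, one per timepoint.
#' @param times_s Optional numeric vector of acquisition times in seconds.
#' @param neuron_id Label for the neuron.
#' @param config An [acquisition_config()].
#' @return A `synatp_series`.
#' @export
assemble_series <- function(fluor_movies, lum_frames, times_s = NULL,
                            neuron_id = "neuron",
                            config = acquisition_config()) {
  n <- length(fluor_movies)
  if (length(lum_frames) != n) {
    stop("counts differ: ", n, " fluorescence movies vs ",
         length(lum_frames), " luminescence frames", call. = FALSE)
  }
  if (is.null(times_s)) times_s <- (seq_len(n) - 1) * 60
  if (length(times_s) != n) {
    stop("`times_s` must have one entry per timepoint", call. = FALSE)
  }
  tps <- lapply(seq_len(n), function(i) {
    new_timepoint(
      index = i - 1L, time_s = times_s[i],
      fluorescence = average_movie(fluor_movies[[i]]),
      luminescence = as_frame(lum_frames[[i]], "luminescence")
    )
  })
  new_series(neuron_id, tps, config)
}

#' Read a series from per-timepoint TIFF files
#'
#' Batch loader for the file naming convention
#' `<neuron_id>_t<index>_<channel>.tif`, with `channel` one of `fluor`
#' (multi-page movie) and `lum` (single page). Timepoint indices are taken
#' from the file names; a timepoint missing either channel is an error that
#' enumerates the missing files.
#'
#' @param dir Directory containing the TIFF files.
#' @param neuron_id Neuron label (file name prefix).
#' @param config An [acquisition_config()].
#' @return A `synatp_series`.
#' @export
read_series <- function(dir, neuron_id, config = acquisition_config()) {
  pat <- sprintf("^%s_t(\\d+)_(fluor|lum)\\.tif+$", neuron_id)
  files <- list.files(dir, pattern = pat)
  if (!length(files)) {
    stop("no files matching '", neuron_id, "_t<index>_<channel>.tif' in ",
         dir, call. = FALSE)
  }
  m <- regmatches(files, regexec(pat, files))
  idx <- as.integer(vapply(m, `[`, character(1), 2))
  ch <- vapply(m, `[`, character(1), 3)
  tp_idx <- sort(unique(idx))
  missing <- character(0)
  for (i in tp_idx) {
    for (c2 in c("fluor", "lum")) {
      if (!any(idx == i & ch == c2)) {
        missing <- c(missing, sprintf("%s_t%d_%s.tif", neuron_id, i, c2))
      }
    }
  }
  if (length(missing)) {
    stop("incomplete timepoints; missing files: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fluor_movies <- lapply(tp_idx, function(i) {
    read_stack(file.path(dir, files[idx == i & ch == "fluor"][1]),
               "fluorescence")
  })
  lum_frames <- lapply(tp_idx, function(i) {
    pages <- read_stack(file.path(dir, files[idx == i & ch == "lum"][1]),
                        "luminescence")
    if (length(pages) != 1L) {
      stop("luminescence stack for timepoint ", i,
           " must be single-page", call. = FALSE)
    }
    pages[[1]]
  })
  assemble_series(fluor_movies, lum_frames, times_s = tp_idx * 60,
                  neuron_id = neuron_id, config = config)
}
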