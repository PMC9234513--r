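#' Construct a single-channel image frame
#'
#' A frame holds one 2-D grid of camera intensities (arbitrary EMCCD units)
#' together with its channel tag and exposure time. Frames are the atomic
#' unit of the pipeline: a timepoint pairs one averaged fluorescence frame
#' with one long-exposure luminescence frame.
#'
#' @param pixels Numeric matrix of nonnegative intensities. At least 8 pixels
#'   on each side; the standard acquisition is 512 x 512.
#' @param channel `"luminescence"` or `"fluorescence"`.
#' @param exposure_s Exposure time in seconds (60 s luminescence, 0.02 s
#'   fluorescence in the reference acquisition). `NA` when unknown.
#' @return An object of class `synatp_frame`.
#' @examples
#' f <- new_frame(matrix(100, 16, 16), "luminescence", exposure_s = 60)
#' dim(f$pixels)
#' @export
new_frame <- function(pixels,
                      channel = c("luminescence", "fluorescence"),
                      exposure_s = NA_real_) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  pixels <- matrix(as.double(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("frame intensities must be nonnegative and non-missing", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("frame must be at least 8 x 8 pixels", call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         channel = channel, exposure_s = as.double(exposure_s)),
    class = "synatp_frame"
  )
}

#' @export
print.synatp_frame <- function(x, ...) {
  cat(sprintf("<synatp_frame> %d x %d %s (exposure %s s), range [%.4g, %.4g]\n",
              x$height, x$width, x$channel,
              format(x$exposure_s), min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_frame <- function(x) inherits(x, "synatp_frame")

# Coerce a bare matrix to a frame; used so low-level operations accept either.
as_frame <- function(x, channel = "luminescence", exposure_s = NA_real_) {
  if (is_frame(x)) x else new_frame(x, channel, exposure_s)
}

#' Construct one imaging timepoint
#'
#' Pairs the movie-averaged fluorescence image with the single long-exposure
#' luminescence frame acquired at the same timepoint. Both frames must share
#' one geometry.
#'
#' @param index Zero-based timepoint index.
#' @param time_s Seconds from experiment start.
#' @param fluorescence,luminescence `synatp_frame` objects (the fluorescence
#'   one is the movie average).
#' @return An object of class `synatp_timepoint`.
#' @export
new_timepoint <- function(index, time_s, fluorescence, luminescence) {
  stopifnot(is_frame(fluorescence), is_frame(luminescence))
  if (fluorescence$channel != "fluorescence" ||
      luminescence$channel != "luminescence") {
    stop("channel tags do not match the slots they are assigned to",
         call. = FALSE)
  }
  if (fluorescence$height != luminescence$height ||
      fluorescence$width != luminescence$width) {
    stop("fluorescence and luminescence frames must share dimensions",
         call. = FALSE)
  }
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("`index` must be >= 0", call. = FALSE)
  structure(
    list(index = index, time_s = as.double(time_s),
         fluorescence = fluorescence, luminescence = luminescence),
    class = "synatp_timepoint"
  )
}

#' Construct a per-neuron imaging series
#'
#' @param neuron_id Label for the neuron (used in trace output).
#' @param timepoints List of `synatp_timepoint`, strictly increasing indices,
#'   all frames sharing one geometry.
#' @param config An [acquisition_config()] carried along for analysis.
#' @return An object of class `synatp_series`.
#' @export
new_series <- function(neuron_id, timepoints, config = acquisition_config()) {
  if (!length(timepoints)) stop("series needs at least one timepoint", call. = FALSE)
  ok <- vapply(timepoints, inherits, logical(1), what = "synatp_timepoint")
  if (!all(ok)) stop("`timepoints` must all be synatp_timepoint objects", call. = FALSE)
  idx <- vapply(timepoints, `[[`, integer(1), "index")
  if (any(diff(idx) <= 0L)) {
    stop("timepoint indices must be strictly increasing", call. = FALSE)
  }
  h <- vapply(timepoints, function(tp) tp$luminescence$height, integer(1))
  w <- vapply(timepoints, function(tp) tp$luminescence$width, integer(1))
  if (length(unique(h)) != 1L || length(unique(w)) != 1L) {
    stop("all timepoints must share one frame geometry", call. = FALSE)
  }
  structure(
    list(neuron_id = as.character(neuron_id), timepoints = timepoints,
         config = config),
    class = "synatp_series"
  )
}

#' @export
print.synatp_series <- function(x, ...) {
  tp <- x$timepoints[[1]]
  cat(sprintf("<synatp_series> neuron '%s': %d timepoints, %d x %d frames\n",
              x$neuron_id, length(x$timepoints),
              tp$luminescence$height, tp$luminescence$width))
  invisible(x)
}

#' @export
length.synatp_series <- function(x) length(x$timepoints)
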