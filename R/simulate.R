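#' Specify a synthetic dual-channel scene
#'
#' Parameters of a simulated Syn-ATP acquisition with known ground truth.
#' The defaults emulate the reference setup: 512 x 512 16-bit frames, a low
#' luminescence background and a much higher mCherry fluorescence
#' background, nerve-terminal puncta about 4 full-resolution pixels across
#' strung along straight "axon" paths, one bright cell body about 128
#' full-resolution pixels (32 downsampled pixels, about 50 um) across, a
#' 20-frame fluorescence movie per timepoint, and 8 one-minute timepoints.
#'
#' Puncta are centred on the 4 x 4 downsample grid so that each punctum
#' occupies exactly one downsampled pixel and the planted background mask is
#' unambiguous at the downsampled geometry; the cell body is rendered as a
#' grid-aligned square for the same reason. Per-channel punctum amplitudes
#' are tied together by `true_lf`: every planted pixel satisfies
#' `(lum - lum_background) = true_lf * (fluor - fluor_background)`, so the
#' planted net-signal ratio equals `true_lf` for any correct mask.
#'
#' @param side_px Full-resolution frame side (divisible by the downsample
#'   factor).
#' @param background_mean Named vector `c(luminescence=, fluorescence=)` of
#'   background offsets (camera units).
#' @param noise_sd Named vector of additive Gaussian noise SDs per channel.
#' @param dark_current_variance Planted dark-current pixel variance for
#'   [dark_frame_series()].
#' @param n_puncta Number of nerve-terminal puncta.
#' @param punctum_diameter_px Punctum diameter, full-resolution pixels.
#' @param punctum_intensity Mean fluorescence amplitude of a punctum above
#'   background; the luminescence amplitude is `true_lf` times the
#'   fluorescence amplitude.
#' @param punctum_amp_cv Coefficient of variation of the per-punctum
#'   amplitude, drawn from a Gamma distribution with mean
#'   `punctum_intensity` (default 0.5, i.e. shape 4), emulating
#'   terminal-to-terminal signal heterogeneity. `0` plants identical
#'   amplitudes — the fully separable scene used for exact-recovery checks,
#'   since arbitrarily dim terminals are genuinely ambiguous to any
#'   intensity clustering.
#' @param soma_present Plant a cell body?
#' @param soma_diameter_px Cell-body side, full-resolution pixels (divisible
#'   by the downsample factor).
#' @param soma_intensity Fluorescence amplitude of the cell body above
#'   background (default twice `punctum_intensity`, so the soma dominates
#'   the sliding-window search).
#' @param true_lf Planted net luminescence / net fluorescence ratio.
#' @param n_timepoints Number of timepoints in the series.
#' @param n_frames_per_movie Frames per fluorescence movie (20 = 2 Hz for
#'   10 s).
#' @param seed Integer seed; a fixed seed makes the scene bit-reproducible.
#' @return A `synatp_scene_spec` list.
#' @export
scene_spec <- function(side_px = 512L,
                       background_mean = c(luminescence = 100,
                                           fluorescence = 900),
                       noise_sd = c(luminescence = 4, fluorescence = 12),
                       dark_current_variance = 25,
                       n_puncta = 150L,
                       punctum_diameter_px = 4L,
                       punctum_intensity = 600,
                       punctum_amp_cv = 0.5,
                       soma_present = TRUE,
                       soma_diameter_px = 128L,
                       soma_intensity = 2 * punctum_intensity,
                       true_lf = 0.1,
                       n_timepoints = 8L,
                       n_frames_per_movie = 20L,
                       seed = 1L) {
  spec <- list(
    side_px = as.integer(side_px),
    background_mean = background_mean,
    noise_sd = noise_sd,
    dark_current_variance = as.double(dark_current_variance),
    n_puncta = as.integer(n_puncta),
    punctum_diameter_px = as.integer(punctum_diameter_px),
    punctum_intensity = as.double(punctum_intensity),
    punctum_amp_cv = as.double(punctum_amp_cv),
    soma_present = isTRUE(soma_present),
    soma_diameter_px = as.integer(soma_diameter_px),
    soma_intensity = as.double(soma_intensity),
    true_lf = as.double(true_lf),
    n_timepoints = as.integer(n_timepoints),
    n_frames_per_movie = as.integer(n_frames_per_movie),
    seed = as.integer(seed)
  )
  nm <- c("luminescence", "fluorescence")
  if (!all(nm %in% names(spec$background_mean)) ||
      !all(nm %in% names(spec$noise_sd))) {
    stop("`background_mean` and `noise_sd` need 'luminescence' and ",
         "'fluorescence' entries", call. = FALSE)
  }
  stopifnot(
    spec$side_px >= 8L,
    all(spec$background_mean > 0), all(spec$noise_sd >= 0),
    spec$dark_current_variance >= 0,
    spec$n_puncta >= 0L, spec$punctum_diameter_px >= 1L,
    spec$punctum_intensity > 0, spec$punctum_amp_cv >= 0,
    spec$soma_intensity > 0,
    spec$true_lf > 0, spec$n_timepoints >= 1L,
    spec$n_frames_per_movie >= 1L
  )
  if (spec$punctum_diameter_px > spec$side_px ||
      (spec$soma_present && spec$soma_diameter_px >= spec$side_px)) {
    stop("planted objects do not fit inside the frame", call. = FALSE)
  }
  class(spec) <- "synatp_scene_spec"
  spec
}

#' Generate a synthetic imaging series with ground truth
#'
#' Renders the noise-free amplitude image (puncta along randomly oriented
#' straight axon paths, optional cell body), derives both channels from it
#' (see [scene_spec()] for the `true_lf` coupling), then emits per timepoint
#' a fluorescence movie of independent noisy replicates and one noisy
#' luminescence frame. Deterministic for a fixed `spec$seed`; the caller's
#' RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @param config An [acquisition_config()] (supplies the downsample factor
#'   linking full-resolution truth to the downsampled ground-truth mask).
#' @return List with `series` (a `synatp_series`) and `truth`, a
#'   `synatp_ground_truth`: `background_mask_true` (downsampled logical
#'   grid, `TRUE` where the underlying block holds no planted signal),
#'   `soma_box_true` (downsampled [cell_body_box()] or `NULL`),
#'   `background_levels_true`, `lf_true`.
#' @export
generate_scene <- function(spec, config = acquisition_config()) {
  stopifnot(inherits(spec, "synatp_scene_spec"))
  f <- config$downsample_factor
  side <- spec$side_px
  if (side %% f != 0L) {
    stop("frame side must be divisible by the downsample factor", call. = FALSE)
  }
  B <- side %/% f
  with_preserved_seed(spec$seed, {
    amp <- matrix(0, side, side)  # fluorescence amplitude above background
    soma_box <- NULL
    soma_blocks <- matrix(FALSE, B, B)
    if (spec$soma_present) {
      if (spec$soma_diameter_px %% f != 0L) {
        stop("`soma_diameter_px` must be divisible by the downsample factor",
             call. = FALSE)
      }
      wd <- spec$soma_diameter_px %/% f
      if (wd + 2L >= B) stop("cell body too large for the frame", call. = FALSE)
      r0 <- sample.int(B - wd - 2L, 1L)  # 1-based block index, 1 block margin
      c0 <- sample.int(B - wd - 2L, 1L)
      soma_blocks[r0 + seq_len(wd) - 1L, c0 + seq_len(wd) - 1L] <- TRUE
      rows <- ((r0 - 1L) * f + 1L):((r0 - 1L + wd) * f)
      cols <- ((c0 - 1L) * f + 1L):((c0 - 1L + wd) * f)
      amp[rows, cols] <- spec$soma_intensity
      soma_box <- cell_body_box(r0 - 1L, c0 - 1L, wd, source = "truth")
    }
    if (spec$n_puncta > 0L) {
      blocks <- place_puncta_blocks(B, spec$n_puncta, soma_blocks)
      amps <- if (spec$punctum_amp_cv == 0) {
        rep(spec$punctum_intensity, nrow(blocks))
      } else {
        shape <- 1 / spec$punctum_amp_cv^2
        stats::rgamma(nrow(blocks), shape = shape,
                      scale = spec$punctum_intensity / shape)
      }
      disc <- punctum_disc(f, spec$punctum_diameter_px)
      for (k in seq_len(nrow(blocks))) {
        rows <- (blocks[k, 1L] - 1L) * f + seq_len(f)
        cols <- (blocks[k, 2L] - 1L) * f + seq_len(f)
        amp[rows, cols][disc] <- amp[rows, cols][disc] + amps[k]
      }
    }
    bg_l <- spec$background_mean[["luminescence"]]
    bg_f <- spec$background_mean[["fluorescence"]]
    clean_f <- bg_f + amp
    clean_l <- bg_l + spec$true_lf * amp
    sd_l <- spec$noise_sd[["luminescence"]]
    sd_f <- spec$noise_sd[["fluorescence"]]
    noisy <- function(clean, sd) {
      if (sd == 0) clean
      else pmax(clean + matrix(stats::rnorm(side * side, sd = sd), side, side), 0)
    }
    fluor_movies <- vector("list", spec$n_timepoints)
    lum_frames <- vector("list", spec$n_timepoints)
    for (t in seq_len(spec$n_timepoints)) {
      fluor_movies[[t]] <- lapply(seq_len(spec$n_frames_per_movie), function(k) {
        new_frame(noisy(clean_f, sd_f), "fluorescence", exposure_s = 0.02)
      })
      lum_frames[[t]] <- new_frame(noisy(clean_l, sd_l), "luminescence",
                                   exposure_s = 60)
    }
    series <- assemble_series(fluor_movies, lum_frames,
                              neuron_id = sprintf("sim%d", spec$seed),
                              config = config)
    block_has_signal <- block_max(amp, f) > 0
    truth <- structure(
      list(
        background_mask_true = !block_has_signal,
        soma_box_true = soma_box,
        background_levels_true = c(luminescence = bg_l, fluorescence = bg_f),
        lf_true = spec$true_lf
      ),
      class = "synatp_ground_truth"
    )
    list(series = series, truth = truth)
  })
}

block_max <- function(m, block) {
  R <- nrow(m) %/% block
  C <- ncol(m) %/% block
  a <- array(m, dim = c(block, R, block, C))
  apply(a, c(2L, 4L), max)
}

# Punctum footprint inside one f x f block: a centred disc of the given
# diameter (clipped to the block).
punctum_disc <- function(f, diameter) {
  ctr <- (f + 1) / 2
  d2 <- outer((seq_len(f) - ctr)^2, (seq_len(f) - ctr)^2, `+`)
  inc <- d2 < (diameter / 2)^2
  if (!any(inc)) inc[ceiling(f / 2), ceiling(f / 2)] <- TRUE
  inc
}

# Choose punctum block positions along straight axon-like paths crossing the
# downsampled grid, skipping the cell body; at most one punctum per block.
place_puncta_blocks <- function(B, n, exclude) {
  taken <- exclude
  out <- matrix(0L, 0L, 2L)
  spacing <- 2L  # blocks between consecutive puncta along an axon
  guard <- 0L
  while (nrow(out) < n && guard < 200L) {
    guard <- guard + 1L
    p0 <- stats::runif(2, 1, B)
    ang <- stats::runif(1, 0, pi)
    dir <- c(cos(ang), sin(ang))
    tt <- seq(-1.5 * B, 1.5 * B, by = 1)
    pts <- cbind(round(p0[1] + tt * dir[1]), round(p0[2] + tt * dir[2]))
    keep <- pts[, 1L] >= 1 & pts[, 1L] <= B & pts[, 2L] >= 1 & pts[, 2L] <= B
    pts <- unique(pts[keep, , drop = FALSE])
    if (!nrow(pts)) next
    pts <- pts[seq(1L, nrow(pts), by = spacing), , drop = FALSE]
    for (k in seq_len(nrow(pts))) {
      r <- pts[k, 1L]; c2 <- pts[k, 2L]
      if (!taken[r, c2]) {
        taken[r, c2] <- TRUE
        out <- rbind(out, c(r, c2))
        if (nrow(out) >= n) break
      }
    }
  }
  if (nrow(out) < n) {
    free <- which(!taken)
    extra <- free[seq_len(min(n - nrow(out), length(free)))]
    out <- rbind(out, cbind((extra - 1L) %% B + 1L, (extra - 1L) %/% B + 1L))
  }
  out
}

#' Simulate signal-free dark frames
#'
#' Frames containing only camera dark current, for calibrating the
#' dark-current variance used by [quality_check()]. Pixels are drawn around
#' a small fixed offset with variance `spec$dark_current_variance`.
#'
#' @param spec A [scene_spec()] (supplies the variance, frame side and
#'   seed).
#' @param n_frames Number of dark frames (>= 2).
#' @return List of `synatp_frame`; pooled pixel variance estimates the
#'   planted value.
#' @export
dark_frame_series <- function(spec, n_frames = 10L) {
  stopifnot(inherits(spec, "synatp_scene_spec"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("need at least 2 dark frames", call. = FALSE)
  v <- spec$dark_current_variance
  offset <- max(50, 10 * sqrt(v))
  side <- spec$side_px
  with_preserved_seed(spec$seed + 101L, {
    lapply(seq_len(n_frames), function(i) {
      px <- if (v == 0) matrix(offset, side, side)
      else pmax(matrix(stats::rnorm(side * side, offset, sqrt(v)), side, side), 0)
      new_frame(px, "luminescence", exposure_s = 60)
    })
  })
}

#' Estimate dark-current variance from dark frames
#'
#' Pooled pixel variance around each frame's own mean (frame-wise means
#' absorb slow offset drift).
#'
#' @param frames List of dark `synatp_frame`s.
#' @return Variance estimate in camera units squared.
#' @export
estimate_dark_variance <- function(frames) {
  stopifnot(length(frames) >= 1L)
  devs <- unlist(lapply(frames, function(f) {
    as.vector(f$pixels) - mean(f$pixels)
  }))
  sum(devs^2) / (length(devs) - length(frames))
}

#' Intersection-over-union of two cell-body boxes
#'
#' @param a,b `synatp_cellbody` boxes on the same grid.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  stopifnot(inherits(a, "synatp_cellbody"), inherits(b, "synatp_cellbody"))
  ir <- max(0L, min(a$row + a$width_px, b$row + b$width_px) - max(a$row, b$row))
  ic <- max(0L, min(a$col + a$width_px, b$col + b$width_px) - max(a$col, b$col))
  inter <- ir * ic
  union <- a$width_px^2 + b$width_px^2 - inter
  inter / union
}

#' Write a scene to disk as TIFF fixtures with a ground-truth sidecar
#'
#' Writes `<id>_t<index>_fluor.tif` / `<id>_t<index>_lum.tif` per timepoint
#' (readable with [read_series()]) plus `<id>_truth.json`. Movie frames are
#' rounded to 16-bit integers on write.
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if missing).
#' @param spec The [scene_spec()] used (echoed into the sidecar).
#' @return Invisibly, the sidecar path.
#' @export
write_scene <- function(scene, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- scene$series$neuron_id
  for (tp in scene$series$timepoints) {
    # the averaged fluorescence image is what the series retains; persist it
    # as a single-page stack alongside the luminescence frame
    write_stack(tp$fluorescence,
                file.path(dir, sprintf("%s_t%d_fluor.tif", id, tp$index)))
    write_stack(tp$luminescence,
                file.path(dir, sprintf("%s_t%d_lum.tif", id, tp$index)))
  }
  truth <- scene$truth
  sidecar <- list(
    neuron_id = id,
    lf_true = truth$lf_true,
    background_levels_true = as.list(truth$background_levels_true),
    soma_box_true = if (is.null(truth$soma_box_true)) NULL else
      unclass(truth$soma_box_true),
    background_mask_true_rle = rle_encode(truth$background_mask_true),
    mask_dim = dim(truth$background_mask_true),
    spec = if (is.null(spec)) NULL else unclass(spec)
  )
  path <- file.path(dir, sprintf("%s_truth.json", id))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# run-length encoding of a logical matrix (column-major), for JSON sidecars
rle_encode <- function(grid) {
  r <- rle(as.vector(grid))
  list(lengths = r$lengths, values = r$values)
}
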