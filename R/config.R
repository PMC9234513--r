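#' Acquisition and analysis configuration
#'
#' Bundles the camera/optics constants and the analysis parameters of the
#' pipeline. Defaults reproduce the reference acquisition: 16.4 um physical
#' camera pixels behind a 40x objective (0.41 um/pixel at the sample),
#' 4-fold block-median downsampling of 512 x 512 frames to 128 x 128
#' (1.64 um per downsampled pixel), a 32-downsampled-pixel (about 50 um)
#' cell-body search window, and a quality-control threshold of 3 times the
#' EMCCD dark-current variance.
#'
#' @param camera_pixel_um Physical camera pixel size in micrometres.
#' @param magnification Objective magnification.
#' @param downsample_factor Block side for the median downsample (512 -> 128
#'   at the default 4).
#' @param smooth Logical; additionally replace every 4 x 4 tile of the
#'   downsampled image by its median (geometry preserved) before clustering.
#'   Off by default: the tile median of 16 downsampled pixels suppresses
#'   isolated noise but also erases nerve-terminal-scale objects, which
#'   occupy about one downsampled pixel. See the methods vignette.
#' @param smoothing_block Tile side for the optional smoothing stage.
#' @param cell_body_width_px Default cell-body window side, in downsampled
#'   pixels (32 is about 50 um at the default optics).
#' @param qc_factor Quality control passes when the signal-cluster mean is at
#'   least `qc_factor` times `dark_current_variance`.
#' @param dark_current_variance Pixel variance of signal-free (dark) frames,
#'   camera units squared; camera-specific, measurable with
#'   [dark_frame_series()].
#' @param gain_enabled,gain_coefficient When enabled, final L/F values are
#'   multiplied by `gain_coefficient` to compensate linear intensity changes
#'   such as a different EM-gain setting.
#' @param ph_factors Optional numeric vector of per-timepoint multiplicative
#'   pH correction factors (luciferase activity is pH sensitive during
#'   electrical stimulation); `NULL` means no correction.
#' @param baseline_n Number of initial timepoints treated as the
#'   pre-stimulation baseline for variability statistics.
#' @param seed Integer seed controlling the k-means restarts (and any other
#'   stochastic step), for reproducible segmentations.
#' @param delta_lf_metric Baseline-variability metric: `"mad_pct"` (mean
#'   absolute percent deviation from the baseline mean, default) or
#'   `"cv_pct"` (percent coefficient of variation).
#' @param cluster_method `"kmeans"` (restarted Lloyd/Hartigan-Wong) or
#'   `"threshold"` (exhaustive 1-D within-cluster-SSE scan; deterministic and
#'   provably optimal). The two agree on all tested inputs.
#' @return A list with class `synatp_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$cell_body_width_px
#' @export
acquisition_config <- function(camera_pixel_um = 16.4,
                               magnification = 40,
                               downsample_factor = 4L,
                               smooth = FALSE,
                               smoothing_block = 4L,
                               cell_body_width_px = 32L,
                               qc_factor = 3,
                               dark_current_variance = 25,
                               gain_enabled = FALSE,
                               gain_coefficient = 1,
                               ph_factors = NULL,
                               baseline_n = 3L,
                               seed = 1L,
                               delta_lf_metric = c("mad_pct", "cv_pct"),
                               cluster_method = c("kmeans", "threshold")) {
  cfg <- list(
    camera_pixel_um = as.double(camera_pixel_um),
    magnification = as.double(magnification),
    downsample_factor = as.integer(downsample_factor),
    smooth = isTRUE(smooth),
    smoothing_block = as.integer(smoothing_block),
    cell_body_width_px = as.integer(cell_body_width_px),
    qc_factor = as.double(qc_factor),
    dark_current_variance = as.double(dark_current_variance),
    gain_enabled = isTRUE(gain_enabled),
    gain_coefficient = as.double(gain_coefficient),
    ph_factors = if (is.null(ph_factors)) NULL else as.double(ph_factors),
    baseline_n = as.integer(baseline_n),
    seed = as.integer(seed),
    delta_lf_metric = match.arg(delta_lf_metric),
    cluster_method = match.arg(cluster_method)
  )
  class(cfg) <- "synatp_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$camera_pixel_um > 0, cfg$magnification > 0,
    cfg$downsample_factor >= 1L, cfg$smoothing_block >= 1L,
    cfg$cell_body_width_px >= 1L,
    cfg$qc_factor > 0, cfg$dark_current_variance >= 0,
    cfg$gain_coefficient > 0, cfg$baseline_n >= 2L
  )
  if (!is.null(cfg$ph_factors) && any(cfg$ph_factors <= 0)) {
    stop("all pH correction factors must be positive", call. = FALSE)
  }
  cfg
}

#' Micrometres per downsampled pixel
#'
#' `camera_pixel_um / magnification * downsample_factor`; 1.64 um with the
#' defaults, so the 32-pixel cell-body window spans about 50 um.
#'
#' @param config An [acquisition_config()].
#' @return Micrometres per downsampled pixel.
#' @export
downsampled_pixel_um <- function(config = acquisition_config()) {
  config$camera_pixel_um / config$magnification * config$downsample_factor
}

#' Read / write a configuration as YAML
#'
#' `read_config()` loads a YAML file and merges it over the defaults of
#' [acquisition_config()]; unknown keys are an error so typos do not silently
#' fall back to defaults. `write_config()` serializes a configuration.
#'
#' @param path YAML file path.
#' @param config A `synatp_config`.
#' @return `read_config()` returns a `synatp_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(acquisition_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(acquisition_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synatp_config"))
  out <- unclass(config)
  out$ph_factors <- if (is.null(out$ph_factors)) NULL else as.list(out$ph_factors)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.synatp_config <- function(x, ...) {
  cat("<synatp_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

# Run `code` under a fixed seed, leaving the caller's RNG state untouched.
with_preserved_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
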