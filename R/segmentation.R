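#' Block-median downsampling
#'
#' Partitions the frame into `factor` x `factor` blocks and represents each
#' block by its median (even counts: mean of the two central order
#' statistics). At the default factor 4 a 512 x 512 frame becomes 128 x 128,
#' which suppresses single-pixel noise while keeping nerve terminals
#' (about 4 full-resolution pixels across) at roughly one output pixel.
#'
#' @param frame A `synatp_frame` or numeric matrix; sides must divide evenly
#'   by `factor` (no implicit cropping).
#' @param factor Integer block side, >= 1.
#' @param config Optional [acquisition_config()] used to record the physical
#'   size of a downsampled pixel.
#' @return A `synatp_downsampled` object: `pixels` matrix, `factor`,
#'   `physical_pixel_um`.
#' @examples
#' d <- block_median_downsample(matrix(7, 16, 16), 4)
#' dim(d$pixels)
#' @export
block_median_downsample <- function(frame, factor = 4L,
                                    config = acquisition_config()) {
  m <- if (is_frame(frame)) frame$pixels else frame
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (nrow(m) %% factor != 0L || ncol(m) %% factor != 0L) {
    stop(sprintf("frame sides (%d x %d) are not divisible by factor %d",
                 nrow(m), ncol(m), factor), call. = FALSE)
  }
  out <- block_median(m, factor)
  structure(
    list(pixels = out, factor = factor,
         physical_pixel_um = config$camera_pixel_um / config$magnification *
           factor),
    class = "synatp_downsampled"
  )
}

# median of every `block` x `block` tile, returned at tile resolution
block_median <- function(m, block) {
  if (block == 1L) return(m)
  R <- nrow(m) %/% block
  C <- ncol(m) %/% block
  a <- array(m, dim = c(block, R, block, C))
  apply(a, c(2L, 4L), stats::median)
}

#' Geometry-preserving median smoothing
#'
#' Replaces every `block` x `block` tile of a downsampled image by that
#' tile's median, keeping the geometry unchanged (a 128 x 128 image still
#' flattens to 16,384 entries for clustering). At the default 4-pixel tile
#' on 1.64-um downsampled pixels each region spans about 6.6 x 6.6 um.
#' Optional preprocessing before [cluster_background()]; see
#' [acquisition_config()] for why it is off by default.
#'
#' @param img A `synatp_downsampled` (or numeric matrix); sides must divide
#'   evenly by `block`.
#' @param block Integer tile side.
#' @return Same type as `img`, same dimensions, tile-median values.
#' @export
block_median_smooth <- function(img, block = 4L) {
  m <- if (inherits(img, "synatp_downsampled")) img$pixels else img
  block <- as.integer(block)
  if (block < 1L) stop("`block` must be >= 1", call. = FALSE)
  if (nrow(m) %% block != 0L || ncol(m) %% block != 0L) {
    stop(sprintf("image sides (%d x %d) are not divisible by block %d",
                 nrow(m), ncol(m), block), call. = FALSE)
  }
  med <- block_median(m, block)
  out <- med[rep(seq_len(nrow(med)), each = block),
             rep(seq_len(ncol(med)), each = block), drop = FALSE]
  if (inherits(img, "synatp_downsampled")) {
    img$pixels <- out
    img
  } else {
    out
  }
}

#' Optimal two-cluster split of scalar intensities
#'
#' Exhaustive scan over all thresholds between consecutive distinct sorted
#' values, minimizing the total within-cluster sum of squares. For
#' one-dimensional data with two clusters this is the global optimum that
#' k-means approximates, so it doubles as a deterministic clustering backend
#' and as an independent oracle for the k-means route.
#'
#' @param v Numeric vector with at least two distinct values.
#' @return List: `background` (logical, `TRUE` for the lower cluster),
#'   `threshold` (midpoint between the two clusters' boundary values),
#'   `wcss` (total within-cluster sum of squares).
#' @export
threshold_cluster_1d <- function(v) {
  v <- as.double(v)
  if (length(v) < 2L) stop("need at least 2 values", call. = FALSE)
  xs <- sort(v)
  n <- length(xs)
  if (xs[1] == xs[n]) {
    stop("no signal detected: all intensities identical", call. = FALSE)
  }
  xc <- xs - mean(xs)  # centering improves the conditioning of the SSE sums
  cs <- cumsum(xc)
  cs2 <- cumsum(xc^2)
  k <- seq_len(n - 1L)
  valid <- xs[k] < xs[k + 1L]
  sse_l <- cs2[k] - cs[k]^2 / k
  sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- ifelse(valid, sse_l + sse_r, Inf)
  kbest <- which.min(tot)
  cut <- xs[kbest]
  list(
    background = v <= cut,
    threshold = (xs[kbest] + xs[kbest + 1L]) / 2,
    wcss = tot[kbest]
  )
}

#' Two-cluster background detection by intensity clustering
#'
#' Flattens the downsampled luminescence image to a one-dimensional
#' intensity vector (16,384 entries for 128 x 128) and partitions it into
#' two clusters; the cluster with the lower mean is the image background,
#' the other holds the regions of interest. No training data is required.
#'
#' @param img A `synatp_downsampled` or numeric matrix with at least two
#'   distinct intensities.
#' @param seed Integer seed for the k-means restarts.
#' @param method `"kmeans"` (stats::kmeans, 10 restarts, best
#'   within-cluster SSE kept) or `"threshold"`
#'   ([threshold_cluster_1d()], deterministic exhaustive scan). The two
#'   agree on every tested input.
#' @return A `synatp_bgmask`: `grid` (logical matrix, `TRUE` = background),
#'   `background_cluster_mean`, `signal_cluster_mean`.
#' @export
cluster_background <- function(img, seed = 1L,
                               method = c("kmeans", "threshold")) {
  method <- match.arg(method)
  m <- if (inherits(img, "synatp_downsampled")) img$pixels else img
  v <- as.vector(m)
  if (length(v) < 2L) stop("need at least 2 pixels to cluster", call. = FALSE)
  if (min(v) == max(v)) {
    stop("no signal detected: all intensities identical", call. = FALSE)
  }
  if (method == "threshold") {
    bg_vec <- threshold_cluster_1d(v)$background
  } else {
    km <- with_preserved_seed(seed, {
      stats::kmeans(v, centers = 2L, nstart = 10L, iter.max = 100L)
    })
    low <- which.min(km$centers)
    bg_vec <- km$cluster == low
  }
  structure(
    list(
      grid = matrix(bg_vec, nrow(m), ncol(m)),
      background_cluster_mean = mean(v[bg_vec]),
      signal_cluster_mean = mean(v[!bg_vec])
    ),
    class = "synatp_bgmask"
  )
}

#' Construct a cell-body bounding box
#'
#' Coordinates are 0-based, row-major, origin top-left; the box covers the
#' half-open ranges `[row, row + width_px)` x `[col, col + width_px)` in
#' downsampled pixels.
#'
#' @param row,col Top-left corner (0-based, downsampled pixels).
#' @param width_px Square side in downsampled pixels.
#' @param source `"auto"` (sliding-window detection), `"user"` (manual
#'   override), or `"truth"` (planted ground truth from the simulator).
#' @return A `synatp_cellbody` object.
#' @export
cell_body_box <- function(row, col, width_px, source = c("auto", "user", "truth")) {
  source <- match.arg(source)
  row <- as.integer(row); col <- as.integer(col); width_px <- as.integer(width_px)
  if (width_px <= 0L) stop("`width_px` must be positive", call. = FALSE)
  if (row < 0L || col < 0L) stop("box coordinates must be >= 0", call. = FALSE)
  structure(list(row = row, col = col, width_px = width_px, source = source),
            class = "synatp_cellbody")
}

#' Detect the neuronal cell body by sliding-window search
#'
#' The cell body (soma) is much brighter and larger than nerve terminals;
#' its ATP metabolism may differ from terminals, so it is excluded from
#' quantification. A `width_px` x `width_px` square is moved one pixel at a
#' time over the background-zeroed image (background pixels contribute 0)
#' and the placement with the highest mean intensity wins; at fixed width
#' the highest mean and the highest total are the same placement. Ties go to
#' the first placement in row-major scan order.
#'
#' @param img A `synatp_downsampled` or numeric matrix.
#' @param bg A `synatp_bgmask` from [cluster_background()].
#' @param width_px Window side in downsampled pixels (default 32, about
#'   50 um at default optics).
#' @return A `synatp_cellbody` with `source = "auto"`.
#' @export
detect_cell_body <- function(img, bg, width_px = 32L) {
  m <- if (inherits(img, "synatp_downsampled")) img$pixels else img
  width_px <- as.integer(width_px)
  if (width_px <= 0L) stop("`width_px` must be positive", call. = FALSE)
  if (width_px > nrow(m) || width_px > ncol(m)) {
    stop("`width_px` exceeds the image side", call. = FALSE)
  }
  stopifnot(inherits(bg, "synatp_bgmask"))
  if (!identical(dim(bg$grid), dim(m))) {
    stop("background mask geometry does not match the image", call. = FALSE)
  }
  z <- m
  z[bg$grid] <- 0
  sums <- window_sums(z, width_px)
  # first maximum in row-major order; R matrices are column-major, so scan
  # the transpose, whose flat order visits `sums` row by row
  st <- t(sums)
  flat <- which.max(st)
  r0 <- (flat - 1L) %/% nrow(st)
  c0 <- (flat - 1L) %% nrow(st)
  cell_body_box(row = r0, col = c0, width_px = width_px, source = "auto")
}

# All width x width window sums via a summed-area table.
window_sums <- function(m, w) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  nr <- nrow(m) - w + 1L
  nc <- ncol(m) - w + 1L
  i <- seq_len(nr); j <- seq_len(nc)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Expand a downsampled mask to full resolution
#'
#' Nearest-neighbour block expansion: each entry becomes a `factor` x
#' `factor` block of the same value, so downsampled masks can be applied to
#' full-resolution frames.
#'
#' @param grid Logical matrix.
#' @param factor Integer expansion factor >= 1.
#' @return Logical matrix with `factor^2` times as many entries.
#' @export
upsample_mask <- function(grid, factor) {
  stopifnot(is.matrix(grid))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  grid[rep(seq_len(nrow(grid)), each = factor),
       rep(seq_len(ncol(grid)), each = factor), drop = FALSE]
}

#' Mean background intensity of a full-resolution frame
#'
#' Average intensity of the frame pixels lying under the (upsampled)
#' background mask. Computed at full resolution so that it is on the same
#' scale as the net-signal sums of the quantification step.
#'
#' @param frame A `synatp_frame` or matrix.
#' @param bg A `synatp_bgmask` (downsampled geometry).
#' @param factor Downsample factor linking mask and frame geometries.
#' @return Mean intensity (scalar).
#' @export
estimate_background_level <- function(frame, bg, factor) {
  m <- if (is_frame(frame)) frame$pixels else frame
  stopifnot(inherits(bg, "synatp_bgmask"))
  up <- upsample_mask(bg$grid, factor)
  if (!identical(dim(up), dim(m))) {
    stop("upsampled mask geometry does not match the frame", call. = FALSE)
  }
  if (!any(up)) stop("background mask is empty", call. = FALSE)
  mean(m[up])
}

#' Segment one timepoint
#'
#' Full segmentation of a timepoint, all decisions taken on the luminescence
#' channel (its background is far lower than fluorescence): block-median
#' downsample, optional geometry-preserving median smoothing, two-cluster
#' background detection, and cell-body search on the background-zeroed
#' image. The background mask derived from luminescence is then applied
#' verbatim to both channels' full-resolution frames to measure each
#' channel's background level; it is never recomputed on fluorescence.
#'
#' @param record A `synatp_timepoint`.
#' @param config An [acquisition_config()].
#' @param cell_body_override `"auto"` (detect), `"none"` (field contains no
#'   cell body; nothing is masked), or a `synatp_cellbody` giving a manual
#'   box (stored with `source = "user"`).
#' @return A `synatp_segmentation`: `background` mask, `cell_body` box (or
#'   `NULL`), `bg_level_lum`, `bg_level_fluor`, `downsampled` image,
#'   `factor`.
#' @export
segment_timepoint <- function(record, config = acquisition_config(),
                              cell_body_override = "auto") {
  stopifnot(inherits(record, "synatp_timepoint"))
  f <- config$downsample_factor
  ds <- block_median_downsample(record$luminescence, f, config)
  if (config$smooth) ds <- block_median_smooth(ds, config$smoothing_block)
  bg <- cluster_background(ds, seed = config$seed,
                           method = config$cluster_method)
  cb <- resolve_cell_body(ds, bg, config, cell_body_override)
  seg <- structure(
    list(background = bg, cell_body = cb, downsampled = ds, factor = f),
    class = "synatp_segmentation"
  )
  seg$bg_level_lum <- estimate_background_level(record$luminescence, bg, f)
  seg$bg_level_fluor <- estimate_background_level(record$fluorescence, bg, f)
  seg
}

resolve_cell_body <- function(ds, bg, config, override) {
  if (inherits(override, "synatp_cellbody")) {
    box <- override
    box$source <- "user"
    side_r <- nrow(ds$pixels); side_c <- ncol(ds$pixels)
    if (box$row + box$width_px > side_r || box$col + box$width_px > side_c) {
      stop("user cell-body box extends outside the downsampled image",
           call. = FALSE)
    }
    return(box)
  }
  if (identical(override, "none")) return(NULL)
  if (identical(override, "auto")) {
    return(detect_cell_body(ds, bg, config$cell_body_width_px))
  }
  stop("`cell_body_override` must be \"auto\", \"none\", or a cell-body box",
       call. = FALSE)
}

#' Mask partition of a segmentation
#'
#' Every downsampled pixel belongs to exactly one of three classes:
#' background, cell body (background pixels inside the cell-body box stay
#' background), or signal (the quantified nerve-terminal regions).
#'
#' @param seg A `synatp_segmentation`.
#' @return List of logical matrices `background`, `cell_body`, `signal`
#'   forming a partition of the downsampled grid.
#' @export
segmentation_masks <- function(seg) {
  stopifnot(inherits(seg, "synatp_segmentation"))
  bg <- seg$background$grid
  cb <- matrix(FALSE, nrow(bg), ncol(bg))
  if (!is.null(seg$cell_body)) {
    b <- seg$cell_body
    cb[b$row + seq_len(b$width_px), b$col + seq_len(b$width_px)] <- TRUE
  }
  cb <- cb & !bg
  list(background = bg, cell_body = cb, signal = !bg & !cb)
}

#' @export
print.synatp_segmentation <- function(x, ...) {
  mk <- segmentation_masks(x)
  cat(sprintf(paste0(
    "<synatp_segmentation> %d x %d downsampled: %d background, ",
    "%d cell-body, %d signal pixels\n"),
    nrow(mk$background), ncol(mk$background),
    sum(mk$background), sum(mk$cell_body), sum(mk$signal)))
  cat(sprintf("  background level: lum %.4g, fluor %.4g; cluster means %.4g / %.4g\n",
              x$bg_level_lum, x$bg_level_fluor,
              x$background$background_cluster_mean,
              x$background$signal_cluster_mean))
  if (!is.null(x$cell_body)) {
    cat(sprintf("  cell body (%s): (%d, %d) width %d\n", x$cell_body$source,
                x$cell_body$row, x$cell_body$col, x$cell_body$width_px))
  }
  invisible(x)
}
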