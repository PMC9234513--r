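# Shared fixture builders. All fixtures are generated in code; tests never
# touch stored image data.

# a frame filled with a constant (or a supplied matrix)
const_frame <- function(value, side = 8L, channel = "luminescence") {
  new_frame(matrix(value, side, side), channel)
}

mat_frame <- function(m, channel = "luminescence") new_frame(m, channel)

# hand-built segmentation at factor 1: full control over masks and levels
manual_seg <- function(bg_grid, bg_level_lum, bg_level_fluor,
                       cell_body = NULL, factor = 1L) {
  structure(
    list(
      background = structure(
        list(grid = bg_grid, background_cluster_mean = bg_level_lum,
             signal_cluster_mean = bg_level_lum + 1),
        class = "synatp_bgmask"),
      cell_body = cell_body,
      downsampled = NULL, factor = factor,
      bg_level_lum = bg_level_lum, bg_level_fluor = bg_level_fluor
    ),
    class = "synatp_segmentation"
  )
}

# small, fast default scene for pipeline-level tests: 256 px frames,
# 64 px (16 downsampled px) soma, matched detection window
small_spec <- function(...) {
  args <- utils::modifyList(
    list(side_px = 256L, soma_diameter_px = 64L, n_puncta = 60L,
         n_timepoints = 2L, n_frames_per_movie = 5L),
    list(...))
  do.call(scene_spec, args)
}

small_config <- function(...) acquisition_config(cell_body_width_px = 16L, ...)

# brute-force window-mean scan: the independent oracle for detect_cell_body
brute_force_best_window <- function(m, bg_grid, w) {
  z <- m
  z[bg_grid] <- 0
  best <- c(-Inf, NA, NA)
  for (r in 0:(nrow(m) - w)) {
    for (c2 in 0:(ncol(m) - w)) {
      mu <- mean(z[r + seq_len(w), c2 + seq_len(w)])
      if (mu > best[1]) best <- c(mu, r, c2)
    }
  }
  best[2:3]
}

# exhaustive two-cluster SSE scan written independently of the package's
# vectorized version: plain loop over candidate thresholds
brute_force_two_cluster <- function(v) {
  xs <- sort(unique(v))
  best_sse <- Inf
  best_cut <- NA
  for (cut in xs[-length(xs)]) {
    lo <- v[v <= cut]; hi <- v[v > cut]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best_sse) { best_sse <- sse; best_cut <- cut }
  }
  v <= best_cut
}
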