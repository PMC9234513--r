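test_that("block-median downsample reduces geometry and takes block medians", {
  d <- block_median_downsample(const_frame(7, 512), 4)
  expect_equal(dim(d$pixels), c(128, 128))
  expect_true(all(d$pixels == 7))
  expect_equal(d$physical_pixel_um, 1.64)

  # one block holding 1..16: even-count median = mean of 8th and 9th order stats
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- matrix(1:16, 4, 4)
  d2 <- block_median_downsample(mat_frame(m), 4)
  expect_equal(d2$pixels[1, 1], 8.5)

  # checkerboard: every 4x4 block holds eight 0s and eight 1s
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  d3 <- block_median_downsample(mat_frame(cb), 4)
  expect_true(all(d3$pixels == 0.5))

  expect_error(block_median_downsample(const_frame(1, 10), 4), "divisible")
})

test_that("downsample output is bounded by the input range", {
  set.seed(5)
  m <- matrix(runif(64 * 64, 10, 90), 64, 64)
  d <- block_median_downsample(mat_frame(m), 4)
  expect_gte(min(d$pixels), min(m))
  expect_lte(max(d$pixels), max(m))
})

test_that("median smoothing preserves geometry and tile-medians values", {
  d <- block_median_downsample(const_frame(3, 512), 4)
  s <- block_median_smooth(d, 4)
  expect_equal(dim(s$pixels), c(128, 128))
  expect_length(as.vector(s$pixels), 16384)
  expect_true(all(s$pixels == 3))

  tile <- matrix(c(1, 1, 1, 9), 2, 2)
  sm <- block_median_smooth(tile, 2)
  expect_true(all(sm == 1))
  expect_error(block_median_smooth(matrix(0, 6, 6), 4), "divisible")
})

test_that("two-cluster background detection separates bimodal intensities", {
  m <- matrix(c(rep(0, 8), rep(100, 8)), 4, 4)
  for (method in c("kmeans", "threshold")) {
    bg <- cluster_background(m, seed = 1, method = method)
    expect_identical(bg$grid, m == 0)
    expect_equal(bg$background_cluster_mean, 0)
    expect_equal(bg$signal_cluster_mean, 100)
  }
  expect_error(cluster_background(matrix(5, 4, 4)), "no signal")
  expect_error(cluster_background(matrix(5, 1, 1)), "2 pixels")
})

test_that("k-means and the exhaustive SSE threshold scan agree", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(100:2000, 1)
    v <- c(rnorm(n, 100, sample(1:5, 1)),
           rnorm(sample(10:n, 1), sample(150:400, 1), 10))
    m <- matrix(v[1:(floor(length(v) / 2) * 2)], ncol = 2)
    km <- cluster_background(m, seed = rep, method = "kmeans")
    th <- cluster_background(m, seed = rep, method = "threshold")
    expect_identical(km$grid, th$grid)
    # and both match a plain-loop scan over thresholds
    expect_identical(as.vector(th$grid), brute_force_two_cluster(as.vector(m)))
  }
})

test_that("cell-body search finds the highest-mean window with stated ties", {
  # planted 32x32 block of value 10 at (40, 40) on a 128 grid
  m <- matrix(0, 128, 128)
  m[41:72, 41:72] <- 10
  bg <- structure(list(grid = matrix(FALSE, 128, 128),
                       background_cluster_mean = 0, signal_cluster_mean = 10),
                  class = "synatp_bgmask")
  box <- detect_cell_body(m, bg, 32)
  expect_equal(c(box$row, box$col), c(40, 40))
  expect_equal(box$source, "auto")

  # uniform image: tie broken at the first row-major placement
  u <- matrix(5, 64, 64)
  bgu <- structure(list(grid = matrix(FALSE, 64, 64),
                        background_cluster_mean = 0, signal_cluster_mean = 5),
                   class = "synatp_bgmask")
  expect_equal(unlist(detect_cell_body(u, bgu, 16)[c("row", "col")],
                      use.names = FALSE), c(0, 0))

  expect_error(detect_cell_body(u, bgu, 100), "exceeds")
  expect_error(detect_cell_body(u, bgu, 0), "positive")
})

test_that("cell-body search matches brute force and ignores offsets", {
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(runif(48 * 48, 0, 5), 48, 48)
    # two blobs with different means; the brighter must win
    m[6:15, 6:15] <- m[6:15, 6:15] + 10
    m[30:39, 28:37] <- m[30:39, 28:37] + 12
    bg_grid <- m < 3
    bg <- structure(list(grid = bg_grid, background_cluster_mean = 0,
                         signal_cluster_mean = 1), class = "synatp_bgmask")
    box <- detect_cell_body(m, bg, 10)
    expect_equal(c(box$row, box$col), brute_force_best_window(m, bg_grid, 10))
    expect_gte(box$row, 25)  # the mean-12 blob

    # translation invariance: adding a constant moves nothing
    bg2 <- structure(list(grid = bg_grid, background_cluster_mean = 0,
                          signal_cluster_mean = 1), class = "synatp_bgmask")
    box2 <- detect_cell_body(m + 37.5, bg2, 10)
    expect_equal(c(box2$row, box2$col), c(box$row, box$col))
  }
})

test_that("mask upsampling is nearest-neighbour block expansion", {
  expect_identical(upsample_mask(matrix(TRUE, 1, 1), 4), matrix(TRUE, 4, 4))
  g <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_identical(upsample_mask(g, 1), g)
  set.seed(3)
  for (f in c(2, 4)) {
    g <- matrix(runif(36) > 0.5, 6, 6)
    up <- upsample_mask(g, f)
    expect_equal(dim(up), c(6 * f, 6 * f))
    expect_equal(sum(up), sum(g) * f^2)
    # each entry expands to a constant block
    expect_identical(up[((2 - 1) * f + 1):(2 * f), ((3 - 1) * f + 1):(3 * f)],
                     matrix(g[2, 3], f, f))
  }
})

test_that("background level is the mean full-resolution masked intensity", {
  m <- matrix(10, 8, 8)
  bg <- structure(list(grid = matrix(c(TRUE, FALSE), 4, 4),
                       background_cluster_mean = 10, signal_cluster_mean = 11),
                  class = "synatp_bgmask")
  expect_equal(estimate_background_level(m, bg, 2), 10)

  # two-point mean through a factor-1 mask
  m2 <- matrix(100, 8, 8); m2[1, 1] <- 8; m2[2, 1] <- 12
  g2 <- matrix(FALSE, 8, 8); g2[1:2, 1] <- TRUE
  bg2 <- structure(list(grid = g2, background_cluster_mean = 0,
                        signal_cluster_mean = 1), class = "synatp_bgmask")
  expect_equal(estimate_background_level(m2, bg2, 1), 10)

  set.seed(11)
  m3 <- matrix(runif(256, 0, 1e4), 16, 16)
  g3 <- matrix(runif(64) > 0.4, 8, 8)
  bg3 <- structure(list(grid = g3, background_cluster_mean = 0,
                        signal_cluster_mean = 1), class = "synatp_bgmask")
  up <- g3[rep(1:8, each = 2), rep(1:8, each = 2)]
  expect_equal(estimate_background_level(m3, bg3, 2),
               sum(m3[up]) / sum(up), tolerance = 1e-9)

  bg_empty <- structure(list(grid = matrix(FALSE, 8, 8),
                             background_cluster_mean = 0,
                             signal_cluster_mean = 1),
                        class = "synatp_bgmask")
  expect_error(estimate_background_level(m2, bg_empty, 1), "empty")
})

test_that("segment_timepoint recovers planted levels and honors overrides", {
  sp <- small_spec(seed = 21, n_timepoints = 1,
                   noise_sd = c(luminescence = 0, fluorescence = 0),
                   punctum_amp_cv = 0)
  scene <- generate_scene(sp, small_config())
  tp <- scene$series$timepoints[[1]]
  seg <- segment_timepoint(tp, small_config())
  expect_equal(seg$bg_level_lum,
               unname(scene$truth$background_levels_true["luminescence"]))
  expect_equal(seg$bg_level_fluor,
               unname(scene$truth$background_levels_true["fluorescence"]))

  # the luminescence-derived mask is reused verbatim on fluorescence
  seg_f <- cluster_background(block_median_downsample(tp$fluorescence, 4))
  expect_identical(dim(seg$background$grid), dim(seg_f$grid))
  expect_equal(seg$bg_level_fluor, mean(tp$fluorescence$pixels[
    upsample_mask(seg$background$grid, 4)]))

  # user override recorded as such; suppression leaves no cell body
  ovr <- segment_timepoint(tp, small_config(),
                           cell_body_override = cell_body_box(10, 10, 48))
  expect_equal(ovr$cell_body$source, "user")
  expect_equal(c(ovr$cell_body$row, ovr$cell_body$col,
                 ovr$cell_body$width_px), c(10, 10, 48))
  none <- segment_timepoint(tp, small_config(), cell_body_override = "none")
  expect_null(none$cell_body)

  # every downsampled pixel lands in exactly one mask class
  mk <- segmentation_masks(seg)
  expect_equal(sum(mk$background) + sum(mk$cell_body) + sum(mk$signal),
               64 * 64)
  expect_true(all(mk$background + mk$cell_body + mk$signal == 1))
})
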