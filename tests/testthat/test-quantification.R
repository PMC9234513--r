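test_that("net signal is the masked sum minus count x background level", {
  # 8 signal pixels each 20 over background level 10: 8*20 - 8*10 = 80
  m <- matrix(10, 8, 8)
  sig <- matrix(FALSE, 8, 8); sig[1, 1:8] <- TRUE
  m[sig] <- 20
  seg <- manual_seg(!sig, bg_level_lum = 10, bg_level_fluor = 10)
  expect_equal(compute_net_signal(m, seg, "luminescence"), 80)

  # signal pixels equal to the background level cancel exactly
  m2 <- matrix(10, 8, 8)
  expect_equal(compute_net_signal(m2, seg, "luminescence"), 0)

  # brute-force per-pixel oracle on random data
  set.seed(13)
  m3 <- matrix(runif(64, 0, 5000), 8, 8)
  bgl <- runif(1, 0, 100)
  seg3 <- manual_seg(!sig, bg_level_lum = bgl, bg_level_fluor = bgl)
  expect_equal(compute_net_signal(m3, seg3, "luminescence"),
               sum(m3[sig] - bgl), tolerance = 1e-9)

  all_bg <- manual_seg(matrix(TRUE, 8, 8), 10, 10)
  expect_error(compute_net_signal(m, all_bg, "luminescence"), "no signal")
})

test_that("net signal ignores a constant offset added to one channel", {
  set.seed(14)
  m <- matrix(runif(64, 100, 200), 8, 8)
  sig <- matrix(runif(64) > 0.6, 8, 8)
  mk_seg <- function(mm) manual_seg(!sig, bg_level_lum = mean(mm[!sig]),
                                    bg_level_fluor = mean(mm[!sig]))
  base <- compute_net_signal(m, mk_seg(m), "luminescence")
  shifted <- compute_net_signal(m + 123.4, mk_seg(m + 123.4), "luminescence")
  expect_equal(shifted, base, tolerance = 1e-9)
})

test_that("L/F division flags nonpositive denominators instead of erroring", {
  expect_equal(compute_lf(100, 200), 0.5)
  expect_equal(compute_lf(3.7, 3.7), 1.0)
  expect_true(is.na(compute_lf(100, 0)))
  expect_true(is.na(compute_lf(100, -5)))
})

test_that("dark-current QC is boundary-inclusive and configurable", {
  cfg <- acquisition_config(dark_current_variance = 100, qc_factor = 3)
  expect_true(quality_check(300, cfg))
  expect_false(quality_check(299, cfg))
  expect_true(quality_check(1e-9, acquisition_config(dark_current_variance = 0)))
  bad <- acquisition_config()
  bad$dark_current_variance <- -1
  expect_error(quality_check(10, bad), "nonnegative")
})

test_that("gain adjustment is a pure multiplier gated by the flag", {
  on <- acquisition_config(gain_enabled = TRUE, gain_coefficient = 2)
  expect_equal(apply_gain_adjustment(0.5, on), 1.0)
  off <- acquisition_config(gain_enabled = FALSE, gain_coefficient = 2)
  expect_equal(apply_gain_adjustment(0.5, off), 0.5)
  unit <- acquisition_config(gain_enabled = TRUE, gain_coefficient = 1)
  expect_equal(apply_gain_adjustment(c(0.1, 0.7, 2), unit), c(0.1, 0.7, 2))
})

test_that("pH correction is per-timepoint, invertible, and keeps raw values", {
  sp <- small_spec(seed = 31, n_timepoints = 3)
  trace <- build_trace(generate_scene(sp, small_config())$series,
                       config = small_config())
  t1 <- apply_ph_correction(trace, c(1, 1, 1))
  expect_equal(t1$points$lf_ph_corrected, t1$points$lf)
  t2 <- apply_ph_correction(trace, c(2, 0.5, 1.25))
  expect_equal(t2$points$lf_ph_corrected, trace$points$lf * c(2, 0.5, 1.25))
  expect_equal(t2$points$lf, trace$points$lf)  # raw retained
  # multiplying the corrected values by the reciprocal factors recovers raw
  expect_equal(t2$points$lf_ph_corrected / c(2, 0.5, 1.25),
               trace$points$lf, tolerance = 1e-12)
  expect_error(apply_ph_correction(trace, c(1, 1)), "one pH factor per")
})

test_that("build_trace recovers the planted ratio on noise-free scenes", {
  sp <- small_spec(seed = 41, n_timepoints = 2, true_lf = 0.07,
                   noise_sd = c(luminescence = 0, fluorescence = 0),
                   punctum_amp_cv = 0)
  scene <- generate_scene(sp, small_config())
  trace <- build_trace(scene$series, config = small_config())
  expect_equal(nrow(trace$points), 2)
  expect_true(all(trace$points$valid))
  expect_equal(trace$points$lf, rep(0.07, 2), tolerance = 1e-6)
})

test_that("L/F is invariant to rescaling both channels", {
  sp <- small_spec(seed = 43, n_timepoints = 1)
  scene <- generate_scene(sp, small_config())
  trace <- build_trace(scene$series, config = small_config())
  scaled <- scene$series
  for (i in seq_along(scaled$timepoints)) {
    tp <- scaled$timepoints[[i]]
    tp$luminescence$pixels <- tp$luminescence$pixels * 3.5
    tp$fluorescence$pixels <- tp$fluorescence$pixels * 3.5
    scaled$timepoints[[i]] <- tp
  }
  trace2 <- build_trace(scaled, config = small_config())
  expect_equal(trace2$points$lf, trace$points$lf, tolerance = 1e-9)
})

test_that("a degenerate timepoint is flagged while the rest are computed", {
  sp <- small_spec(seed = 45, n_timepoints = 3)
  scene <- generate_scene(sp, small_config())
  # replace the middle luminescence frame with a featureless one
  tp <- scene$series$timepoints[[2]]
  scene$series$timepoints[[2]] <- new_timepoint(
    tp$index, tp$time_s, tp$fluorescence,
    new_frame(matrix(100, 256, 256), "luminescence"))
  trace <- build_trace(scene$series, config = small_config())
  expect_equal(trace$points$valid, c(TRUE, FALSE, TRUE))
  expect_false(trace$points$qc_pass[2])
  expect_true(is.na(trace$points$lf[2]))
  expect_match(paste(trace$notes, collapse = " "), "timepoint 1")
  expect_true(all(is.finite(trace$points$lf[c(1, 3)])))
})

test_that("QC failure propagates into the trace when signal is near the floor", {
  sp <- small_spec(seed = 47, n_timepoints = 1)
  scene <- generate_scene(sp, small_config())
  # an absurdly high dark variance makes every channel fail the 3x rule
  cfg <- small_config(dark_current_variance = 1e7)
  trace <- build_trace(scene$series, config = cfg)
  expect_true(all(trace$points$valid))
  expect_false(any(trace$points$qc_pass))
})

test_that("trace CSV round-trips through write and read", {
  sp <- small_spec(seed = 49, n_timepoints = 2)
  trace <- build_trace(generate_scene(sp, small_config())$series,
                       config = small_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(trace, path)
  back <- read_trace_csv(path)
  expect_equal(back$neuron_id, trace$neuron_id)
  expect_equal(back$points$lf, trace$points$lf)
  expect_equal(back$points$qc_pass, trace$points$qc_pass)
})
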