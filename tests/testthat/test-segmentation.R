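test_that("reference images average frames as requested", {
  fr <- array(0, dim = c(4, 4, 2))
  fr[, , 1] <- 0
  fr[, , 2] <- 10
  st <- raw_stack(fr, 4.3, c("a", "b"))
  expect_equal(build_reference(st, "time-average")$pixels,
               matrix(5, 4, 4))
  expect_equal(build_reference(st, "single-frame", frame = 2)$pixels,
               matrix(10, 4, 4))
  # autofluorescence-channel mode uses only that channel's frames
  expect_equal(build_reference(st, "autofluorescence-channel",
                               channel = "b")$pixels,
               matrix(10, 4, 4))
  # identical frames: reference equals any frame
  st2 <- raw_stack(array(3, dim = c(4, 4, 5)))
  expect_equal(build_reference(st2, "time-average")$pixels, matrix(3, 4, 4))
  expect_error(build_reference(st, "autofluorescence-channel",
                               channel = "zzz"), "channel")
})

test_that("autofluorescence-channel reference matches manual slicing", {
  cfg <- mini_config(n_frames = 6, channel_sequence = c("395", "475"),
                     autofluorescence = c("395" = 700, "475" = 100))
  mv <- render_movie(cfg)
  ref <- build_reference(mv$stack, "autofluorescence-channel",
                         channel = "395")
  manual <- apply(mv$stack$frames[, , c(1, 3, 5)], c(1, 2), mean)
  expect_equal(ref$pixels, manual)
})

test_that("a seven-core mini bundle is segmented exactly", {
  cfg <- synthetic_config(fov_diameter_um = 9, lattice_spacing_um = 3.71,
                          jitter_sd_um = 0, n_frames = 1, cells = list(),
                          noise = NULL, flicker_sd = 0,
                          autofluorescence = 500, seed = 1)
  mv <- render_movie(cfg)
  expect_identical(nrow(mv$truth$core_centers_um), 7L)
  cm <- segment_cores(build_reference(mv$stack, "single-frame"))
  expect_identical(cm$n_cores, 7L)
  d <- center_match_dist(true_centers_px(mv, cfg), cm$centers_px)
  expect_lt(max(d), 0.5)
})

test_that("default jittered noisy fixture recovers the core count exactly", {
  cfg <- synthetic_config(n_frames = 3, cells = list(), seed = 42)
  mv <- render_movie(cfg)
  cm <- segment_cores(build_reference(mv$stack, "time-average"))
  expect_identical(cm$n_cores, nrow(mv$truth$core_centers_um))
})

test_that("segmentation rejects degenerate references", {
  expect_error(segment_cores(matrix(5, 32, 32)), "no cores")
  expect_error(build_reference(raw_stack(array(1, c(2, 2, 0))),
                               "time-average"), "empty")
})

test_that("segmentation is invariant to affine intensity changes", {
  cfg <- mini_config()
  mv <- render_movie(cfg)
  ref <- build_reference(mv$stack, "single-frame")$pixels
  a <- segment_cores(ref)
  b <- segment_cores(3.7 * ref + 120)
  expect_identical(a$n_cores, b$n_cores)
  # floating-point rounding of a*I + b can move watershed boundaries in
  # the flat dark region between and outside cores, where basin borders
  # are arbitrary; the centers and the bright-core partition must agree
  expect_lt(max(abs(a$centers_px - b$centers_px)), 0.01)
  bright <- a$smoothed >= quantile(a$smoothed, 0.5)
  expect_lt(mean(a$label_image[bright] != b$label_image[bright]), 0.005)
})

test_that("every center lies in its own region; labels partition cores", {
  cm <- bundle_clean()$coremap
  n <- cm$n_cores
  expect_identical(sort(unique(as.integer(cm$label_image[cm$label_image > 0]))),
                   seq_len(n))
  at_label <- cm$label_image[cbind(pmin(pmax(round(cm$centers_px[, 1]), 1),
                                        nrow(cm$label_image)),
                                   pmin(pmax(round(cm$centers_px[, 2]), 1),
                                        ncol(cm$label_image)))]
  expect_gt(mean(at_label == seq_len(n)), 0.99)
  # the FOV mask covers all labeled pixels
  expect_true(all(cm$fov_mask[cm$label_image > 0]))
})

test_that("lattice statistics recover the generating parameters", {
  fx <- bundle_clean()
  st <- lattice_stats(fx$coremap, fx$cfg$raw_pixel_um)
  expect_identical(st$n_cores, nrow(fx$movie$truth$core_centers_um))
  expect_equal(st$mean_nn_spacing_um, 3.71, tolerance = 0.01)
  expect_equal(st$mean_core_diameter_um, 2.34, tolerance = 0.1)
  d <- center_match_dist(true_centers_px(fx$movie, fx$cfg),
                         fx$coremap$centers_px)
  expect_lt(sqrt(mean(d^2)), 0.5)
})

test_that("two cores give the trivial pair spacing", {
  cm <- structure(
    list(label_image = matrix(0L, 4, 4),
         centers_px = cbind(y = c(2, 2), x = c(1, 11)),
         fov_mask = matrix(TRUE, 4, 4), n_cores = 2L,
         smoothed = matrix(1, 4, 4), smoothing_sigma_px = 1,
         core_sigma_px = NULL, core_amplitude = NULL),
    class = "core_map")
  st <- lattice_stats(cm, pixel_size_um = 0.3)
  expect_equal(st$mean_nn_spacing_um, 3)
  expect_true(is.na(st$mean_core_diameter_um))
  cm$centers_px <- cm$centers_px[1, , drop = FALSE]
  cm$n_cores <- 1L
  expect_error(lattice_stats(cm), "two cores")
})
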