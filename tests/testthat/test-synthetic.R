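test_that("hexagonal lattice matches brute-force enumeration in the FOV", {
  cfg <- synthetic_config(fov_diameter_um = 147.5,
                          lattice_spacing_um = 3.676, jitter_sd_um = 0,
                          n_frames = 1, seed = 1)
  centers <- generate_lattice(cfg)

  # independent brute-force enumeration of hex lattice points in the circle
  s <- 3.676
  r <- 147.5 / 2
  row_h <- s * sqrt(3) / 2
  count <- 0L
  for (j in seq(-ceiling(r / row_h) - 2L, ceiling(r / row_h) + 2L)) {
    y <- j * row_h
    off <- if (j %% 2 == 0) 0 else s / 2
    for (i in seq(-ceiling(r / s) - 2L, ceiling(r / s) + 2L)) {
      x <- i * s + off
      if (x^2 + y^2 <= r^2) count <- count + 1L
    }
  }
  expect_identical(nrow(centers), as.integer(count))
  expect_gte(nrow(centers), 1400)
  expect_lte(nrow(centers), 1520)
})

test_that("unjittered lattice has minimal spacing equal to the constant", {
  cfg <- mini_config()
  centers <- generate_lattice(cfg)
  d <- as.matrix(dist(centers))
  diag(d) <- Inf
  expect_equal(min(d), cfg$lattice_spacing_um, tolerance = 1e-12)
})

test_that("degenerate lattice configurations error", {
  expect_error(synthetic_config(fov_diameter_um = 10, lattice_spacing_um = 20),
               "degenerate")
  expect_error(synthetic_config(core_fwhm_um = 5, lattice_spacing_um = 4),
               "FWHM")
})

test_that("cell transient follows rise / plateau / exponential decay", {
  sp <- cell_spec(center_um = c(0, 0), amplitude_rel = 0.6, onset_s = 10,
                  rise_s = 2, plateau_s = 3, decay_s = 17.5)
  expect_equal(cell_transient(sp, c(0, 5, 9.99)), rep(1, 3))
  expect_equal(cell_transient(sp, 12), 1.6)           # onset + rise
  expect_equal(cell_transient(sp, 11), 1.3)           # mid-rise, linear
  expect_equal(cell_transient(sp, 14), 1.6)           # plateau
  sp1 <- cell_spec(center_um = c(0, 0), amplitude_rel = 1, onset_s = 2,
                   rise_s = 1, plateau_s = 1, decay_s = 5)
  expect_equal(cell_transient(sp1, 2 + 1 + 1 + 5), 1 + exp(-1))
  # optional pre-onset dip
  spd <- cell_spec(center_um = c(0, 0), onset_s = 10, dip_rel = 0.1,
                   dip_s = 4)
  expect_equal(cell_transient(spd, 8), 0.9)
  expect_equal(cell_transient(spd, 5), 1)
})

test_that("frames cycle through the channel sequence starting at frame 1", {
  cfg <- mini_config(n_frames = 10, channel_sequence = c("475", "555"),
                     autofluorescence = c("475" = 600, "555" = 200))
  mv <- render_movie(cfg)
  expect_identical(frame_channels(mv$stack),
                   rep(c("475", "555"), 5))
  m <- apply(mv$stack$frames, 3, mean)
  expect_true(all(m[c(1, 3, 5, 7, 9)] > 2 * m[c(2, 4, 6, 8, 10)]))
})

test_that("static noise-free scenes give byte-identical frames per channel", {
  cfg <- mini_config(n_frames = 6)
  mv <- render_movie(cfg)
  for (k in 2:6)
    expect_identical(mv$stack$frames[, , k], mv$stack$frames[, , 1])
})

test_that("a fixed seed reproduces the movie and ground truth exactly", {
  cfg <- synthetic_config(fov_diameter_um = 25, n_frames = 4, seed = 99,
                          cells = list(cell_spec(center_um = c(0, 0),
                                                 radius_um = 4)),
                          motion = list(amplitude_px = 2, period_s = 1))
  a <- render_movie(cfg)
  b <- render_movie(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$core_centers_um, b$truth$core_centers_um)
  expect_identical(a$truth$per_frame_shift_px, b$truth$per_frame_shift_px)
})

test_that("seeded rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(render_movie(mini_config(n_frames = 2)))
  expect_identical(runif(3), expected)
})

test_that("ground truth invariants hold", {
  cfg <- synthetic_config(fov_diameter_um = 25, n_frames = 8, seed = 2,
                          cells = list(cell_spec(center_um = c(0, 0),
                                                 radius_um = 4,
                                                 onset_s = 0.8)),
                          motion = list(amplitude_px = 3, period_s = 1.5))
  mv <- render_movie(cfg)
  expect_equal(unlist(mv$truth$per_frame_shift_px[1, c("dy", "dx")]),
               c(dy = 0, dx = 0))
  pre <- subset(mv$truth$cell_traces, time_s < 0.8)
  expect_true(all(pre$rel_intensity == 1))
})

test_that("core mean traces reproduce baseline x transient x gain", {
  cell <- cell_spec(center_um = c(0, 0), radius_um = 5, baseline = 800,
                    amplitude_rel = 0.6, onset_s = 2, rise_s = 1,
                    plateau_s = 1, decay_s = 4)
  cfg <- synthetic_config(fov_diameter_um = 25, n_frames = 30,
                          frame_rate_fps = 4.3, jitter_sd_um = 0,
                          autofluorescence = 0.0001, flicker_sd = 0.03,
                          noise = NULL, cells = list(cell), seed = 21)
  mv <- render_movie(cfg)
  cm <- segment_cores(build_reference(mv$stack, "time-average"))
  ct <- extract_core_means(mv$stack, cm)
  # the brightest core sits inside the cell: its trace must follow
  # transient(t) * gain(t) up to 16-bit quantization
  i <- which.max(ct$values[1, ])
  tr <- ct$values[, i]
  ideal <- cell_transient(cell, frame_times(mv$stack))
  gains <- tr / (tr[1] / ideal[1]) / ideal
  # gains recovered per frame must be common across distinct bright cores
  j <- order(ct$values[1, ], decreasing = TRUE)[2]
  gains2 <- ct$values[, j] / (ct$values[1, j] / ideal[1]) / ideal
  expect_equal(gains, gains2, tolerance = 0.01)
  # and the de-flickered trace matches the ideal transient shape
  expect_equal(tr / tr[1] / gains, ideal, tolerance = 0.01)
})

test_that("saturating scenes raise rather than silently clip", {
  cfg <- mini_config(autofluorescence = 70000)
  expect_error(render_movie(cfg), "saturation")
})
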