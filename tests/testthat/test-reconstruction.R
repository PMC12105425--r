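make_coremap <- function(labels, centers = NULL) {
  n <- max(labels)
  structure(
    list(label_image = labels,
         centers_px = centers,
         fov_mask = labels > 0, n_cores = as.integer(n),
         smoothed = matrix(1, nrow(labels), ncol(labels)),
         smoothing_sigma_px = 1, core_sigma_px = NULL,
         core_amplitude = NULL),
    class = "core_map")
}

test_that("core means average exactly over labeled regions", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1:3] <- 1L
  lab[3, 1:2] <- 2L
  fr <- matrix(7, 4, 4)
  st <- raw_stack(fr)
  cm <- make_coremap(lab)
  expect_equal(extract_core_means(st, cm)$values, matrix(7, 1, 2))
  fr2 <- matrix(0, 4, 4)
  fr2[1, 1:3] <- c(2, 4, 6)
  ct <- extract_core_means(raw_stack(fr2), cm)
  expect_equal(ct$values[1, 1], 4)
  expect_error(extract_core_means(raw_stack(matrix(1, 5, 5)), cm),
               "geometry")
})

test_that("interpolation reproduces an affine field exactly", {
  centers <- cbind(y = c(0, 1, 0), x = c(0, 0, 1))
  vals <- c(1, 3, 2) # f = 1 + 2y + x
  op <- interp_operator(centers, grid_n = 2, bbox = c(0, 1, 0, 1))
  fr <- interpolate_frame(vals, op)
  # grid pixel (1,1) center sits at (0.25, 0.25)
  expect_true(fr$valid_mask[1, 1])
  expect_equal(fr$frame[1, 1], 1 + 2 * 0.25 + 0.25, tolerance = 1e-12)
  # larger random affine check
  set.seed(4)
  ctr <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  v <- 2 - 0.3 * ctr[, 1] + 0.7 * ctr[, 2]
  op2 <- interp_operator(ctr, grid_n = 64)
  fr2 <- interpolate_frame(v, op2)
  gy <- op2$grid$origin_px[1] + (seq_len(64) - 1) * op2$grid$step_px
  gx <- op2$grid$origin_px[2] + (seq_len(64) - 1) * op2$grid$step_px
  want <- outer(2 - 0.3 * gy, 0.7 * gx, "+")
  expect_lt(max(abs((fr2$frame - want)[fr2$valid_mask])), 1e-6)
})

test_that("constant core values give a constant in-mask field", {
  set.seed(5)
  ctr <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  fr <- interpolate_frame(rep(4.2, 30), interp_operator(ctr, grid_n = 32))
  expect_lt(max(abs(fr$frame[fr$valid_mask] - 4.2)), 1e-12)
  expect_true(all(fr$frame[!fr$valid_mask] == 0))
})

test_that("interpolation is exact at core centers placed on grid points", {
  # cores on integer grid coordinates of a unit-step grid
  centers <- cbind(y = c(2, 2, 6, 6, 4), x = c(2, 6, 2, 6, 4))
  vals <- c(1, 2, 3, 4, 10)
  op <- interp_operator(centers, grid_n = 8, bbox = c(0.5, 8.5, 0.5, 8.5))
  fr <- interpolate_frame(vals, op)
  for (i in seq_len(5))
    expect_equal(fr$frame[centers[i, 1], centers[i, 2]], vals[i],
                 tolerance = 1e-9)
})

test_that("degenerate center sets are rejected", {
  expect_error(interp_operator(cbind(c(0, 1), c(0, 0))), "3")
  expect_error(interp_operator(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               "collinear")
})

test_that("a single-core impulse reconstructs at the lattice-spacing width", {
  cfg <- mini_config()
  mv <- render_movie(cfg)
  cm <- segment_cores(build_reference(mv$stack, "single-frame"))
  op <- interp_operator(cm$centers_px, grid_n = 128)
  # impulse at the core closest to the bundle center
  ctr_px <- (cfg$frame_px + 1) / 2
  i0 <- which.min((cm$centers_px[, 1] - ctr_px)^2 +
                    (cm$centers_px[, 2] - ctr_px)^2)
  v <- rep(0, cm$n_cores)
  v[i0] <- 1
  fr <- interpolate_frame(v, op)
  peak <- which(fr$frame == max(fr$frame), arr.ind = TRUE)[1, ]
  prof <- fr$frame[peak[1], ]
  w_px <- fwhm(prof, 1)
  spacing_grid <- cfg$lattice_spacing_um / cfg$raw_pixel_um / op$grid$step_px
  expect_equal(w_px, spacing_grid, tolerance = 1 / spacing_grid)
})

test_that("percentile subtraction zeroes the in-mask percentile per frame", {
  mask <- matrix(TRUE, 2, 2)
  rc <- recon_stack(matrix(5, 2, 2), mask)
  rs <- subtract_percentile(rc)
  expect_equal(rs$frames[, , 1], matrix(0, 2, 2))
  expect_true(rs$background_subtracted)
  # the stated linear-interpolation percentile convention
  rc2 <- recon_stack(matrix(1:4, 2, 2), mask)
  rs2 <- subtract_percentile(rc2, 25)
  expect_equal(rs2$frames[, , 1], matrix(1:4 - 1.75, 2, 2))
  expect_error(subtract_percentile(rs2), "already")
  # negatives retained; in-mask percentile exactly zero for random stacks
  set.seed(8)
  fr <- array(rnorm(16 * 16 * 5, 100, 20), c(16, 16, 5))
  m <- matrix(runif(256) < 0.8, 16, 16)
  rs3 <- subtract_percentile(recon_stack(fr, m), 25)
  for (k in 1:5)
    expect_equal(unname(quantile(rs3$frames[, , k][m], 0.25)), 0,
                 tolerance = 1e-12)
  expect_lt(min(rs3$frames), 0)
})

test_that("per-frame additive offsets cancel exactly", {
  set.seed(9)
  base <- matrix(rnorm(64 * 64, 500, 50), 64, 64)
  offs <- c(0, 30, -12, 7)
  fr <- array(0, c(64, 64, 4))
  for (k in 1:4) fr[, , k] <- base + offs[k]
  rs <- subtract_percentile(recon_stack(fr, matrix(TRUE, 64, 64)))
  for (k in 2:4)
    expect_equal(rs$frames[, , k], rs$frames[, , 1], tolerance = 1e-12)
})

test_that("per-frame subtraction beats a fixed baseline under gain flicker", {
  # multiplicative flicker on a static background: the stated motivation
  # for proportional (per-frame) subtraction
  set.seed(10)
  g <- rnorm(40, 1, 0.05)
  base <- matrix(rnorm(32 * 32, 600, 80), 32, 32)
  fr <- array(0, c(32, 32, 40))
  for (k in 1:40) fr[, , k] <- g[k] * base
  mask <- matrix(TRUE, 32, 32)
  per_frame <- subtract_percentile(recon_stack(fr, mask))
  fixed_q <- quantile(fr[, , 1][mask], 0.25)
  roi <- matrix(FALSE, 32, 32)
  roi[10:20, 10:20] <- TRUE
  tr_pf <- vapply(1:40, function(k) mean(per_frame$frames[, , k][roi]),
                  numeric(1))
  tr_fx <- vapply(1:40, function(k) mean((fr[, , k] - fixed_q)[roi]),
                  numeric(1))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(tr_pf), cv(tr_fx))
})

test_that("full reconstruction matches per-frame interpolation", {
  cfg <- mini_config(n_frames = 3)
  mv <- render_movie(cfg)
  cm <- segment_cores(build_reference(mv$stack, "time-average"))
  rc <- reconstruct(mv$stack, cm, grid_n = 64)
  ct <- extract_core_means(mv$stack, cm)
  op <- interp_operator(cm$centers_px, grid_n = 64)
  f2 <- interpolate_frame(ct$values[2, ], op)
  expect_equal(rc$frames[, , 2], f2$frame, tolerance = 1e-12)
  expect_identical(rc$valid_mask, f2$valid_mask)
})

test_that("reconstruction agrees with an independent interpolation oracle", {
  skip_if_not_installed("interp")
  # jittered layout: an unjittered hexagonal lattice has cocircular quads
  # whose Delaunay diagonals are ambiguous between implementations
  cfg <- mini_config(jitter_sd_um = 0.1)
  mv <- render_movie(cfg)
  cm <- segment_cores(build_reference(mv$stack, "single-frame"))
  ct <- extract_core_means(mv$stack, cm)
  op <- interp_operator(cm$centers_px, grid_n = 48)
  mine <- interpolate_frame(ct$values[1, ], op)
  gy <- op$grid$origin_px[1] + (seq_len(48) - 1) * op$grid$step_px
  gx <- op$grid$origin_px[2] + (seq_len(48) - 1) * op$grid$step_px
  ref <- interp::interp(x = cm$centers_px[, 2], y = cm$centers_px[, 1],
                        z = ct$values[1, ], xo = gx, yo = gy,
                        method = "linear", output = "grid")
  # interp returns z[x, y]; transpose to [y, x]
  want <- t(ref$z)
  both <- mine$valid_mask & !is.na(want)
  expect_gt(sum(both), 1000)
  expect_lt(max(abs(mine$frame[both] - want[both])), 1e-4)
})
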