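# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small unjittered noise-free bundle: fast, exact ground truth
mini_config <- function(...) {
  args <- list(fov_diameter_um = 30, lattice_spacing_um = 3.71,
               jitter_sd_um = 0, n_frames = 1, cells = list(),
               noise = NULL, flicker_sd = 0, autofluorescence = 500,
               seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# full-size instrument geometry, unjittered, noise-free: the reference
# condition for lattice parameter recovery
bundle_clean <- function() {
  fixture("bundle_clean", {
    cfg <- synthetic_config(jitter_sd_um = 0, n_frames = 1, cells = list(),
                            noise = NULL, flicker_sd = 0, seed = 42)
    mv <- render_movie(cfg)
    cm <- segment_cores(build_reference(mv$stack, "single-frame"))
    list(cfg = cfg, movie = mv, coremap = cm)
  })
}

# full-size default (jittered, noisy) movie with one in-situ-like cell at
# amplitude 0.6 - the end-to-end parameter-recovery condition
insitu_movie <- function() {
  fixture("insitu_movie", {
    cells <- list(cell_spec(center_um = c(10, -15), radius_um = 6,
                            baseline = 600, amplitude_rel = 0.6,
                            onset_s = 10, rise_s = 2, plateau_s = 3,
                            decay_s = 17.5))
    cfg <- synthetic_config(n_frames = 172, cells = cells, seed = 42)
    list(cfg = cfg, movie = render_movie(cfg))
  })
}

# true core centers in raw-pixel coordinates
true_centers_px <- function(movie, cfg) {
  movie$truth$core_centers_um / cfg$raw_pixel_um + (cfg$frame_px + 1) / 2
}

# distance from each true center to its nearest estimated center
center_match_dist <- function(true_px, est_px) {
  d2 <- outer(true_px[, 1], est_px[, 1], "-")^2 +
    outer(true_px[, 2], est_px[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

# grid-pixel position of a sample-plane point (um) in a recon stack
grid_pos <- function(recon, cfg, point_um) {
  raw <- point_um / cfg$raw_pixel_um + (cfg$frame_px + 1) / 2
  (raw - recon$grid$origin_px) / recon$grid$step_px + 1
}

# registration-friendly mini scene: compact bright cells on dim background
motion_cells <- function() {
  list(
    cell_spec(center_um = c(2, -4), radius_um = 3, baseline = 900,
              onset_s = 1e6),
    cell_spec(center_um = c(-9, 5), radius_um = 2.5, baseline = 700,
              onset_s = 1e6),
    cell_spec(center_um = c(8, 9), radius_um = 3.5, baseline = 800,
              onset_s = 1e6),
    cell_spec(center_um = c(-4, -10), radius_um = 2.5, baseline = 750,
              onset_s = 1e6)
  )
}
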