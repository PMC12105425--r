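#' Synthetic fiber-bundle movies with ground truth
#'
#' The generator emulates the raw output of a multicore-fiber microendoscope
#' so every pipeline stage can be verified against known ground truth: a
#' jittered hexagonal lattice of bright cores inside a circular field of
#' view, channel-dependent core autofluorescence, multiplicative per-frame
#' gain flicker, rigid breathing-like motion, sparse cells with calcium-like
#' transients, and Poisson + Gaussian camera noise, quantized to 16 bits.
#'
#' @name synthetic
NULL

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specify one synthetic cell
#'
#' A disk-shaped cell whose fluorescence follows a calcium-transient time
#' course: baseline until `onset_s`, a linear rise to `1 + amplitude_rel`
#' times baseline over `rise_s`, an optional plateau of `plateau_s`, then an
#' exponential return to baseline with time constant `decay_s`. An optional
#' shallow pre-onset dip (seen in some in-situ recordings; mechanism
#' unknown) can be enabled via `dip_rel`/`dip_s`; it is off by default.
#'
#' @param center_um Cell center, c(y, x) in µm relative to the FOV center.
#' @param radius_um Cell radius (µm).
#' @param baseline Baseline fluorescence at a core fully covering the cell
#'   (camera counts).
#' @param amplitude_rel Peak relative response (0.6 = 60% above baseline;
#'   in-situ tuft-cell responses are around 1.6-fold, i.e. 0.6).
#' @param onset_s,rise_s,plateau_s,decay_s Transient timing (s). Typical
#'   values: rise 1-3 s, plateau < 10 s, decay 15-50 s.
#' @param channel_response Named per-channel gain on the cell's relative
#'   modulation: in channel ch the cell emits
#'   `baseline * (1 + (transient(t) - 1) * channel_response[ch])`. Use 1
#'   for a responsive channel, 0 for a static reference fluorophore, and a
#'   negative value for a channel that dims when the other brightens (the
#'   two excitation arms of a ratiometric redox sensor). An unnamed scalar
#'   applies to all channels.
#' @param dip_rel,dip_s Pre-onset dip depth (relative) and duration (s).
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center_um, radius_um = 5, baseline = 600,
                      amplitude_rel = 0.6, onset_s = 10, rise_s = 2,
                      plateau_s = 3, decay_s = 17.5,
                      channel_response = 1, dip_rel = 0, dip_s = 0) {
  stopifnot(length(center_um) == 2, radius_um > 0)
  if (baseline <= 0) stop("baseline must be positive")
  if (rise_s <= 0 || decay_s <= 0) stop("rise_s and decay_s must be positive")
  if (amplitude_rel < 0) stop("amplitude_rel must be non-negative")
  structure(
    list(center_um = as.numeric(center_um), radius_um = radius_um,
         baseline = baseline, amplitude_rel = amplitude_rel,
         onset_s = onset_s, rise_s = rise_s, plateau_s = plateau_s,
         decay_s = decay_s, channel_response = channel_response,
         dip_rel = dip_rel, dip_s = dip_s),
    class = "cell_spec"
  )
}

#' Ideal cell transient
#'
#' Relative fluorescence (1 = baseline) of a [cell_spec()] at times `t`:
#' piecewise linear rise, flat plateau, exponential decay.
#'
#' @param spec A [cell_spec()].
#' @param t Numeric vector of times (s), >= 0.
#' @return Numeric vector of relative intensities.
#' @export
cell_transient <- function(spec, t) {
  stopifnot(all(t >= 0))
  a <- spec$amplitude_rel
  t0 <- spec$onset_s
  t_rise <- t0 + spec$rise_s
  t_plat <- t_rise + spec$plateau_s
  out <- rep(1, length(t))
  if (spec$dip_rel > 0 && spec$dip_s > 0) {
    dip <- t >= (t0 - spec$dip_s) & t < t0
    out[dip] <- 1 - spec$dip_rel
  }
  ris <- t >= t0 & t < t_rise
  out[ris] <- 1 + a * (t[ris] - t0) / spec$rise_s
  pla <- t >= t_rise & t < t_plat
  out[pla] <- 1 + a
  dec <- t >= t_plat
  out[dec] <- 1 + a * exp(-(t[dec] - t_plat) / spec$decay_s)
  out
}

#' Configure a synthetic microendoscope movie
#'
#' Defaults mirror the measured geometry of the instrument being emulated:
#' a 147.5 µm circular FOV holding ~1460 cores at 3.71 µm mean spacing with
#' 2.34 µm core FWHM, imaged at 0.2883 µm/px onto a 512 x 512 camera frame
#' at 4.3 fps. Positional jitter defaults to 0.057 µm per axis so the SD of
#' nearest-neighbor spacing is ~0.08 µm (the difference of two jittered
#' centers carries twice the per-center variance).
#'
#' @param fov_diameter_um Circular FOV diameter (µm).
#' @param lattice_spacing_um Hexagonal core spacing (µm).
#' @param jitter_sd_um Isotropic Gaussian jitter SD per axis (µm).
#' @param core_fwhm_um Painted core spot FWHM (µm); also the Gaussian
#'   aperture over which a core samples the scene. Must be smaller than the
#'   lattice spacing.
#' @param raw_pixel_um Sample-plane size of one raw camera pixel (µm).
#' @param frame_px Raw frame side length (px); default fits the FOV.
#' @param n_frames Number of frames (>= 1).
#' @param frame_rate_fps Acquisition rate (frames/s).
#' @param channel_sequence Ordered excitation-channel labels; frames cycle
#'   through them starting at frame 1.
#' @param autofluorescence Named per-channel core autofluorescence (counts);
#'   an unnamed scalar applies to all channels.
#' @param flicker_sd SD of the multiplicative per-frame gain (gain ~
#'   Normal(1, flicker_sd)); 0 disables flicker.
#' @param motion `NULL` for no motion, or `list(amplitude_px =, period_s =)`
#'   for a rigid integer-pixel sinusoidal (breathing-like) shift of the scene
#'   relative to the fiber.
#' @param cells List of [cell_spec()] objects (possibly empty).
#' @param noise `NULL` for noise-free, or `list(poisson = TRUE, read_sd = 3)`
#'   (Poisson shot noise on the counts plus Gaussian read noise in counts).
#' @param sat_tolerance Maximum tolerated fraction of pixels exceeding the
#'   16-bit range per movie; more raises a saturation error.
#' @param seed Integer seed; a fixed seed makes the movie byte-identical.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fov_diameter_um = 147.5,
                             lattice_spacing_um = 3.71,
                             jitter_sd_um = 0.057,
                             core_fwhm_um = 2.34,
                             raw_pixel_um = 0.2883,
                             frame_px = NULL,
                             n_frames = 100,
                             frame_rate_fps = 4.3,
                             channel_sequence = "475",
                             autofluorescence = 300,
                             flicker_sd = 0.02,
                             motion = NULL,
                             cells = list(),
                             noise = list(poisson = TRUE, read_sd = 3),
                             sat_tolerance = 0,
                             seed = 1) {
  if (fov_diameter_um <= 0 || lattice_spacing_um <= 0)
    stop("FOV diameter and lattice spacing must be positive")
  if (lattice_spacing_um >= fov_diameter_um) stop("degenerate lattice")
  if (core_fwhm_um >= lattice_spacing_um)
    stop("core FWHM must be below the lattice spacing")
  if (n_frames < 1) stop("need at least one frame")
  if (length(channel_sequence) < 1L || anyDuplicated(channel_sequence))
    stop("channel labels must be non-empty and unique")
  if (is.null(frame_px))
    frame_px <- 2L * as.integer(ceiling(fov_diameter_um / raw_pixel_um / 2))
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  af <- autofluorescence
  if (is.null(names(af))) af <- setNames(rep(af[1], length(channel_sequence)),
                                         channel_sequence)
  if (!all(channel_sequence %in% names(af)))
    stop("autofluorescence must cover every channel")
  structure(
    list(fov_diameter_um = fov_diameter_um,
         lattice_spacing_um = lattice_spacing_um,
         jitter_sd_um = jitter_sd_um, core_fwhm_um = core_fwhm_um,
         raw_pixel_um = raw_pixel_um, frame_px = as.integer(frame_px),
         n_frames = as.integer(n_frames), frame_rate_fps = frame_rate_fps,
         channel_sequence = as.character(channel_sequence),
         autofluorescence = af, flicker_sd = flicker_sd, motion = motion,
         cells = cells, noise = noise, sat_tolerance = sat_tolerance,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate jittered hexagonal core centers
#'
#' Enumerates the ideal hexagonal lattice with the configured spacing,
#' keeps the points inside the circular FOV, and displaces each by isotropic
#' Gaussian jitter.
#'
#' @param config A [synthetic_config()].
#' @return N x 2 matrix of centers, columns `y_um`, `x_um`, relative to the
#'   FOV center.
#' @export
generate_lattice <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$lattice_spacing_um
  r <- config$fov_diameter_um / 2
  row_h <- s * sqrt(3) / 2
  jmax <- ceiling(r / row_h) + 1L
  pts <- do.call(rbind, lapply(seq(-jmax, jmax), function(j) {
    y <- j * row_h
    x_off <- if (j %% 2 == 0) 0 else s / 2
    imax <- ceiling(r / s) + 1L
    x <- seq(-imax, imax) * s + x_off
    cbind(y_um = y, x_um = x)
  }))
  pts <- pts[pts[, 1]^2 + pts[, 2]^2 <= r^2, , drop = FALSE]
  if (nrow(pts) == 0) stop("degenerate lattice")
  if (config$jitter_sd_um > 0) {
    pts <- with_seed(config$seed, {
      pts + matrix(rnorm(length(pts), sd = config$jitter_sd_um), ncol = 2)
    })
  }
  pts
}

# Gaussian-aperture weight of each cell seen by each core: the fraction of a
# unit-mass Gaussian aperture (FWHM = core FWHM) centered at the sampled
# scene position that falls inside the cell disk. For an isotropic Gaussian
# at distance d from a disk of radius R this is radial:
#   w(d) = int_0^R r/sigma^2 exp(-(r^2+d^2)/(2 sigma^2)) I0(r d/sigma^2) dr
# (the Marcum-Q complement), evaluated by fixed-grid quadrature with the
# exponentially scaled Bessel function for stability. Being an exact smooth
# function of distance, the weight pattern translates rigidly with the
# scene, which downstream registration relies on.
aperture_weights <- function(centers_um, cells, core_fwhm_um) {
  sigma <- core_fwhm_um / (2 * sqrt(2 * log(2)))
  n <- nrow(centers_um)
  out <- matrix(0, n, length(cells))
  for (k in seq_along(cells)) {
    cc <- cells[[k]]$center_um
    R <- cells[[k]]$radius_um
    d <- sqrt((centers_um[, 1] - cc[1])^2 + (centers_um[, 2] - cc[2])^2)
    # integrate only cores the aperture can reach
    reach <- d <= R + 6 * sigma
    if (!any(reach)) next
    dr <- d[reach]
    nr <- 96L
    r <- (seq_len(nr) - 0.5) * R / nr
    h <- R / nr
    # integrand with scaled Bessel: r/s^2 * exp(-(r-d)^2/(2 s^2)) * I0s(rd/s^2)
    w <- vapply(dr, function(di) {
      z <- r * di / sigma^2
      sum(r / sigma^2 * exp(-(r - di)^2 / (2 * sigma^2)) *
            besselI(z, 0, expon.scaled = TRUE)) * h
    }, numeric(1))
    out[reach, k] <- pmin(w, 1)
  }
  out
}

# Sparse painting operator: column i is the unit-amplitude Gaussian spot of
# core i rasterized on the raw frame (window +-3 sigma).
painting_matrix <- function(centers_px, frame_px, sigma_px) {
  hw <- max(1L, as.integer(ceiling(3 * sigma_px)))
  off <- seq(-hw, hw)
  win <- expand.grid(dy = off, dx = off)
  ii <- jj <- xx <- vector("list", nrow(centers_px))
  for (i in seq_len(nrow(centers_px))) {
    cy <- centers_px[i, 1]; cx <- centers_px[i, 2]
    y <- round(cy) + win$dy
    x <- round(cx) + win$dx
    keep <- y >= 1 & y <= frame_px & x >= 1 & x <= frame_px
    y <- y[keep]; x <- x[keep]
    v <- exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma_px^2))
    ii[[i]] <- y + (x - 1L) * frame_px
    jj[[i]] <- rep.int(i, length(y))
    xx[[i]] <- v
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(frame_px^2, nrow(centers_px)))
}

#' Render a synthetic raw movie with ground truth
#'
#' Composes, per frame: channel-dependent core autofluorescence plus the
#' aperture-weighted cell scene sampled at the (motion-shifted) core
#' positions; cores painted as Gaussian spots at their raw-pixel positions;
#' a multiplicative per-frame gain; Poisson and Gaussian noise; and 16-bit
#' quantization. The fiber (core pattern) is static; motion displaces the
#' scene relative to the fiber, which is what downstream registration of the
#' reconstructed movie must recover.
#'
#' @param config A [synthetic_config()].
#' @return A list with `stack` (a [raw_stack()]) and `truth`, a list holding
#'   `core_centers_um` (N x 2), `per_frame_shift_px` (tibble: frame, dy, dx —
#'   the rigid displacement of the image content relative to frame 1, in raw
#'   pixels; frame 1 is (0,0)), `cell_traces` (tibble: cell, frame, time_s,
#'   channel, rel_intensity), and `config`.
#' @export
render_movie <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  centers_um <- generate_lattice(config)
  n_core <- nrow(centers_um)
  W <- config$frame_px
  ctr <- (W + 1) / 2
  centers_px <- centers_um / config$raw_pixel_um + ctr
  sigma_px <- config$core_fwhm_um / (2 * sqrt(2 * log(2))) / config$raw_pixel_um
  P <- painting_matrix(centers_px, W, sigma_px)

  t_s <- (seq_len(config$n_frames) - 1) / config$frame_rate_fps
  chans <- config$channel_sequence[
    ((seq_len(config$n_frames) - 1L) %% length(config$channel_sequence)) + 1L]

  # integer sinusoidal scene shift (dy, dx), frame 1 at (0, 0)
  if (!is.null(config$motion)) {
    amp <- config$motion$amplitude_px
    per <- config$motion$period_s
    dy <- as.integer(round(amp * sin(2 * pi * t_s / per)))
    dx <- as.integer(round(amp * sin(2 * pi * t_s / per + pi / 2) -
                             amp * sin(pi / 2)))
  } else {
    dy <- dx <- integer(config$n_frames)
  }
  shifts <- cbind(dy, dx)

  # per-cell channel response resolved to the channel of each frame
  chresp <- function(cell, ch) {
    cr <- cell$channel_response
    if (is.null(names(cr))) cr[1] else if (ch %in% names(cr)) cr[[ch]] else 1
  }

  n_cell <- length(config$cells)
  trans <- if (n_cell)
    matrix(vapply(config$cells, cell_transient, numeric(length(t_s)),
                  t = t_s), nrow = length(t_s))
  else matrix(0, length(t_s), 0)

  # aperture weights cached per distinct scene shift
  wcache <- new.env(parent = emptyenv())
  weights_for <- function(dy_i, dx_i) {
    key <- paste(dy_i, dx_i)
    if (is.null(wcache[[key]])) {
      # image content displaced by +shift: cores sample the scene at -shift
      sc <- centers_um
      sc[, 1] <- sc[, 1] - dy_i * config$raw_pixel_um
      sc[, 2] <- sc[, 2] - dx_i * config$raw_pixel_um
      wcache[[key]] <- aperture_weights(sc, config$cells, config$core_fwhm_um)
    }
    wcache[[key]]
  }

  gains <- if (config$flicker_sd > 0)
    with_seed(config$seed + 1L, rnorm(config$n_frames, 1, config$flicker_sd))
  else rep(1, config$n_frames)

  frames <- array(0, dim = c(W, W, config$n_frames))
  n_sat <- 0
  noisy <- !is.null(config$noise)
  sim <- function() {
    for (tt in seq_len(config$n_frames)) {
      amp <- rep(config$autofluorescence[[chans[tt]]], n_core)
      if (n_cell) {
        wmat <- weights_for(shifts[tt, 1], shifts[tt, 2])
        cellsig <- vapply(seq_len(n_cell), function(k) {
          cl <- config$cells[[k]]
          cl$baseline * (1 + (trans[tt, k] - 1) * chresp(cl, chans[tt]))
        }, numeric(1))
        amp <- amp + as.numeric(wmat %*% cellsig)
      }
      img <- as.numeric(P %*% amp) * gains[tt]
      if (noisy) {
        if (isTRUE(config$noise$poisson)) img <- rpois(length(img), img)
        rs <- config$noise$read_sd
        if (!is.null(rs) && rs > 0) img <- img + rnorm(length(img), 0, rs)
      }
      img <- round(img)
      n_sat <<- n_sat + sum(img > 65535)
      frames[, , tt] <<- matrix(pmin(pmax(img, 0), 65535), W, W)
    }
  }
  if (noisy) with_seed(config$seed + 2L, sim()) else sim()

  if (n_sat > config$sat_tolerance * length(frames))
    stop("saturation: scene exceeds the 16-bit range")

  truth <- list(
    core_centers_um = centers_um,
    per_frame_shift_px = tibble::tibble(frame = seq_len(config$n_frames),
                                        dy = shifts[, 1], dx = shifts[, 2]),
    cell_traces = if (n_cell) tibble::tibble(
      cell = rep(seq_len(n_cell), each = length(t_s)),
      frame = rep(seq_along(t_s), n_cell),
      time_s = rep(t_s, n_cell),
      channel = rep(chans, n_cell),
      # per-channel ideal relative intensity seen on that frame
      rel_intensity = as.numeric(vapply(seq_len(n_cell), function(k) {
        cl <- config$cells[[k]]
        as.numeric(1 + (trans[, k] - 1) *
          vapply(chans, function(ch) chresp(cl, ch), numeric(1)))
      }, numeric(length(t_s))))
    ) else tibble::tibble(cell = integer(), frame = integer(),
                          time_s = numeric(), channel = character(),
                          rel_intensity = numeric()),
    config = config
  )
  list(
    stack = raw_stack(frames, frame_rate_fps = config$frame_rate_fps,
                      channels = config$channel_sequence),
    truth = truth
  )
}
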