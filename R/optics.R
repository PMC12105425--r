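#' Optical characterization of a fiber-bundle microendoscope
#'
#' Small analytic calculations used to characterize a GRIN-lens multicore
#' fiber endoscope: system magnification, sample-plane pixel size, field of
#' view geometry, ideal hexagonal core spacing, the Rayleigh diffraction
#' limit, and FWHM measurement on intensity profiles. Results are rounded to
#' the precision at which such quantities are conventionally reported
#' (magnification to two decimals, areas to three significant figures, core
#' density to one decimal, spacing to two decimals, resolution to the nearest
#' 10 nm).
#'
#' @name optics
NULL

#' Theoretical magnification of a 4f relay with a GRIN objective
#'
#' `M = f_tube / f_objective * |grin_mag|`. With a 3.6 mm objective, a 200 mm
#' tube lens and a unit-magnification GRIN lens this gives 55.56.
#'
#' @param f_objective_mm Objective focal length (mm).
#' @param f_tube_mm Tube lens focal length (mm).
#' @param grin_magnification Nominal GRIN relay magnification (its sign is
#'   an image inversion and is ignored). Default 1.
#' @return Magnification, rounded to two decimals.
#' @examples
#' theoretical_magnification(3.6, 200) # 55.56
#' @export
theoretical_magnification <- function(f_objective_mm, f_tube_mm,
                                      grin_magnification = 1) {
  stopifnot(is.numeric(f_objective_mm), is.numeric(f_tube_mm))
  if (f_objective_mm <= 0 || f_tube_mm <= 0)
    stop("focal lengths must be positive")
  round(f_tube_mm / f_objective_mm * abs(grin_magnification), 2)
}

#' Magnification measured from a known sample shift
#'
#' The sample is translated by a known distance with a micromanipulator and
#' the resulting pixel displacement of the fiber pattern on the camera is
#' measured; the displacement magnitude (Pythagoras on its two components)
#' times the camera pixel pitch, divided by the physical shift, is the
#' magnification. The sample-plane pixel size is the physical shift divided
#' by the pixel displacement.
#'
#' @param shift_um Physical sample shift (µm), > 0.
#' @param dpx Pixel displacement on the camera: a length-2 vector (dx, dy)
#'   or a single magnitude.
#' @param camera_pixel_um Camera pixel pitch (µm).
#' @return A list with `magnification` and `pixel_size_um` (sample plane).
#' @examples
#' magnification_from_shift(5, c(3, 4), 1) # M = 1, pixel 1 um
#' @export
magnification_from_shift <- function(shift_um, dpx, camera_pixel_um) {
  if (shift_um <= 0) stop("shift must be positive")
  mag_px <- sqrt(sum(dpx^2))
  if (mag_px == 0) stop("zero pixel displacement")
  list(
    magnification = mag_px * camera_pixel_um / shift_um,
    pixel_size_um = shift_um / mag_px
  )
}

#' Field-of-view area of a circular fiber bundle
#'
#' @param diameter_um FOV diameter (µm).
#' @return Area in µm², rounded to three significant figures
#'   (145 µm gives 16 500 µm²).
#' @export
fov_area <- function(diameter_um) {
  if (diameter_um <= 0) stop("diameter must be positive")
  signif(pi * (diameter_um / 2)^2, 3)
}

#' Bundle area per fiber core
#'
#' @param area_um2 Bundle area (µm²).
#' @param n_cores Number of cores.
#' @return µm² per core, one decimal (16 500 µm² / 1460 cores gives 11.3).
#' @export
core_density <- function(area_um2, n_cores) {
  if (area_um2 <= 0 || n_cores < 1) stop("invalid inputs")
  round(area_um2 / n_cores, 1)
}

#' Ideal hexagonal center-to-center core spacing
#'
#' For N cores hexagonally packed in a circular bundle of diameter D, each
#' core occupies a hexagonal cell of area (sqrt(3)/2) d^2, so
#' `d = sqrt(2 * pi * (D/2)^2 / (sqrt(3) * N))`. With 1460 cores in a
#' 147.5 µm bundle this gives 3.68 µm.
#'
#' @param n_cores Number of cores (>= 1).
#' @param fov_diameter_um Bundle diameter (µm).
#' @return Spacing in µm, rounded to two decimals.
#' @export
hex_spacing <- function(n_cores, fov_diameter_um) {
  if (n_cores < 1) stop("need at least one core")
  if (fov_diameter_um <= 0) stop("diameter must be positive")
  area <- pi * (fov_diameter_um / 2)^2
  round(sqrt(2 * area / (sqrt(3) * n_cores)), 2)
}

#' Rayleigh resolution limit
#'
#' `0.61 * lambda / NA`, rounded to the nearest 10 nm. At 475 nm and NA 0.4
#' this is 720 nm.
#'
#' @param wavelength_nm Wavelength (nm).
#' @param na Numerical aperture.
#' @return Resolution in nm, nearest 10 nm.
#' @export
rayleigh_resolution <- function(wavelength_nm, na) {
  if (wavelength_nm <= 0 || na <= 0) stop("invalid inputs")
  round(0.61 * wavelength_nm / na / 10) * 10
}

#' Full width at half maximum of a 1-D intensity profile
#'
#' Locates the global maximum, then linearly interpolates the half-maximum
#' crossing on each side of the peak. The half-maximum level is measured
#' relative to the profile minimum so a constant pedestal does not bias the
#' width.
#'
#' @param profile Numeric vector of intensity samples.
#' @param pixel_size_um Physical sample spacing (µm per sample). Default 1.
#' @return FWHM in µm.
#' @examples
#' fwhm(c(0, 0.5, 1, 0.5, 0)) # 2
#' @export
fwhm <- function(profile, pixel_size_um = 1) {
  n <- length(profile)
  if (n < 3) stop("profile too short")
  ipk <- which.max(profile)
  if (ipk == 1L || ipk == n)
    stop("no peak interior to the profile (monotone profile?)")
  lo <- min(profile)
  half <- lo + (profile[ipk] - lo) / 2
  cross <- function(idx_from, idx_to) {
    # walk from the peak outwards until the profile drops below half-max,
    # then interpolate the crossing position
    ii <- if (idx_from < idx_to) idx_from:idx_to else idx_from:idx_to
    for (k in seq_along(ii)[-1]) {
      a <- ii[k - 1]; b <- ii[k]
      if (profile[b] <= half) {
        if (profile[a] == profile[b]) return(b)
        return(a + (profile[a] - half) / (profile[a] - profile[b]) * (b - a))
      }
    }
    stop("no half-maximum crossing on one side of the peak")
  }
  left <- cross(ipk, 1L)
  right <- cross(ipk, n)
  abs(right - left) * pixel_size_um
}

#' Assemble an optical calibration record
#'
#' Combines the design constants and derived quantities into one tibble row,
#' enforcing `pixel_size_um = camera_pixel_um / magnification`.
#'
#' @param f_objective_mm,f_tube_mm,grin_magnification Relay optics constants.
#' @param camera_pixel_um Camera pixel pitch (µm).
#' @param numerical_aperture Fiber NA.
#' @param wavelength_nm Excitation wavelength (nm).
#' @param fov_diameter_um Bundle FOV diameter (µm).
#' @param n_cores Core count.
#' @return A one-row tibble with magnification, sample-plane pixel size, FOV
#'   area, core density, ideal hexagonal spacing and Rayleigh limit.
#' @export
optical_calibration <- function(f_objective_mm = 3.6, f_tube_mm = 200,
                                grin_magnification = 1,
                                camera_pixel_um = 16,
                                numerical_aperture = 0.4,
                                wavelength_nm = 475,
                                fov_diameter_um = 147.5,
                                n_cores = 1460) {
  m <- theoretical_magnification(f_objective_mm, f_tube_mm, grin_magnification)
  area <- fov_area(fov_diameter_um)
  tibble::tibble(
    magnification = m,
    pixel_size_um = camera_pixel_um / m,
    camera_pixel_um = camera_pixel_um,
    fov_diameter_um = fov_diameter_um,
    fov_area_um2 = area,
    n_cores = n_cores,
    um2_per_core = core_density(area, n_cores),
    hex_spacing_um = hex_spacing(n_cores, fov_diameter_um),
    rayleigh_nm = rayleigh_resolution(wavelength_nm, numerical_aperture)
  )
}
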