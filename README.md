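# fiberscope

Image processing for multicore fiber-bundle microendoscopy in R.

Ultrathin microendoscopes relay an image through a coherent bundle of
thousands of fiber cores, each core sampling one point of the scene. The
raw camera frames therefore show a honeycomb of bright core spots on dark
cladding, riding on strong core autofluorescence that is multiplied by
frame-to-frame camera gain flicker, and — in vivo — displaced by
breathing-like rigid motion. fiberscope turns such recordings into smooth,
artifact-corrected movies and single-cell functional traces:

- **Core segmentation** — Gaussian smoothing + watershed around each local
  maximum, with sub-pixel center refinement by neighbor-corrected Gaussian
  peak fitting; lattice statistics (core count, nearest-neighbor spacing,
  core diameter).
- **Honeycomb removal** — per-core mean intensities interpolated onto a
  128 × 128 grid by barycentric-linear interpolation on the Delaunay
  triangulation of the core centers (precomputed as one sparse operator
  per layout).
- **Background correction** — per-frame subtraction of the 25th in-bundle
  intensity percentile, which cancels gain flicker acting on the
  autofluorescence pedestal.
- **Motion correction** — FFT cross-correlation of every reconstructed
  frame against the first; integer peak offset, shift-back, per-frame
  validity mask.
- **Channels** — de-interleaving of frame-alternating excitation (e.g.
  475/555 nm at 4.3 fps → 2.15 fps per channel) and first-50-normalized
  ratio traces for ratiometric sensors (roGFP2-Orp1).
- **Traces** — ROI means, ΔF/F (= F/min(F) − 1), moving-median denoising,
  onset detection (first crossing of 80% or 96% of max), onset-aligned
  ensemble mean ± SD.
- **Optics** — the calibration arithmetic of such an instrument:
  magnification (f_tube/f_obj, 3.6/200 mm → 55.56×), shift-based measured
  magnification, FOV area, core density, ideal hexagonal spacing
  d = √(2A/(√3·N)), Rayleigh limit 0.61λ/NA, FWHM measurement.
- **Synthetic scope** — a generator producing raw movies with known ground
  truth (jittered hexagonal lattice, channel-dependent autofluorescence,
  gain flicker, Poisson/read noise, rigid motion, calcium-like cell
  transients), used throughout the test suite.

## Worked example

Simulate a default in-situ-style recording (147.5 µm FOV, ~1420 cores,
512² raw pixels, 172 frames at 4.3 fps, one cell responding with
amplitude 0.6), then run the pipeline:

```r
library(fiberscope)

optical_calibration()
#>   magnification pixel_size_um ... fov_area_um2 um2_per_core hex_spacing_um rayleigh_nm
#> 1         55.56        0.2879 ...        17100         11.7           3.68         720

cells <- list(cell_spec(center_um = c(10, -15), radius_um = 6, baseline = 600,
                        amplitude_rel = 0.6, onset_s = 10, rise_s = 2,
                        plateau_s = 3, decay_s = 17.5))
cfg <- synthetic_config(n_frames = 172, cells = cells, seed = 42)
mv  <- render_movie(cfg)

cm  <- segment_cores(build_reference(mv$stack, "time-average"))
cm
#> <core_map> 1417 cores on a 512 x 512 reference
lattice_stats(cm, pixel_size_um = 0.2883)
#>   n_cores mean_nn_spacing_um sd_nn_spacing_um mean_core_diameter_um ...
#> 1    1417              3.608           0.0511                 2.338 ...

rc  <- subtract_percentile(reconstruct(mv$stack, cm))
rc
#> <recon_stack> 172 frames, 128 x 128 grid, 4.3 fps, background-subtracted (p = 25)

pos <- (c(10, -15) / cfg$raw_pixel_um + (cfg$frame_px + 1) / 2 -
        rc$grid$origin_px) / rc$grid$step_px + 1
roi <- roi_disk(128, pos, 6 / cfg$raw_pixel_um / rc$grid$step_px)
tr  <- dff(median_filter(roi_mean_trace(rc, roi), 30))
max(tr$value)
#> peak dF/F: 0.579 at t = 13.3 s
autoplot(tr)
```

The segmentation finds all 1417 generated cores; the measured core
diameter (2.34 µm) matches the generator; the nearest-neighbor spacing of
the jittered lattice (3.61 µm mean) sits, as expected for a minimum
statistic over jittered distances, just below the 3.71 µm lattice
constant; and the extracted peak ΔF/F of 0.579 recovers the generated
amplitude 0.6 within 4% despite shot noise, read noise and 2% gain
flicker.

Multichannel and pipeline usage:

```r
# de-interleave a two-channel recording and form a normalized ratio trace
cs  <- deinterleave(rc)                       # when cfg uses two channels
rt  <- ratio_trace(roi_mean_trace(rc, roi, channel = "395"),
                   roi_mean_trace(rc, roi, channel = "475"))

# or run everything from a config
run_pipeline(pipeline_config(input = "movie.tif", output_dir = "out",
                             channels = c("475", "555"), register = TRUE,
                             roi_file = "rois.tif"))
```

A thin CLI wraps the same functions:
`inst/cli/fiberscope <simulate|segment|reconstruct|register|channels|trace|ratio|calibrate|run> [options]`.

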