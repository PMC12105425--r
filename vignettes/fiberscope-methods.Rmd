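---
title: "Processing fiber-bundle microendoscope movies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing fiber-bundle microendoscope movies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberscope)
```

## The problem

A multicore imaging fiber relays an image as thousands of discrete samples:
each core guides the light of one sample point, and the camera sees a
honeycomb of bright core spots separated by dark cladding. On top of this
sampling artifact, recordings carry substantial core autofluorescence,
frame-to-frame gain flicker that multiplies that autofluorescence, and — in
living animals — rigid breathing-like motion. fiberscope converts such raw
movies into smooth, artifact-corrected image series and extracts per-cell
functional traces (calcium ΔF/F, or dual-excitation ratios for redox
sensors such as roGFP2-Orp1).

The geometry the defaults describe is a bundle of ~1460 cores in a 147.5 µm
circular field of view: cores ~2.34 µm wide at ~3.71 µm center-to-center
spacing, imaged at ≈55× magnification so one raw camera pixel spans
0.2883 µm in the sample plane. With an ideal hexagonal arrangement that
core count and area predict a 3.68 µm spacing
(`hex_spacing(1460, 147.5)`), in good agreement with what is measured on
segmented images. Since the cores — not diffraction (`0.61 λ/NA ≈ 720 nm`
at 475 nm) — set the sampling density, the effective resolution of the
system is the core spacing.

## Pipeline

1. **Reference image** (`build_reference`): per-pixel mean over the movie,
   a designated frame, or the mean over a strongly autofluorescent
   excitation channel; anything in which every core is plainly visible.
2. **Core segmentation** (`segment_cores`): Gaussian smoothing (default
   σ = 1 raw px, about half a core radius — enough to merge intra-core
   noise without merging neighbors), then watershed so each basin contains
   exactly one local maximum. Basins whose peak lies below the 25th
   percentile of the smoothed reference are background (the dark corners
   outside the round bundle). Labels are ordered row-major by position so
   results do not depend on intensity ordering.
3. **Center refinement**: watershed-basin centroids carry a few tenths of
   a pixel of error (pixel-phase effects, neighbor tails leaking into each
   basin). Because downstream interpolation quality and lattice statistics
   depend on the centers, each core spot is refit as a 2-D Gaussian by
   weighted least squares on log intensities — linear in center, width and
   log-amplitude — while the current estimates of all neighbors within 2.5
   spacings are subtracted from the window. Four damped iterations
   (relaxation 0.5) converge; on unjittered synthetic bundles the centers
   are recovered to ~0.006 px and the fitted widths to a fraction of a
   percent. The damping matters: an undamped update oscillates because
   over-subtracted neighbors bias the next width estimate in the opposite
   direction.
4. **Lattice statistics** (`lattice_stats`): mean ± SD nearest-neighbor
   spacing from the refined centers; core diameter as the FWHM of the
   fitted spot width, corrected for the smoothing kernel by quadrature
   subtraction (`sqrt(fwhm² − fwhm_kernel²)`). A min-distance statistic is
   biased low by center noise (the minimum of several noisy distances sits
   below their common mean), which is why the refinement step is on by
   default.
5. **Reconstruction** (`reconstruct`): per-frame mean intensity of each
   core region, then barycentric-linear interpolation on the Delaunay
   triangulation of the core centers onto a 128 × 128 grid. The
   triangulation is computed once (deldir) and turned into a sparse
   grid-by-core weight matrix, so a movie reconstructs as one
   matrix product per frame. The grid spans the bounding square of the
   core centers (grid pixel ≈ 1.15 µm for the full bundle); pixels outside
   the convex hull are invalid and carry fill value 0. Interpolation is
   exact on affine fields and reproduces each core's value at its center.
6. **Background subtraction** (`subtract_percentile`): the 25th percentile
   of the in-mask intensities is subtracted from every frame. A per-frame
   percentile, rather than one fixed baseline, cancels multiplicative gain
   flicker acting on the large autofluorescence pedestal; the 25th
   percentile rather than the minimum keeps the estimate off the noise
   floor. Percentiles use the linear-interpolation convention (R quantile
   type 7; for values {1,2,3,4} the 25th percentile is 1.75). Negatives
   are kept, so the subtracted in-mask percentile of every frame is
   exactly 0 — export code may offset for display, analysis never does.
7. **Registration** (`register_stack`, optional): each frame has its
   out-of-bundle pixels replaced by the in-bundle mean (so the round
   border cannot dominate), its mean subtracted, and is cross-correlated
   against frame 1 by FFT; the integer peak offset is the displacement,
   and the frame is shifted back by it, vacated pixels filled with the
   mean and flagged invalid per frame. Ties break toward the smallest
   displacement, then row-major. Displacements beyond 25% of the grid are
   rejected with a warning. Registration must run on reconstructed
   frames: on raw frames the static honeycomb dominates the correlation
   and the measured shift is always zero — the API enforces this.
8. **Traces** (`roi_mean_trace`, `dff`, `median_filter`, `onset_index`,
   `align_and_average`): ROI mean over the valid region per frame;
   ΔF/F = F/min(F) − 1; centered moving median (window 30 frames at
   4.3 fps, 53 at 7.6 fps; an even window w covers [t − w/2, t + w/2 − 1]
   and even-count medians average the two central order statistics);
   onset as the first crossing of 80% of the trace maximum (96% for weak
   in-vivo signals); ensembles aligned at onset and summarized by mean and
   population SD (N in the denominator — sample SD is unstable for the
   3–4-cell ensembles this serves).
9. **Channels** (`deinterleave`, `ratio_trace`): frame k belongs to
   channel (k − 1) mod period, so a 4.3 fps two-channel recording yields
   2.15 fps per channel. Ratio traces pair frames by within-channel index
   (acquired ~230 ms apart, treated as simultaneous), divide point-wise,
   and normalize to the mean of the first 50 values; shorter recordings
   normalize by all values, with a warning.

## The synthetic generator

`synthetic_config()`/`render_movie()` emulate the instrument so every stage
is testable against ground truth. Defaults are the measured geometry above;
jitter defaults to 0.057 µm per axis so nearest-neighbor spacing scatters
by ~0.08 µm (a pair distance carries twice the per-center variance).
Per channel, each core carries an autofluorescence pedestal (default 300
counts) plus the aperture-weighted scene: a core reads a cell disk through
a Gaussian aperture with FWHM equal to the core diameter, computed as the
exact radial Gaussian-mass-in-disk integral (a Marcum-Q complement) so the
weight pattern translates rigidly under motion. Cores are painted as
Gaussian spots, the frame is multiplied by a per-frame gain
~Normal(1, 0.02), Poisson shot noise and Gaussian read noise (SD 3 counts)
are applied, and the result is quantized to 16 bits; scenes that exceed
the 16-bit range raise a saturation error rather than clipping silently.
Cell transients are a linear rise (1–3 s) to 1 + amplitude, an optional
plateau (<10 s), and an exponential return with a 15–50 s time constant;
the default in-situ amplitude is 0.6, echoing ~1.6-fold responses. A
shallow pre-onset dip is available behind a flag (off by default) because
its mechanism and shape in real recordings are unclear. Motion is a rigid
integer-pixel sinusoidal scene shift; sub-pixel and non-rigid motion are
out of scope.

What the generator does not emulate — and what passing tests therefore do
not show about real data: optical blur beyond the core aperture (the
measured 4.6 µm bead FWHM includes blur that is not modeled; the desk-scale
analogue is that a single-core impulse reconstructs with FWHM equal to one
lattice spacing), fiber-to-fiber cross-talk, photobleaching, broken cores,
non-rigid tissue deformation, and structured tissue background.

## Registration accuracy: an honest limit

On movies produced by this generator, recovered shifts track the true
scene motion only to within ~2 raw px. This is not a defect of the
correlator: the core lattice (12.9 raw px spacing) undersamples the scene,
so the reconstruction of a scene shifted by a few pixels is not an exact
translation of the original reconstruction — brute-force SSD matching of
the frames themselves shows the same ±1–2 px discrepancy, and
overlap-normalized correlation does not improve it. True integer
translations of reconstructed frames are recovered exactly, which is the
operation the registration implements and what its tests assert; the
generator-motion tests assert ≤2 px agreement and a tightly correlated
trajectory.

## Numerical and interface choices

- Percentile convention, even-window median centering, onset-tie and
  correlation-peak tie-breaks are all fixed and documented above, since
  conventions differ between environments.
- ΔF/F uses the minimum of the unfiltered ROI trace as baseline (the
  literal reading of the normalization); a min-based baseline is
  noise-biased, so onset detection and display run on the median-filtered
  trace.
- Whether ratio traces should use percentile-subtracted or raw channel
  intensities is not settled; the default is subtracted, and
  `roi_mean_trace` can be pointed at an unsubtracted reconstruction to do
  otherwise.
- Stacks travel as multipage TIFF (16-bit raw, scaled 32-bit float recon
  with the affine scale in a YAML sidecar); tables as CSV; configs as
  YAML with unknown keys rejected. A thin command-line front end
  (`inst/cli/fiberscope`, subcommands simulate / segment / reconstruct /
  register / channels / trace / ratio / calibrate / run) wraps the same
  functions.

## Problem sizes used in the test suite

Unit and property tests run on mini-bundles (30–40 µm FOV, 60–90 cores)
where ground truth is exact and fast; parameter-recovery checks run on the
full default geometry (147.5 µm, ~1420 cores at the default spacing, 512²
raw frames), with a 172-frame noisy movie (40 s at 4.3 fps) for the
end-to-end ΔF/F recovery and 240 interleaved frames for the two-channel
redox shape check. The full suite completes in about a minute on one CPU.

## Known limitations

Manual ROIs only (no cell detection); integer-pixel rigid registration
(no rotation, no sub-pixel fitting); no bleaching or cross-talk
correction; dead cores are not gap-filled — they interpolate like any
other core value. The diameter estimator assumes roughly Gaussian core
profiles; strongly non-Gaussian cores would need a different width
convention.
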