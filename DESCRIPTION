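Package: fiberscope
Title: Image Processing for Multicore Fiber-Bundle Microendoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs honeycomb-free fluorescence movies from raw
    multicore fiber-bundle microendoscope recordings and extracts single-cell
    functional traces. Fiber cores are segmented by watershed on a smoothed
    reference image, per-core mean intensities are interpolated onto a regular
    grid by triangulation-based linear interpolation, per-frame 25th-percentile
    background subtraction removes autofluorescence and gain flicker, and
    cross-correlation registration removes rigid motion. Frame-interleaved
    excitation channels are de-interleaved for ratiometric (e.g. roGFP2) redox
    analysis, and per-ROI dF/F traces are median-filtered, onset-aligned and
    ensemble-averaged. Includes the optical-characterization calculations
    (magnification, field of view, hexagonal core spacing, Rayleigh limit,
    FWHM) and a synthetic fiber-bundle movie generator with ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    deldir,
    ggplot2,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    interp,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
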