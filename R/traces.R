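#' Per-ROI functional traces
#'
#' Cell responses are read out as the spatial mean intensity inside a
#' manually delineated ROI over time, converted to relative change
#' (dF/F = F / min(F) - 1), denoised with a moving-window median filter,
#' and — for ensemble statistics — aligned at response onset (the first
#' crossing of a fixed fraction of the trace maximum) before averaging,
#' since response latencies vary between stimulations.
#'
#' @name traces
NULL

new_trace <- function(values, frame_rate_fps, t0_s = 0, history = character(),
                      channel = NULL) {
  out <- tibble::tibble(
    frame = seq_along(values),
    time_s = t0_s + (seq_along(values) - 1) / frame_rate_fps,
    value = as.numeric(values)
  )
  attr(out, "frame_rate_fps") <- frame_rate_fps
  attr(out, "history") <- history
  attr(out, "channel") <- channel
  class(out) <- c("fiber_trace", class(out))
  out
}

trace_values <- function(trace) {
  if (is.data.frame(trace)) trace$value else as.numeric(trace)
}

# rebuild a trace tibble around new values, appending to its history
update_trace <- function(trace, values, step) {
  if (is.data.frame(trace)) {
    out <- trace
    out$value <- values
    attr(out, "history") <- c(attr(out, "history"), step)
    out
  } else values
}

#' Circular ROI on the reconstruction grid
#'
#' Convenience constructor for disk-shaped ROIs.
#'
#' @param grid_n Grid side length.
#' @param center c(y, x) center in grid pixels.
#' @param radius Radius in grid pixels.
#' @return Logical grid_n x grid_n mask.
#' @export
roi_disk <- function(grid_n, center, radius) {
  yy <- outer(seq_len(grid_n) - center[1], rep(1, grid_n))
  xx <- outer(rep(1, grid_n), seq_len(grid_n) - center[2])
  yy^2 + xx^2 <= radius^2
}

#' ROI mean-intensity trace
#'
#' Per frame, the mean over the ROI intersected with the validity mask
#' (and, for registered stacks, with that frame's per-frame validity).
#'
#' @param recon A [recon_stack()].
#' @param roi Logical mask matching the grid.
#' @param channel Optional: restrict to frames of one excitation channel.
#' @return A `fiber_trace` tibble: `frame`, `time_s`, `value`, carrying the
#'   frame rate and a processing history as attributes.
#' @export
roi_mean_trace <- function(recon, roi, channel = NULL) {
  stopifnot(inherits(recon, "recon_stack"), is.logical(roi),
            all(dim(roi) == dim(recon$frames)[1:2]))
  base <- roi & recon$valid_mask
  if (!any(base)) stop("ROI does not intersect the valid region")
  sel <- seq_len(n_frames(recon))
  fps <- recon$frame_rate_fps
  t0 <- recon$t0_s %||% 0
  if (!is.null(channel)) {
    if (!channel %in% recon$channels) stop("unknown channel")
    sel <- which(frame_channels(recon) == channel)
    period <- length(recon$channels)
    t0 <- t0 + (which(recon$channels == channel) - 1) / fps
    fps <- fps / period
  }
  vals <- vapply(sel, function(k) {
    m <- base
    if (!is.null(recon$frame_valid)) m <- m & recon$frame_valid[, , k]
    if (!any(m)) return(NA_real_)
    mean(recon$frames[, , k][m])
  }, numeric(1))
  new_trace(vals, fps, t0_s = t0, history = "roi_mean", channel = channel)
}

#' Relative fluorescence change dF/F
#'
#' `F / min(F) - 1`: the trace normalized to its lowest intensity, minus
#' one. The minimum of the result is exactly 0 and the transform is
#' invariant to positive rescaling. Requires a positive baseline; on
#' background-subtracted data with a non-positive ROI minimum, add an
#' offset or extract the trace before subtraction.
#'
#' @param trace A `fiber_trace` tibble or numeric vector.
#' @return Same shape as the input, dF/F valued.
#' @export
dff <- function(trace) {
  v <- trace_values(trace)
  m <- min(v)
  if (!is.finite(m) || m <= 0)
    stop("nonpositive baseline: dF/F needs min(F) > 0 ",
         "(offset the trace or use unsubtracted reconstruction)")
  update_trace(trace, v / m - 1, "dff")
}

#' Moving-window median filter
#'
#' Centered moving median; for an even window of length w the window covers
#' `[t - w/2, t + w/2 - 1]` and an even count of samples is summarized by
#' the mean of the two central order statistics (R's `median`). Windows are
#' truncated at the trace ends. Typical windows: 30 frames for 4.3 fps
#' recordings, 53 frames for faster (7.6 fps) ones.
#'
#' @param trace A `fiber_trace` tibble or numeric vector.
#' @param window Window length in frames (>= 1).
#' @return Filtered trace, same shape as the input.
#' @export
median_filter <- function(trace, window) {
  v <- trace_values(trace)
  n <- length(v)
  if (window < 1) stop("window must be >= 1")
  if (window > 2 * n) stop("window larger than twice the trace length")
  half_lo <- floor(window / 2)
  half_hi <- ceiling(window / 2) - 1L
  out <- vapply(seq_len(n), function(t)
    median(v[max(1L, t - half_lo):min(n, t + half_hi)]), numeric(1))
  update_trace(trace, out, sprintf("median_filter(%d)", window))
}

#' Response onset index
#'
#' The earliest time point at which the trace reaches `fraction` of its
#' maximum. Compute it on the median-filtered trace: on raw traces, noise
#' jitters the crossing and misaligns the ensemble.
#'
#' @param trace A `fiber_trace` tibble or numeric vector (non-constant).
#' @param fraction Fraction of the maximum in (0, 1]. 0.8 suits strong
#'   responses; 0.96 is appropriate for weak (e.g. in vivo) signals.
#' @return Integer frame index (1-based).
#' @export
onset_index <- function(trace, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  v <- trace_values(trace)
  if (diff(range(v)) == 0) stop("constant trace has no onset")
  which(v >= fraction * max(v))[1]
}

#' Onset-aligned ensemble mean and SD
#'
#' Shifts each trace so the response onsets coincide, crops all members to
#' the maximal common window around the aligned onset, and computes the
#' per-timepoint mean and population SD (N in the denominator; sample SD is
#' unstable for the small ensembles — a few cells — this is used on).
#'
#' @param traces List of >= 2 traces (`fiber_trace` tibbles or numeric
#'   vectors) sharing a frame rate.
#' @param fraction Onset threshold fraction, see [onset_index()].
#' @param filter_window Optional median-filter window applied before onset
#'   detection and averaging; NULL if the traces are already filtered.
#' @return An `aligned_ensemble` tibble: `offset_frame` (0 at onset),
#'   `time_s`, `mean`, `sd`, `n`, with attributes `onsets` (per-member
#'   onset indices) and `aligned` (the member matrix).
#' @export
align_and_average <- function(traces, fraction = 0.8, filter_window = NULL) {
  if (length(traces) < 2) stop("need at least two traces to average")
  fps <- unique(vapply(traces, function(tr)
    attr(tr, "frame_rate_fps") %||% NA_real_, numeric(1)))
  fps <- fps[is.finite(fps)]
  if (length(fps) > 1) stop("traces have different frame rates")
  fps <- if (length(fps)) fps else 1
  vals <- lapply(traces, function(tr) {
    if (!is.null(filter_window)) tr <- median_filter(tr, filter_window)
    trace_values(tr)
  })
  onsets <- vapply(vals, onset_index, integer(1), fraction = fraction)
  lens <- lengths(vals)
  before <- min(onsets) - 1L
  after <- min(lens - onsets)
  if (before + after < 0) stop("empty common window")
  offs <- seq(-before, after)
  mat <- vapply(seq_along(vals), function(i)
    vals[[i]][onsets[i] + offs], numeric(length(offs)))
  mu <- rowMeans(mat)
  sdev <- sqrt(rowMeans((mat - mu)^2)) # population SD
  out <- tibble::tibble(offset_frame = offs, time_s = offs / fps,
                        mean = mu, sd = sdev, n = ncol(mat))
  attr(out, "onsets") <- onsets
  attr(out, "aligned") <- mat
  attr(out, "frame_rate_fps") <- fps
  class(out) <- c("aligned_ensemble", class(out))
  out
}
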