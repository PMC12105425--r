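#' Movie stack containers
#'
#' Two light S3 containers carry movies through the pipeline:
#'
#' * `raw_stack`: frames as captured through the fiber (16-bit counts),
#'   an `H x W x T` array with frame rate and excitation-channel metadata.
#' * `recon_stack`: honeycomb-free reconstructed frames (float, default
#'   128 x 128) with a validity mask marking grid pixels inside the convex
#'   hull of the fiber cores, the grid-to-raw-pixel transform, and the
#'   background-subtraction state.
#'
#' Frames are indexed `[y, x, t]` (row = y), matching how [tiff::readTIFF()]
#' returns pages.
#'
#' @name stacks
NULL

#' Construct a raw movie stack
#'
#' @param frames `H x W x T` numeric array (a matrix is taken as T = 1).
#' @param frame_rate_fps Acquisition frame rate (frames per second).
#' @param channels Character vector of excitation-channel labels cycled over
#'   frames (frame 1 carries `channels[1]`). Default a single channel.
#' @return A `raw_stack` object.
#' @export
raw_stack <- function(frames, frame_rate_fps = 1, channels = "ch1") {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (anyNA(frames) || any(!is.finite(frames)))
    stop("frames must be finite")
  if (frame_rate_fps <= 0) stop("frame rate must be positive")
  if (length(channels) < 1L || anyDuplicated(channels))
    stop("channel labels must be non-empty and unique")
  structure(
    list(frames = frames, frame_rate_fps = frame_rate_fps,
         channels = as.character(channels)),
    class = "raw_stack"
  )
}

#' Construct a reconstructed (honeycomb-free) stack
#'
#' Usually produced by [reconstruct()]; exported for programmatic use.
#'
#' @param frames `G x G x T` numeric array of interpolated frames.
#' @param valid_mask `G x G` logical matrix: `TRUE` inside the convex hull of
#'   the fiber cores. Pixels outside carry the fill value 0.
#' @param grid Grid transform as returned by the reconstruction: a list with
#'   `origin_px` (raw-pixel coordinate of grid pixel (1,1) center, c(y, x))
#'   and `step_px` (raw pixels per grid pixel).
#' @param frame_rate_fps,channels As in [raw_stack()].
#' @param background_subtracted Has per-frame percentile subtraction run?
#' @param percentile_p Percentile used for subtraction (if run).
#' @return A `recon_stack` object.
#' @export
recon_stack <- function(frames, valid_mask, grid = NULL,
                        frame_rate_fps = 1, channels = "ch1",
                        background_subtracted = FALSE, percentile_p = NA_real_) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            is.logical(valid_mask),
            all(dim(valid_mask) == dim(frames)[1:2]))
  structure(
    list(frames = frames, valid_mask = valid_mask, grid = grid,
         frame_rate_fps = frame_rate_fps, channels = as.character(channels),
         background_subtracted = isTRUE(background_subtracted),
         percentile_p = percentile_p),
    class = "recon_stack"
  )
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raw_stack> %d frames, %d x %d px, %.3g fps, channels: %s\n",
              d[3], d[1], d[2], x$frame_rate_fps,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
print.recon_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<recon_stack> %d frames, %d x %d grid, %.3g fps, %s%s\n",
    d[3], d[1], d[2], x$frame_rate_fps,
    if (x$background_subtracted)
      sprintf("background-subtracted (p = %g)", x$percentile_p)
    else "not background-subtracted",
    if (length(x$channels) > 1L)
      paste0(", channels: ", paste(x$channels, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Number of frames in a stack
#' @param x A `raw_stack` or `recon_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' Channel label of each frame
#'
#' Frames cycle through the stack's channel labels in order, starting with
#' the first label at frame 1.
#'
#' @param x A `raw_stack` or `recon_stack`.
#' @return Character vector, one label per frame.
#' @export
frame_channels <- function(x) {
  p <- length(x$channels)
  x$channels[((seq_len(n_frames(x)) - 1L) %% p) + 1L]
}

#' Frame acquisition times
#' @param x A `raw_stack` or `recon_stack`.
#' @return Numeric vector of times (s), frame 1 at t = 0.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1L) / x$frame_rate_fps
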