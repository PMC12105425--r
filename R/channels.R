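#' Frame-interleaved excitation channels
#'
#' Alternating the excitation wavelength on successive camera frames records
#' several channels quasi-simultaneously on one detector: with channels
#' ("475", "555") the odd frames (1st, 3rd, ...) carry the first channel and
#' the even frames the second, so a raw rate of 4.3 fps yields an effective
#' 2.15 fps per channel. De-interleaving splits such a stack; ratio traces
#' divide two channels' ROI traces point by point for ratiometric sensors
#' (e.g. roGFP2-Orp1), whose ratio is insensitive to expression level and
#' motion.
#'
#' @name channels
NULL

#' Split a frame-interleaved stack into per-channel stacks
#'
#' Frame k (1-based) is assigned to channel `((k - 1) mod period) + 1`;
#' each channel's frame rate is the raw rate divided by the period, and its
#' acquisition-time offset within the cycle is recorded in `t0_s`.
#'
#' @param stack A [raw_stack()] or [recon_stack()] whose `channels` field
#'   holds the excitation sequence (period = number of labels).
#' @return A named list of single-channel stacks (a `channel_set`), one per
#'   label, in sequence order. Channel lengths differ by at most one frame.
#' @export
deinterleave <- function(stack) {
  stopifnot(inherits(stack, "raw_stack") || inherits(stack, "recon_stack"))
  period <- length(stack$channels)
  chans <- frame_channels(stack)
  out <- lapply(seq_len(period), function(j) {
    lab <- stack$channels[j]
    sel <- which(chans == lab)
    sub <- stack
    sub$frames <- stack$frames[, , sel, drop = FALSE]
    if (!is.null(stack$frame_valid))
      sub$frame_valid <- stack$frame_valid[, , sel, drop = FALSE]
    sub$channels <- lab
    sub$frame_rate_fps <- stack$frame_rate_fps / period
    sub$t0_s <- (j - 1) / stack$frame_rate_fps
    sub
  })
  names(out) <- stack$channels
  structure(out, class = "channel_set")
}

#' Re-interleave a channel set into one stack
#'
#' Inverse of [deinterleave()]: frames of the member stacks are merged back
#' in sequence order. Round-trips exactly for any period.
#'
#' @param chset A `channel_set` from [deinterleave()].
#' @return The merged stack.
#' @export
interleave <- function(chset) {
  stopifnot(inherits(chset, "channel_set"))
  period <- length(chset)
  lens <- vapply(chset, n_frames, integer(1))
  if (max(lens) - min(lens) > 1L)
    stop("channel lengths differ by more than one frame")
  total <- sum(lens)
  first <- chset[[1]]
  d <- dim(first$frames)
  frames <- array(0, dim = c(d[1], d[2], total))
  for (j in seq_len(period)) {
    sel <- seq(j, total, by = period)
    frames[, , sel] <- chset[[j]]$frames
  }
  out <- first
  out$frames <- frames
  out$frame_valid <- NULL
  out$channels <- names(chset)
  out$frame_rate_fps <- first$frame_rate_fps * period
  out$t0_s <- NULL
  out
}

#' Normalized two-channel ratio trace
#'
#' Divides two per-ROI intensity traces point by point (frames paired by
#' within-channel index, acquired one raw-frame period apart and treated as
#' simultaneous) and normalizes the ratio to the mean of its initial
#' `n_norm` values, so the trace starts at 1 and reports relative change.
#' If the recording is shorter than `n_norm`, all available values are used
#' (with a warning).
#'
#' @param num,den Numerator and denominator traces: numeric vectors or
#'   trace tibbles with a `value` column (see [roi_mean_trace()]). Lengths
#'   are trimmed to the shorter.
#' @param n_norm Number of initial ratio values whose mean defines 1.
#'   Default 50.
#' @param frame_rate_fps Per-channel frame rate used for the time axis;
#'   taken from `num` if it is a trace tibble.
#' @return A `ratio_trace` tibble: `frame`, `time_s`, `ratio`, with
#'   attributes `n_norm_used` and channel labels when available.
#' @export
ratio_trace <- function(num, den, n_norm = 50, frame_rate_fps = NULL) {
  lab <- c(numerator = NA_character_, denominator = NA_character_)
  if (is.data.frame(num)) {
    if (is.null(frame_rate_fps))
      frame_rate_fps <- attr(num, "frame_rate_fps")
    lab["numerator"] <- attr(num, "channel") %||% NA_character_
    num <- num$value
  }
  if (is.data.frame(den)) {
    lab["denominator"] <- attr(den, "channel") %||% NA_character_
    den <- den$value
  }
  tlen <- min(length(num), length(den))
  if (tlen < 2) stop("need at least two paired time points")
  num <- num[seq_len(tlen)]
  den <- den[seq_len(tlen)]
  if (any(den <= 0)) stop("invalid denominator: non-positive values")
  r <- num / den
  k <- min(n_norm, tlen)
  if (k < n_norm)
    warning(sprintf("trace shorter than n_norm; normalizing by all %d values", k))
  r <- r / mean(r[seq_len(k)])
  fps <- frame_rate_fps %||% 1
  out <- tibble::tibble(frame = seq_len(tlen),
                        time_s = (seq_len(tlen) - 1) / fps,
                        ratio = r)
  attr(out, "n_norm_used") <- k
  attr(out, "channels") <- lab
  class(out) <- c("ratio_trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
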