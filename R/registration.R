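#' Rigid motion correction by cross-correlation
#'
#' Breathing and pulse move the sample rigidly under the fiber. Each
#' reconstructed frame is cross-correlated against the first frame and
#' shifted back by the integer peak offset. Registration operates on
#' reconstructed (honeycomb-free) frames only: on raw frames the static core
#' lattice dominates the correlation and the measured shift would always be
#' zero.
#'
#' @name registration
NULL

# integer-peak displacement of frame b relative to frame a via FFT
# cross-correlation; both already mean-filled and mean-subtracted
xcorr_peak <- function(a, b, max_shift) {
  g <- nrow(a)
  s <- 2L * g
  pa <- matrix(0, s, s); pa[1:g, 1:g] <- a
  pb <- matrix(0, s, s); pb[1:g, 1:g] <- b
  cc <- Re(fft(Conj(fft(pa)) * fft(pb), inverse = TRUE)) / s^2
  # index (dy, dx) of cc element k: circular shift, map to signed range
  sh <- c(0:(s / 2 - 1), -(s / 2):-1)
  dy <- rep(sh, times = s)
  dx <- rep(sh, each = s)
  ok <- abs(dy) <= max_shift & abs(dx) <= max_shift
  ccv <- as.numeric(cc)[ok]
  dyv <- dy[ok]; dxv <- dx[ok]
  top <- which(ccv >= max(ccv) - 1e-9 * max(abs(ccv)))
  # ties: smallest displacement magnitude, then row-major (dy, then dx)
  o <- order(dyv[top]^2 + dxv[top]^2, dyv[top], dxv[top])
  c(dyv[top[o[1]]], dxv[top[o[1]]])
}

# shift a matrix by integer (dy, dx), filling vacated pixels with `fill`;
# returns the shifted matrix and a logical matrix of still-valid pixels
shift_frame <- function(m, dy, dx, fill) {
  g1 <- nrow(m); g2 <- ncol(m)
  out <- matrix(fill, g1, g2)
  valid <- matrix(FALSE, g1, g2)
  ys <- seq_len(g1) + dy # source rows
  xs <- seq_len(g2) + dx
  oky <- ys >= 1 & ys <= g1
  okx <- xs >= 1 & xs <= g2
  if (any(oky) && any(okx)) {
    out[which(oky), which(okx)] <- m[ys[oky], xs[okx]]
    valid[which(oky), which(okx)] <- TRUE
  }
  list(frame = out, valid = valid)
}

#' Register a reconstructed stack against its first frame
#'
#' Per frame: pixels outside the bundle mask are replaced with the in-mask
#' mean (so the bundle border does not dominate the correlation), the frame
#' mean is subtracted, the normalized cross-correlation with frame 1 is
#' computed, and the integer offset of the correlation peak from the origin
#' is the measured displacement. The frame is then shifted back by that
#' displacement; vacated pixels are filled with the in-mask mean and marked
#' invalid in the per-frame validity array.
#'
#' Peak ties are broken by smallest displacement magnitude, then row-major
#' order. Displacements beyond `max_shift_frac` of the grid are rejected
#' (shift set to 0 with a warning), as is a zero-variance frame.
#'
#' @param recon A [recon_stack()].
#' @param max_shift_frac Largest accepted displacement as a fraction of the
#'   grid side. Default 0.25.
#' @param reference `"first"` (default) correlates against frame 1;
#'   `"mean"` against the time-average image (extension, off by default).
#' @return List with `stack` (registered [recon_stack()], carrying a
#'   `frame_valid` G x G x T logical array) and `shifts` (tibble: `frame`,
#'   `dy`, `dx` — the measured displacement of each frame relative to the
#'   reference; the frame was realigned by its negation).
#' @export
register_stack <- function(recon, max_shift_frac = 0.25,
                           reference = c("first", "mean")) {
  stopifnot(inherits(recon, "recon_stack"))
  reference <- match.arg(reference)
  g <- dim(recon$frames)[1]
  tt <- n_frames(recon)
  mask <- recon$valid_mask
  max_shift <- floor(max_shift_frac * g)

  prep <- function(fr) {
    mu <- mean(fr[mask])
    fr[!mask] <- mu
    fr - mean(fr)
  }
  ref <- if (reference == "first") prep(recon$frames[, , 1])
         else prep(apply(recon$frames, c(1, 2), mean))
  ref_sd <- stats::sd(as.numeric(ref))

  shifts <- matrix(0L, tt, 2)
  frame_valid <- array(TRUE, dim = dim(recon$frames))
  out <- recon$frames
  for (k in seq_len(tt)) {
    fr <- recon$frames[, , k]
    mu <- mean(fr[mask])
    pf <- prep(fr)
    if (ref_sd == 0 || stats::sd(as.numeric(pf)) == 0) {
      warning(sprintf("frame %d: zero variance, shift set to (0,0)", k))
      next
    }
    d <- xcorr_peak(ref, pf, max_shift = max_shift)
    if (max(abs(d)) >= max_shift) {
      warning(sprintf(
        "frame %d: correlation peak at the shift limit, rejected (0,0)", k))
      d <- c(0L, 0L)
    }
    shifts[k, ] <- d
    if (any(d != 0)) {
      sh <- shift_frame(fr, d[1], d[2], fill = mu)
      out[, , k] <- sh$frame
      frame_valid[, , k] <- sh$valid
    }
  }
  reg <- recon
  reg$frames <- out
  reg$frame_valid <- frame_valid
  list(
    stack = reg,
    shifts = tibble::tibble(frame = seq_len(tt),
                            dy = shifts[, 1], dx = shifts[, 2])
  )
}
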