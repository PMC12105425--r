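#' Honeycomb removal by per-core averaging and interpolation
#'
#' Raw fiber-bundle frames show the honeycomb of bright cores. The
#' reconstruction averages each frame over every segmented core region,
#' interpolates the per-core means onto a regular (default 128 x 128) grid
#' by barycentric-linear interpolation on the Delaunay triangulation of the
#' core centers, and subtracts the per-frame 25th intensity percentile of
#' the in-bundle pixels to remove autofluorescence and multiplicative gain
#' flicker.
#'
#' @name reconstruction
NULL

#' Per-core mean intensities over time
#'
#' @param stack A [raw_stack()] whose geometry matches the core map.
#' @param coremap A `core_map` from [segment_cores()].
#' @return A `core_traces` object: list with `values` (T x N matrix of mean
#'   counts), `frame_rate_fps`, `channels`.
#' @export
extract_core_means <- function(stack, coremap) {
  stopifnot(inherits(stack, "raw_stack"), inherits(coremap, "core_map"))
  if (!all(dim(stack$frames)[1:2] == dim(coremap$label_image)))
    stop("stack geometry does not match the core map")
  idx <- which(coremap$label_image > 0)
  lab <- coremap$label_image[idx]
  npx <- dim(stack$frames)[1] * dim(stack$frames)[2]
  tt <- n_frames(stack)
  pix <- matrix(stack$frames, npx, tt)[idx, , drop = FALSE]
  sums <- rowsum(pix, lab)
  counts <- tabulate(lab, nbins = coremap$n_cores)
  values <- t(sums / counts)
  dimnames(values) <- NULL
  structure(
    list(values = values, frame_rate_fps = stack$frame_rate_fps,
         channels = stack$channels),
    class = "core_traces"
  )
}

#' @export
print.core_traces <- function(x, ...) {
  cat(sprintf("<core_traces> %d frames x %d cores\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Precompute the interpolation operator for a core layout
#'
#' Builds, once per core layout, the sparse matrix that maps N per-core
#' values to the `grid_n` x `grid_n` reconstruction grid: the core centers
#' are Delaunay-triangulated and each in-hull grid pixel receives the
#' barycentric weights of its enclosing triangle's three vertices. Pixels
#' outside the convex hull are invalid and filled with 0.
#'
#' @param centers_px N x 2 matrix of core centers (columns y, x, raw px),
#'   N >= 3, not all collinear.
#' @param grid_n Grid side length (128 matches typical core oversampling).
#' @param bbox Optional square to map onto the grid: `c(y0, y1, x0, x1)` in
#'   raw px. Default: the bounding square of the centers.
#' @return An `interp_operator`: list with `W` (sparse grid_n^2 x N),
#'   `valid_mask` (grid_n x grid_n logical), `grid` (list `origin_px` =
#'   raw-px coordinate of grid pixel (1,1)'s center, `step_px`), `centers_px`.
#' @export
interp_operator <- function(centers_px, grid_n = 128, bbox = NULL) {
  stopifnot(is.matrix(centers_px), ncol(centers_px) == 2)
  n <- nrow(centers_px)
  if (n < 3) stop("need at least 3 core centers to triangulate")
  y <- centers_px[, 1]; x <- centers_px[, 2]
  ev <- eigen(stats::cov(cbind(y, x)), symmetric = TRUE, only.values = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1))
    stop("core centers are collinear")
  if (is.null(bbox)) {
    side <- max(diff(range(y)), diff(range(x)))
    cy <- mean(range(y)); cx <- mean(range(x))
    bbox <- c(cy - side / 2, cy + side / 2, cx - side / 2, cx + side / 2)
  }
  step <- (bbox[2] - bbox[1]) / grid_n
  org <- c(bbox[1] + step / 2, bbox[3] + step / 2)
  gy <- org[1] + (seq_len(grid_n) - 1) * step
  gx <- org[2] + (seq_len(grid_n) - 1) * step
  py <- rep(gy, times = grid_n) # column-major: y fastest
  px <- rep(gx, each = grid_n)

  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (length(tl) == 0) stop("triangulation failed (collinear centers?)")

  assigned <- logical(grid_n^2)
  ii <- jj <- ww <- vector("list", length(tl))
  eps <- 1e-9
  for (k in seq_along(tl)) {
    tr <- tl[[k]]
    ay <- tr$y[1]; ax <- tr$x[1]
    by <- tr$y[2]; bx <- tr$x[2]
    cy2 <- tr$y[3]; cx2 <- tr$x[3]
    cand <- which(!assigned &
                    py >= min(ay, by, cy2) - eps & py <= max(ay, by, cy2) + eps &
                    px >= min(ax, bx, cx2) - eps & px <= max(ax, bx, cx2) + eps)
    if (length(cand) == 0) next
    det <- (bx - ax) * (cy2 - ay) - (cx2 - ax) * (by - ay)
    if (abs(det) < 1e-12) next
    l1 <- ((bx - px[cand]) * (cy2 - py[cand]) -
             (cx2 - px[cand]) * (by - py[cand])) / det
    l2 <- ((cx2 - px[cand]) * (ay - py[cand]) -
             (ax - px[cand]) * (cy2 - py[cand])) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(inside)) next
    g <- cand[inside]
    assigned[g] <- TRUE
    ii[[k]] <- rep(g, 3L)
    jj[[k]] <- rep(tr$ptNum, each = length(g))
    ww[[k]] <- c(l1[inside], l2[inside], l3[inside])
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(grid_n^2, n))
  structure(
    list(W = W, valid_mask = matrix(assigned, grid_n, grid_n),
         grid = list(origin_px = org, step_px = step, grid_n = grid_n),
         centers_px = centers_px),
    class = "interp_operator"
  )
}

#' Interpolate one frame of per-core values onto the grid
#'
#' @param core_values Numeric vector, one mean intensity per core.
#' @param op An [interp_operator()]; alternatively pass `centers_px` and
#'   `grid_n` to build one on the fly.
#' @param centers_px,grid_n Used only when `op` is NULL.
#' @return List with `frame` (grid_n x grid_n matrix, 0 outside the hull)
#'   and `valid_mask`.
#' @export
interpolate_frame <- function(core_values, op = NULL, centers_px = NULL,
                              grid_n = 128) {
  if (is.null(op)) op <- interp_operator(centers_px, grid_n)
  stopifnot(inherits(op, "interp_operator"),
            length(core_values) == ncol(op$W))
  g <- op$grid$grid_n
  list(frame = matrix(as.numeric(op$W %*% core_values), g, g),
       valid_mask = op$valid_mask)
}

#' Reconstruct a honeycomb-free movie
#'
#' Runs per-core averaging and triangulation-based linear interpolation for
#' every frame of the stack.
#'
#' @param stack A [raw_stack()].
#' @param coremap A `core_map` from [segment_cores()].
#' @param grid_n Reconstruction grid side (default 128).
#' @param bbox Optional square mapped onto the grid (see
#'   [interp_operator()]).
#' @return A [recon_stack()].
#' @export
reconstruct <- function(stack, coremap, grid_n = 128, bbox = NULL) {
  ct <- extract_core_means(stack, coremap)
  op <- interp_operator(coremap$centers_px, grid_n = grid_n, bbox = bbox)
  dense <- as.matrix(op$W %*% t(ct$values)) # grid_n^2 x T
  frames <- array(dense, dim = c(grid_n, grid_n, n_frames(stack)))
  recon_stack(frames, valid_mask = op$valid_mask, grid = op$grid,
              frame_rate_fps = stack$frame_rate_fps,
              channels = stack$channels)
}

#' Per-frame percentile background subtraction
#'
#' Subtracts, from every frame, the p-th percentile of its in-mask (inside
#' the bundle) pixel intensities. Using a per-frame percentile rather than a
#' single fixed baseline cancels multiplicative gain flicker acting on the
#' large autofluorescence pedestal; using the 25th percentile rather than
#' the minimum makes the estimate robust to noise while still tracking the
#' dark regions of the image. Percentiles use the linear-interpolation
#' convention between closest ranks (R's default quantile type 7). Negative
#' results are retained so the in-mask p-th percentile of every subtracted
#' frame is exactly 0.
#'
#' @param recon A [recon_stack()] not yet background-subtracted.
#' @param p Percentile in (0, 100). Default 25.
#' @return The subtracted [recon_stack()] with `background_subtracted` set.
#' @export
subtract_percentile <- function(recon, p = 25) {
  stopifnot(inherits(recon, "recon_stack"))
  if (recon$background_subtracted)
    stop("stack is already background-subtracted")
  if (p <= 0 || p >= 100) stop("p must be in (0, 100)")
  mask <- recon$valid_mask
  for (tt in seq_len(n_frames(recon))) {
    fr <- recon$frames[, , tt]
    q <- stats::quantile(fr[mask], p / 100, names = FALSE, type = 7)
    fr[mask] <- fr[mask] - q
    recon$frames[, , tt] <- fr
  }
  recon$background_subtracted <- TRUE
  recon$percentile_p <- p
  recon
}
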