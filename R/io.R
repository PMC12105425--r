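#' File formats
#'
#' Movies travel as multipage grayscale TIFF: raw stacks as 16-bit unsigned
#' integers, reconstructed stacks as 32-bit float. Because the TIFF writer
#' stores values in `[0, 1]`, float stacks are written with an affine
#' scale/offset that is recorded in a YAML sidecar (`<name>.yml`) next to
#' the image and undone on read; the sidecar also carries the frame rate,
#' the excitation-channel sequence, and the background-subtraction state,
#' so a write/read round trip reproduces the stack and its metadata. The
#' validity mask of a reconstructed stack is written as `<name>_mask.tif`.
#' Tables (core centers, lattice statistics, shifts, traces, ensembles) are
#' plain CSV.
#'
#' @name fiberscope_io
NULL

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yml")
mask_path <- function(path) paste0(sub("\\.tiff?$", "", path), "_mask.tif")

#' Write a movie stack to multipage TIFF plus YAML sidecar
#'
#' @param stack A [raw_stack()] (written as 16-bit integer) or
#'   [recon_stack()] (written as scaled 32-bit float; scale recorded in the
#'   sidecar, validity mask written alongside).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  tt <- n_frames(stack)
  if (inherits(stack, "raw_stack")) {
    fr <- stack$frames
    if (any(fr < 0 | fr > 65535) || any(fr != round(fr)))
      stop("raw stacks must hold integers in [0, 65535]")
    pages <- lapply(seq_len(tt), function(k) fr[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta <- list(type = "raw", frame_rate_fps = stack$frame_rate_fps,
                 channels = as.list(stack$channels),
                 t0_s = stack$t0_s %||% 0)
  } else if (inherits(stack, "recon_stack")) {
    fr <- stack$frames
    lo <- min(fr); hi <- max(fr)
    span <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(tt), function(k) (fr[, , k] - lo) / span)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
    tiff::writeTIFF(list(stack$valid_mask * 1), mask_path(path),
                    bits.per.sample = 8L)
    meta <- list(type = "recon", frame_rate_fps = stack$frame_rate_fps,
                 channels = as.list(stack$channels),
                 t0_s = stack$t0_s %||% 0,
                 scale_lo = lo, scale_hi = lo + span,
                 background_subtracted = stack$background_subtracted,
                 percentile_p = stack$percentile_p,
                 grid = stack$grid)
  } else stop("not a stack")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a movie stack written by [write_stack()]
#'
#' Also reads plain multipage grayscale TIFFs from other sources (no
#' sidecar): these come back as raw stacks with the supplied metadata.
#'
#' @param path TIFF path.
#' @param frame_rate_fps,channels Metadata used when no sidecar is present.
#' @return A [raw_stack()] or [recon_stack()].
#' @export
read_stack <- function(path, frame_rate_fps = 1, channels = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("not a grayscale TIFF (multi-sample pages found)")
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d1), logical(1))))
    stop("inconsistent page shapes")
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else NULL
  if (is.null(meta) || identical(meta$type, "raw")) {
    frames <- array(unlist(pages), dim = c(d1, length(pages)))
    st <- raw_stack(frames,
                    frame_rate_fps = meta$frame_rate_fps %||% frame_rate_fps,
                    channels = unlist(meta$channels) %||% channels)
    st$t0_s <- meta$t0_s %||% NULL
    return(st)
  }
  # float pages come back in [0, 1]; undo the recorded affine scale
  pages <- tiff::readTIFF(path, all = TRUE)
  lo <- meta$scale_lo; hi <- meta$scale_hi
  frames <- array(unlist(pages), dim = c(d1, length(pages))) * (hi - lo) + lo
  mask <- tiff::readTIFF(mask_path(path)) > 0.5
  grid <- meta$grid
  st <- recon_stack(frames, valid_mask = mask, grid = grid,
                    frame_rate_fps = meta$frame_rate_fps,
                    channels = unlist(meta$channels),
                    background_subtracted = isTRUE(meta$background_subtracted),
                    percentile_p = meta$percentile_p %||% NA_real_)
  st$t0_s <- meta$t0_s %||% NULL
  st
}

#' Write a core map as label TIFF plus centers CSV
#'
#' @param coremap A `core_map`.
#' @param prefix Output path prefix; writes `<prefix>_labels.tif` and
#'   `<prefix>_centers.csv`.
#' @return `prefix`, invisibly.
#' @export
write_coremap <- function(coremap, prefix) {
  stopifnot(inherits(coremap, "core_map"))
  tiff::writeTIFF(coremap$label_image / 65535,
                  paste0(prefix, "_labels.tif"), bits.per.sample = 16L)
  utils::write.csv(
    data.frame(core = seq_len(coremap$n_cores),
               y_px = coremap$centers_px[, 1],
               x_px = coremap$centers_px[, 2]),
    paste0(prefix, "_centers.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read ROI definitions
#'
#' Two formats: a label-mask TIFF (each positive integer label is one ROI)
#' or a polygon JSON file — an array of objects with `label`, `y`, `x`
#' (vertex coordinates in grid pixels), rasterized by the even-odd rule.
#'
#' @param path `.tif`/`.tiff` or `.json` file.
#' @param grid_n Grid side, required for polygon input.
#' @return Named list of logical masks.
#' @export
read_rois <- function(path, grid_n = 128) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (!is.matrix(img)) stop("ROI TIFF must be single-page grayscale")
    ids <- sort(setdiff(unique(as.integer(img)), 0L))
    out <- lapply(ids, function(i) img == i)
    names(out) <- paste0("roi", ids)
    return(out)
  }
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("polygon ROIs require the jsonlite package")
  polys <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(polys, function(p) polygon_mask(p$y, p$x, grid_n))
  names(out) <- vapply(polys, function(p)
    as.character(p$label %||% "roi"), character(1))
  out
}

# even-odd rasterization of one polygon on a grid_n x grid_n grid
polygon_mask <- function(py, px, grid_n) {
  ys <- rep(seq_len(grid_n), times = grid_n)
  xs <- rep(seq_len(grid_n), each = grid_n)
  n <- length(py)
  inside <- rep(FALSE, grid_n^2)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, grid_n, grid_n)
}

#' Write a trace, ensemble or other tabular result to CSV
#'
#' @param x A tibble/data frame (trace, ratio trace, shifts, ensemble,
#'   lattice statistics).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
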