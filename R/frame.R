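#' Ultrasound frame
#'
#' A single B-mode grayscale frame. Rows index axial depth (increasing
#' downward, so a posterior shadow sits at larger row indices), columns index
#' the lateral direction. Intensities are non-negative echo amplitudes on
#' whatever raw scale the source file used; [normalize_minmax()] maps them to
#' scaled intensity units (SIU) before analysis.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_spacing_mm Physical size of one pixel in millimetres
#'   (default 0.35, a typical abdominal B-mode sampling).
#' @param source_id Opaque identifier carried through to results.
#'
#' @return An object of class `us_frame` with elements `pixels`,
#'   `pixel_spacing_mm` and `source_id`.
#' @export
#' @examples
#' fr <- us_frame(matrix(runif(100, 0, 255), 10, 10))
#' dim(fr)
us_frame <- function(pixels, pixel_spacing_mm = 0.35, source_id = "frame") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("frame must have at least one row and one column.")
  }
  if (!all(is.finite(pixels))) abort("frame intensities must all be finite.")
  if (any(pixels < 0)) abort("frame intensities must be non-negative.")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0) {
    abort("`pixel_spacing_mm` must be a single positive number.")
  }
  structure(
    list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
         source_id = as.character(source_id)),
    class = "us_frame"
  )
}

#' @export
dim.us_frame <- function(x) dim(x$pixels)

#' @export
print.us_frame <- function(x, ...) {
  cat(sprintf("<us_frame> %s: %d x %d px, %.3g mm/px, intensity range [%g, %g]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale ultrasound frame from PNG or TIFF
#'
#' Integer-coded rasters are returned on their stored integer scale (0..255
#' for 8-bit, 0..65535 for 16-bit), so a frame written by
#' [generate_dataset()] reads back pixel-exact. RGB rasters are collapsed to
#' one plane by the unweighted channel mean (clinical B-mode exports are
#' gray-in-RGB, so any channel convention is equivalent).
#'
#' @param path Path to a PNG or TIFF file.
#' @inheritParams us_frame
#' @return A [us_frame].
#' @export
read_frame <- function(path, pixel_spacing_mm = 0.35,
                       source_id = basename(path)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    bd <- attr(px, "info")$bit.depth
    if (is.null(bd)) bd <- 8L
    px <- round(px * (2^bd - 1))
  } else {
    abort(sprintf("unsupported image format '%s' (PNG and TIFF are supported).", ext))
  }
  if (length(dim(px)) == 3L) {
    # unweighted mean over colour channels (alpha, if present, is dropped)
    nc <- min(dim(px)[3], 3L)
    px <- apply(px[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  px <- as.matrix(px)
  if (nrow(px) < 1L || ncol(px) < 1L) abort("zero-sized raster.")
  mode(px) <- "double"
  us_frame(px, pixel_spacing_mm = pixel_spacing_mm, source_id = source_id)
}

#' Rectangular region of interest
#'
#' 1-based closed box: rows `row0 .. row0 + n_rows - 1`, columns
#' `col0 .. col0 + n_cols - 1`.
#'
#' @param row0,col0 Top-left corner (1-based).
#' @param n_rows,n_cols Extents in pixels (each at least 1).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row0, col0, n_rows, n_cols) {
  v <- c(row0 = row0, col0 = col0, n_rows = n_rows, n_cols = n_cols)
  if (!all(is.finite(v)) || any(v != round(v))) {
    abort("roi_box fields must be finite integers.")
  }
  if (row0 < 1L || col0 < 1L) abort("roi_box corner must be at least (1, 1).")
  if (n_rows < 1L || n_cols < 1L) abort("roi_box extents must be at least 1.")
  v <- as.integer(v)
  structure(list(row0 = v[1L], col0 = v[2L], n_rows = v[3L], n_cols = v[4L]),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> rows %d..%d, cols %d..%d\n",
              x$row0, x$row0 + x$n_rows - 1L, x$col0, x$col0 + x$n_cols - 1L))
  invisible(x)
}

roi_rows <- function(roi) seq.int(roi$row0, roi$row0 + roi$n_rows - 1L)
roi_cols <- function(roi) seq.int(roi$col0, roi$col0 + roi$n_cols - 1L)

check_roi_within <- function(roi, n_row, n_col) {
  if (roi$row0 < 1L) abort("ROI extends beyond the top edge of the frame.")
  if (roi$col0 < 1L) abort("ROI extends beyond the left edge of the frame.")
  if (roi$row0 + roi$n_rows - 1L > n_row) {
    abort("ROI extends beyond the bottom edge of the frame.")
  }
  if (roi$col0 + roi$n_cols - 1L > n_col) {
    abort("ROI extends beyond the right edge of the frame.")
  }
  invisible(TRUE)
}

#' Crop a frame to a region of interest
#'
#' All downstream analysis operates exclusively inside the operator-drawn ROI;
#' this mirrors routine clinical practice, where the examiner designates the
#' suspected stone region and its downstream shadow zone.
#'
#' @param frame A [us_frame].
#' @param roi A [roi_box] lying fully inside the frame.
#' @return A [us_frame] holding the sub-grid, spacing inherited.
#' @export
crop_roi <- function(frame, roi) {
  stopifnot(inherits(frame, "us_frame"), inherits(roi, "roi_box"))
  check_roi_within(roi, nrow(frame$pixels), ncol(frame$pixels))
  us_frame(frame$pixels[roi_rows(roi), roi_cols(roi), drop = FALSE],
           pixel_spacing_mm = frame$pixel_spacing_mm,
           source_id = frame$source_id)
}

#' Min-max normalization to scaled intensity units (SIU)
#'
#' Maps intensities linearly so the ROI minimum becomes 0 and the maximum
#' becomes `scale_max`. With the default `scale_max = 1000`, the screening
#' thresholds (`tau_lc = 300`, `tau_sr = 100`) apply directly as stated.
#' A constant input maps to all zeros.
#'
#' @param frame A [us_frame] (or `siu_image`; re-normalizing is idempotent).
#' @param scale_max Upper end of the scaled range, default 1000.
#' @return An object of class `siu_image`: elements `pixels`, `scale_max`,
#'   `pixel_spacing_mm`, `source_id`.
#' @export
normalize_minmax <- function(frame, scale_max = 1000) {
  stopifnot(inherits(frame, c("us_frame", "siu_image")))
  if (!is.numeric(scale_max) || length(scale_max) != 1L || scale_max <= 0) {
    abort("`scale_max` must be a single positive number.")
  }
  px <- frame$pixels
  lo <- min(px); hi <- max(px)
  out <- if (hi > lo) (px - lo) / (hi - lo) * scale_max else px * 0
  structure(
    list(pixels = out, scale_max = scale_max,
         pixel_spacing_mm = frame$pixel_spacing_mm,
         source_id = frame$source_id),
    class = "siu_image"
  )
}

#' @export
dim.siu_image <- function(x) dim(x$pixels)

#' @export
print.siu_image <- function(x, ...) {
  cat(sprintf("<siu_image> %s: %d x %d px, scale_max %g\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$scale_max))
  invisible(x)
}

# replicate-pad row/col index helper: clamps out-of-range indices to the edge
clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

#' Median denoising
#'
#' Square-kernel median filter with edge replication at the borders. The
#' default 3x3 kernel suppresses isolated speckle impulses before
#' morphological enhancement while preserving edges.
#'
#' @param image A `siu_image` (or `us_frame`).
#' @param kernel Odd kernel side length, default 3.
#' @return Object of the same class with filtered pixels.
#' @export
median_denoise <- function(image, kernel = 3L) {
  stopifnot(inherits(image, c("us_frame", "siu_image")))
  if (length(kernel) != 1L || !is.finite(kernel) || kernel < 1L ||
      kernel != round(kernel) || kernel %% 2L == 0L) {
    abort("`kernel` must be a single odd integer >= 1.")
  }
  kernel <- as.integer(kernel)
  out <- image
  if (kernel == 1L) return(out)
  m <- image$pixels
  nr <- nrow(m); nc <- ncol(m)
  r <- (kernel - 1L) %/% 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  k2 <- nrow(offs)
  stack <- matrix(0, nr * nc, k2)
  for (j in seq_len(k2)) {
    stack[, j] <- m[clamp_idx(seq_len(nr) + offs$dr[j], nr),
                    clamp_idx(seq_len(nc) + offs$dc[j], nc)]
  }
  # column-wise compare-exchange (odd-even transposition sort across the k^2
  # neighbourhood slots); vectorized over all pixels at once
  for (pass in seq_len(k2)) {
    start <- if (pass %% 2L == 1L) 1L else 2L
    js <- seq.int(start, k2 - 1L, by = 2L)
    for (j in js) {
      a <- stack[, j]; b <- stack[, j + 1L]
      stack[, j] <- pmin(a, b)
      stack[, j + 1L] <- pmax(a, b)
    }
  }
  out$pixels <- matrix(stack[, (k2 + 1L) %/% 2L], nr, nc)
  out
}
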