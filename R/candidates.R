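#' Candidate-generation parameters
#'
#' Defaults follow the published operating point: disc radius 5 px, 99th
#' percentile threshold, minimum area 20 px, at most K = 5 candidates, and
#' shape-penalty weights alpha = 0.4, beta = 0.3, gamma = 0.3. `elong_tol` is
#' the axis-ratio tolerance below which no elongation penalty applies
#' (default 2.0; setting it to 0 recovers a penalty on any anisotropy).
#'
#' @param se_radius Structuring-element radius, px.
#' @param percentile_q Percentile threshold (percent, in (0, 100)).
#' @param min_area Minimum candidate area, px.
#' @param k_max Maximum number of retained candidates.
#' @param alpha,beta,gamma Shape-penalty weights (eccentricity, solidity
#'   deficit, elongation excess).
#' @param elong_tol Axis-ratio tolerance for the elongation term.
#' @param brightness_mode `"product"` (integrated intensity, mu * A) or
#'   `"mean"` (mu alone).
#' @return A list of class `candidate_params`.
#' @export
candidate_params <- function(se_radius = 5, percentile_q = 99, min_area = 20,
                             k_max = 5, alpha = 0.4, beta = 0.3, gamma = 0.3,
                             elong_tol = 2, brightness_mode = c("product", "mean")) {
  brightness_mode <- match.arg(brightness_mode)
  num <- c(se_radius = se_radius, percentile_q = percentile_q,
           min_area = min_area, k_max = k_max, alpha = alpha, beta = beta,
           gamma = gamma, elong_tol = elong_tol)
  if (!all(is.finite(num)) || any(num[c("se_radius", "min_area", "k_max")] < 1)) {
    abort("candidate_params: se_radius, min_area and k_max must be >= 1.")
  }
  if (percentile_q <= 0 || percentile_q >= 100) {
    abort("`percentile_q` must lie strictly between 0 and 100.")
  }
  if (any(c(alpha, beta, gamma) < 0) || elong_tol < 0) {
    abort("penalty weights and `elong_tol` must be non-negative.")
  }
  structure(c(as.list(num), list(brightness_mode = brightness_mode)),
            class = "candidate_params")
}

#' Threshold the enhanced image at a high percentile
#'
#' Marks pixels strictly exceeding the `percentile_q`-th percentile of all
#' pixels (percentile by linear interpolation over the sorted values,
#' `stats::quantile` type 7). A constant image yields an empty map: the
#' threshold equals every value and the strict inequality admits none.
#'
#' @param enhanced A `siu_image` (typically from [tophat_enhance()]).
#' @param percentile_q Percentile in (0, 100), default 99.
#' @return Logical matrix of candidate pixels.
#' @export
threshold_candidates <- function(enhanced, percentile_q = 99) {
  stopifnot(inherits(enhanced, c("us_frame", "siu_image")))
  if (percentile_q <= 0 || percentile_q >= 100) {
    abort("`percentile_q` must lie strictly between 0 and 100.")
  }
  m <- enhanced$pixels
  thr <- quantile(as.vector(m), percentile_q / 100, type = 7, names = FALSE)
  m > thr
}

# 8-connected component labelling via graph components over the pixel
# adjacency. Returns an integer matrix (0 = background); labels are assigned
# in raster order of each component's first pixel, so labelling is
# deterministic.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[nb] > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(vid[fg[ok]][hit], vid[nb][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence in raster order (fg is sorted)
  lab[fg] <- match(memb, unique(memb))
  lab
}

#' Remove small connected components
#'
#' Deletes 8-connected components with fewer than `min_area` pixels,
#' suppressing noise-induced detections.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in pixels (kept at exactly
#'   `min_area`), default 20.
#' @return Logical matrix.
#' @export
remove_small <- function(mask, min_area = 20) {
  if (min_area < 1) abort("`min_area` must be >= 1.")
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  keep <- which(tabulate(lab) >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Keep only components containing a regional maximum
#'
#' A regional maximum is a connected plateau of the enhanced image all of
#' whose outside neighbours are strictly lower. Components of `mask` that
#' intersect no regional maximum are broad, ridge- or ramp-like responses
#' rather than peaks, and are discarded.
#'
#' @param mask Logical matrix of surviving candidate pixels.
#' @param enhanced The `siu_image` the mask was thresholded from.
#' @return Logical matrix.
#' @export
regional_maxima_gate <- function(mask, enhanced) {
  stopifnot(inherits(enhanced, c("us_frame", "siu_image")))
  if (!all(dim(mask) == dim(enhanced$pixels))) {
    abort("`mask` and `enhanced` must have the same dimensions.")
  }
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  rmax <- regional_maxima(enhanced$pixels)
  keep <- unique(lab[lab > 0L & rmax])
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

hull_area_corners <- function(rows, cols) {
  # convex hull of the pixel-corner points; area by the shoelace formula
  x <- c(cols - 0.5, cols + 0.5, cols + 0.5, cols - 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
}

#' Extract candidate regions with descriptors
#'
#' Groups candidate pixels into 8-connected components and computes the
#' region descriptors used by the screens and the composite score: area,
#' mean intensity, centroid, tight bounding box, eccentricity, solidity and
#' major/minor axis lengths. Axis lengths and eccentricity come from the
#' moment-equivalent ellipse of the pixel set, with the usual 1/12
#' unit-square correction on the second central moments so that a
#' one-pixel-thick component retains a positive minor axis. Solidity is the
#' pixel area divided by the area of the convex hull of the pixel corners.
#'
#' @param mask Logical candidate matrix.
#' @param image The `siu_image` intensities are averaged over.
#' @return A tibble with one row per region: `label`, `area`, `mu`, `xc`,
#'   `yc` (lateral/axial pixel coordinates, 1-based), bounding box columns
#'   `row0`, `col0`, `n_rows`, `n_cols`, `eccentricity`, `solidity`,
#'   `l_max`, `l_min`, and a list-column `pixels` of (row, col) matrices.
#'   Empty mask gives a zero-row tibble.
#' @export
extract_regions <- function(mask, image) {
  stopifnot(inherits(image, c("us_frame", "siu_image")))
  if (!all(dim(mask) == dim(image$pixels))) {
    abort("`mask` and `image` must have the same dimensions.")
  }
  lab <- label_components(mask)
  n_lab <- max(lab)
  empty <- tibble::tibble(
    label = integer(), area = integer(), mu = double(),
    xc = double(), yc = double(),
    row0 = integer(), col0 = integer(), n_rows = integer(), n_cols = integer(),
    eccentricity = double(), solidity = double(),
    l_max = double(), l_min = double(), pixels = list()
  )
  if (n_lab == 0L) return(empty)
  m <- image$pixels
  nr <- nrow(m)
  purrr::map_dfr(seq_len(n_lab), function(l) {
    idx <- which(lab == l)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    a <- length(idx)
    xc <- mean(cols); yc <- mean(rows)
    uxx <- mean((cols - xc)^2) + 1 / 12
    uyy <- mean((rows - yc)^2) + 1 / 12
    uxy <- mean((cols - xc) * (rows - yc))
    common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
    l1 <- (uxx + uyy + common) / 2
    l2 <- (uxx + uyy - common) / 2
    l2 <- max(l2, 0)
    tibble::tibble(
      label = l, area = a, mu = mean(m[idx]), xc = xc, yc = yc,
      row0 = min(rows), col0 = min(cols),
      n_rows = max(rows) - min(rows) + 1L, n_cols = max(cols) - min(cols) + 1L,
      eccentricity = sqrt(max(0, 1 - l2 / l1)),
      solidity = min(1, a / hull_area_corners(rows, cols)),
      l_max = 4 * sqrt(l1), l_min = 4 * sqrt(l2),
      pixels = list(cbind(row = rows, col = cols))
    )
  })
}

#' Shape penalty
#'
#' `alpha * eccentricity + beta * max(0, 1 - solidity) +
#' gamma * min(max(0, L_max / L_min - elong_tol), 10)`. The first term
#' penalizes line-like candidates (boundaries, reverberation), the second
#' fragmented or concave shapes, and the third anisotropy beyond the
#' tolerance `elong_tol`, so mildly elliptical stones are not suppressed.
#' A vanishing minor axis is treated as maximal elongation: the third term
#' saturates at its cap of 10.
#'
#' @param regions Tibble from [extract_regions()].
#' @param params A [candidate_params()].
#' @return `regions` with a `shape_penalty` column appended.
#' @export
shape_penalty <- function(regions, params = candidate_params()) {
  ratio <- ifelse(regions$l_min > 0, regions$l_max / regions$l_min, Inf)
  elong <- pmin(pmax(0, ratio - params$elong_tol), 10)
  dplyr::mutate(regions,
    shape_penalty = params$alpha * .data$eccentricity +
      params$beta * pmax(0, 1 - .data$solidity) +
      params$gamma * elong)
}

#' Candidate brightness
#'
#' Integrated intensity `mu * A` by default (equal to the summed SIU
#' intensity over the region), or the bare mean with
#' `brightness_mode = "mean"`.
#'
#' @inheritParams shape_penalty
#' @return `regions` with a `brightness` column appended.
#' @export
candidate_brightness <- function(regions, params = candidate_params()) {
  b <- if (params$brightness_mode == "product") {
    regions$mu * regions$area
  } else {
    regions$mu
  }
  dplyr::mutate(regions, brightness = b)
}

#' Retain the brightest K candidates
#'
#' Candidates are sorted by brightness, descending; ties go to the shallower
#' candidate (smaller `yc`), then the more leftward (`xc`), so the ordering
#' is deterministic.
#'
#' @param regions Tibble with a `brightness` column.
#' @param k_max Maximum number retained, default 5.
#' @return The top `min(k_max, nrow)` rows, in rank order.
#' @export
select_top_k <- function(regions, k_max = 5) {
  if (k_max < 1) abort("`k_max` must be >= 1.")
  regions |>
    dplyr::arrange(dplyr::desc(.data$brightness), .data$yc, .data$xc) |>
    dplyr::slice_head(n = as.integer(k_max))
}
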