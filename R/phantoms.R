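#' Phantom specification
#'
#' Describes a synthetic B-mode-like frame: a speckled background, an
#' optional hyperechoic elliptical stone, a graded hypoechoic shadow column
#' beneath it, and optional shadow-free bright line confounders (vessel
#' walls, fascial interfaces). The three shadow grades follow the clinical
#' weak / moderate / strong shadow descriptions and map to fixed fixture
#' conventions: centre-band attenuation fractions 0.2 / 0.45 / 0.7, shadow
#' lengths 10 / 20 / 40 px, lateral edge feathering 3 / 2 / 1 px; the weak
#' grade additionally interrupts the column with two random 2-3-row gaps
#' (a "discontinuous" shadow).
#'
#' @param height,width Frame size in pixels.
#' @param background_mean Mean background level on the raw (16-bit) scale.
#' @param speckle_scale Rayleigh scale; `NULL` derives it from
#'   `background_mean`.
#' @param smoothing_sigma Gaussian smoothing of the speckle, px.
#' @param stone_center `(x, y)` ellipse centre, px.
#' @param stone_axes `(semi-major, semi-minor)`, px.
#' @param stone_orientation Radians, major axis from the +x direction.
#' @param stone_gain Multiplicative hyperechoic factor (> 1) of the proximal
#'   (upper) stone surface.
#' @param stone_distal_gain Gain at the distal pole of the ellipse. A real
#'   calculus returns a strong echo from its proximal surface while its
#'   distal portion is attenuated by the stone itself, so the rendered gain
#'   decays linearly with depth from `stone_gain` at the proximal pole to
#'   `stone_distal_gain` at the distal pole (default 1.2).
#' @param shadow_grade `"weak"`, `"moderate"`, `"strong"`, or `"none"`.
#' @param with_stone Set `FALSE` for a pure-speckle frame.
#' @param anechoic_center,anechoic_axes,anechoic_factor An anechoic pocket
#'   (fluid, vessel lumen) rendered in every frame: an ellipse whose pixels
#'   are multiplied by `anechoic_factor`. Abdominal fields always contain
#'   near-anechoic structures, which pin the ROI minimum that the min-max
#'   normalization stretches to; omitting one would let the stone's own
#'   shadow set the minimum, which no clinical frame does. Set
#'   `anechoic_factor = 1` to disable.
#' @param confounders List of `list(x0, y0, x1, y1, gain, thickness)` line
#'   segments.
#' @param pixel_spacing_mm mm per pixel carried into generated frames.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 160, width = 160, background_mean = 120,
                         speckle_scale = NULL, smoothing_sigma = 1.5,
                         stone_center = c(80, 60), stone_axes = c(9, 6),
                         stone_orientation = 0, stone_gain = 3.5,
                         stone_distal_gain = 1.2,
                         shadow_grade = c("strong", "moderate", "weak", "none"),
                         with_stone = TRUE,
                         anechoic_center = c(35, 40), anechoic_axes = c(8, 6),
                         anechoic_factor = 0.12,
                         confounders = list(),
                         pixel_spacing_mm = 0.35, seed = 1L) {
  shadow_grade <- match.arg(shadow_grade)
  if (height < 1 || width < 1) abort("phantom frame must be non-empty.")
  if (is.null(speckle_scale)) speckle_scale <- background_mean / sqrt(pi / 2)
  if (stone_gain <= 1) abort("`stone_gain` must exceed 1 (hyperechoic focus).")
  if (stone_distal_gain < 1 || stone_distal_gain > stone_gain) {
    abort("`stone_distal_gain` must lie in [1, stone_gain].")
  }
  if (stone_axes[1] < stone_axes[2]) abort("`stone_axes` must be (semi-major, semi-minor).")
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    background_mean = background_mean, speckle_scale = speckle_scale,
    smoothing_sigma = smoothing_sigma, stone_center = stone_center,
    stone_axes = stone_axes, stone_orientation = stone_orientation,
    stone_gain = stone_gain, stone_distal_gain = stone_distal_gain,
    shadow_grade = shadow_grade,
    with_stone = isTRUE(with_stone),
    anechoic_center = anechoic_center, anechoic_axes = anechoic_axes,
    anechoic_factor = anechoic_factor,
    confounders = confounders,
    pixel_spacing_mm = pixel_spacing_mm, seed = as.integer(seed)),
    class = "phantom_spec")
  if (spec$with_stone) {
    ext <- stone_extent(spec)
    if (ext$x_min < 1 || ext$x_max > width || ext$y_min < 1 || ext$y_max > height) {
      abort("stone ellipse extends beyond the frame.")
    }
  }
  spec
}

grade_shadow_map <- function(grade) {
  switch(grade,
    weak = list(attenuation = 0.2, length = 10L, feather = 3L, gaps = 2L),
    moderate = list(attenuation = 0.45, length = 20L, feather = 2L, gaps = 0L),
    strong = list(attenuation = 0.7, length = 40L, feather = 1L, gaps = 0L),
    none = NULL)
}

grade_group_label <- function(grade) {
  switch(grade, weak = "50to60", moderate = "60to80", strong = "ge80",
         none = NA_character_)
}

stone_extent <- function(spec) {
  a <- spec$stone_axes[1]; b <- spec$stone_axes[2]
  th <- spec$stone_orientation
  hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  list(x_min = spec$stone_center[1] - hx, x_max = spec$stone_center[1] + hx,
       y_min = spec$stone_center[2] - hy, y_max = spec$stone_center[2] + hy,
       half_width = hx, half_height = hy)
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (j in seq_along(w)) {           # axial pass, replicated edges
    out <- out + w[j] * m[clamp_idx(seq_len(nr) + (j - r - 1L), nr), , drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(w)) {           # lateral pass
    out2 <- out2 + w[j] * out[, clamp_idx(seq_len(nc) + (j - r - 1L), nc), drop = FALSE]
  }
  out2
}

#' Speckled background frame
#'
#' Rayleigh-distributed envelope noise (the canonical fully developed
#' speckle model) smoothed by a Gaussian to emulate the lateral/axial
#' correlation of the imaging point-spread function, then rescaled so the
#' frame mean equals `background_mean`. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A [us_frame].
#' @export
speckle_background <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  u <- matrix(stats::runif(spec$height * spec$width), spec$height, spec$width)
  ray <- spec$speckle_scale * sqrt(-2 * log(u))
  sm <- gauss_smooth(ray, spec$smoothing_sigma)
  sm <- sm * (spec$background_mean / mean(sm))
  us_frame(sm, pixel_spacing_mm = spec$pixel_spacing_mm,
           source_id = sprintf("phantom_seed%d", spec$seed))
}

stone_rho <- function(spec) {
  xs <- matrix(rep(seq_len(spec$width), each = spec$height),
               spec$height, spec$width)
  ys <- matrix(rep(seq_len(spec$height), spec$width),
               spec$height, spec$width)
  u <- xs - spec$stone_center[1]
  v <- ys - spec$stone_center[2]
  th <- spec$stone_orientation
  ur <- u * cos(th) + v * sin(th)
  vr <- -u * sin(th) + v * cos(th)
  sqrt((ur / spec$stone_axes[1])^2 + (vr / spec$stone_axes[2])^2)
}

# Fixed anechoic pocket (fluid/vessel lumen): dimmed ellipse with a 2-px
# soft edge, clipped to the frame. Present in every phantom so the ROI
# minimum is anatomy-determined, not shadow-determined.
add_anechoic_pocket <- function(frame, spec) {
  f <- spec$anechoic_factor %||% 1
  if (f >= 1) return(frame)
  nr <- nrow(frame$pixels); nc <- ncol(frame$pixels)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  rho <- sqrt(((xs - spec$anechoic_center[1]) / spec$anechoic_axes[1])^2 +
              ((ys - spec$anechoic_center[2]) / spec$anechoic_axes[2])^2)
  edge <- 2 / min(spec$anechoic_axes)
  ramp <- pmin(1, pmax(0, (1 - rho) / edge))
  out <- frame
  out$pixels <- frame$pixels * (1 - (1 - f) * ramp)
  out
}

#' Add the hyperechoic stone
#'
#' Multiplies pixels inside the rotated ellipse by a hyperechoic gain, with
#' a one-pixel soft edge just inside the boundary. The gain decays linearly
#' with depth from `stone_gain` at the proximal pole to
#' `stone_distal_gain` at the distal pole, reproducing the standard B-mode
#' appearance of a calculus: a bright proximal cap over a dimmer distal
#' portion that the beam no longer penetrates at full strength. The ground
#' truth (mask, centroid, major-axis endpoints) is derived analytically
#' from the ellipse parameters, never measured from the rendered image.
#'
#' @param frame A [us_frame].
#' @param spec A [phantom_spec()].
#' @return `list(frame, truth)` where `truth` has `stone_mask`,
#'   `stone_centroid`, `axis_a`, `axis_b`, `group_label`, `seed`.
#' @export
add_stone <- function(frame, spec) {
  stopifnot(inherits(frame, "us_frame"), inherits(spec, "phantom_spec"))
  ext <- stone_extent(spec)
  if (ext$x_min < 1 || ext$x_max > ncol(frame$pixels) ||
      ext$y_min < 1 || ext$y_max > nrow(frame$pixels)) {
    abort("stone ellipse extends beyond the frame.")
  }
  rho <- stone_rho(spec)
  edge <- 1 / min(spec$stone_axes)    # ~1 px soft edge in normalized radius
  ramp <- pmin(1, pmax(0, (1 - rho) / edge))
  ys <- matrix(rep(seq_len(nrow(frame$pixels)), ncol(frame$pixels)),
               nrow(frame$pixels), ncol(frame$pixels))
  depth_frac <- pmin(1, pmax(0, (ys - (spec$stone_center[2] - ext$half_height)) /
                                  (2 * ext$half_height)))
  gain <- spec$stone_gain -
    (spec$stone_gain - (spec$stone_distal_gain %||% 1.2)) * depth_frac
  factor <- 1 + (gain - 1) * ramp
  out <- frame
  out$pixels <- frame$pixels * factor
  th <- spec$stone_orientation
  a <- spec$stone_axes[1]
  truth <- list(
    stone_mask = rho <= 1,
    stone_centroid = c(x = spec$stone_center[1], y = spec$stone_center[2]),
    axis_a = c(x = spec$stone_center[1] - a * cos(th),
               y = spec$stone_center[2] - a * sin(th)),
    axis_b = c(x = spec$stone_center[1] + a * cos(th),
               y = spec$stone_center[2] + a * sin(th)),
    group_label = grade_group_label(spec$shadow_grade),
    seed = spec$seed)
  list(frame = out, truth = truth)
}

#' Add the graded posterior shadow
#'
#' Attenuates a column of the stone's lateral extent beneath the stone:
#' pixels are multiplied by `1 - attenuation`, with the attenuation tapering
#' linearly over the grade's feather width at the lateral edges. The weak
#' grade interrupts the column with two random gaps of 2-3 rows (drawn from
#' the current RNG stream). The recorded `shadow_mask` covers the
#' fully-attenuated core columns over the whole nominal row extent
#' (including gap rows).
#'
#' @param frame A [us_frame] with the stone added.
#' @param spec A [phantom_spec()].
#' @param truth Truth list from [add_stone()].
#' @return `list(frame, truth)` with `shadow_mask` (and `shadow_rows`,
#'   `shadow_cols`, `gap_rows`) added to the truth.
#' @export
add_shadow <- function(frame, spec, truth) {
  g <- grade_shadow_map(spec$shadow_grade)
  truth$shadow_mask <- matrix(FALSE, nrow(frame$pixels), ncol(frame$pixels))
  truth$gap_rows <- integer(0)
  if (is.null(g)) return(list(frame = frame, truth = truth))
  ext <- stone_extent(spec)
  nr <- nrow(frame$pixels); nc <- ncol(frame$pixels)
  cols <- max(1L, round(spec$stone_center[1] - ext$half_width)):
          min(nc, round(spec$stone_center[1] + ext$half_width))
  y0 <- round(spec$stone_center[2] + ext$half_height) + 1L
  rows <- y0:min(nr, y0 + g$length - 1L)
  rows <- rows[rows >= 1L & rows <= nr]
  if (length(rows) == 0L || length(cols) == 0L) {
    return(list(frame = frame, truth = truth))
  }
  edge_dist <- pmin(cols - cols[1L], cols[length(cols)] - cols)
  taper <- if (g$feather > 0) pmin(1, (edge_dist + 0.5) / g$feather) else rep(1, length(cols))
  gap_rows <- integer(0)
  if (g$gaps > 0L && length(rows) > 4L) {
    for (k in seq_len(g$gaps)) {
      len <- sample(2:3, 1L)
      start <- sample(seq_len(max(1L, length(rows) - len + 1L)), 1L)
      gap_rows <- union(gap_rows, rows[start:min(length(rows), start + len - 1L)])
    }
  }
  att_rows <- setdiff(rows, gap_rows)
  out <- frame
  for (j in seq_along(cols)) {
    out$pixels[att_rows, cols[j]] <-
      out$pixels[att_rows, cols[j]] * (1 - g$attenuation * taper[j])
  }
  core_cols <- cols[edge_dist >= g$feather]
  if (length(core_cols) == 0L) core_cols <- cols
  truth$shadow_mask[rows, core_cols] <- TRUE
  truth$shadow_rows <- range(rows)
  truth$shadow_cols <- range(cols)
  truth$gap_rows <- sort(gap_rows)
  list(frame = out, truth = truth)
}

#' Add shadow-free bright line confounders
#'
#' Thin (1-2 px) bright segments at the given gain with no posterior
#' attenuation, mimicking vessel walls, fascial interfaces and specular
#' reflections that can out-brighten a stone but cast no shadow.
#'
#' @param frame A [us_frame].
#' @param spec A [phantom_spec()] whose `confounders` are drawn.
#' @return The frame with confounders rendered.
#' @export
add_confounders <- function(frame, spec) {
  out <- frame
  nr <- nrow(out$pixels); nc <- ncol(out$pixels)
  for (cf in spec$confounders) {
    thick <- cf$thickness %||% 2L
    len <- sqrt((cf$x1 - cf$x0)^2 + (cf$y1 - cf$y0)^2)
    t <- seq(0, 1, length.out = max(2L, 2L * ceiling(len) + 1L))
    px <- round(cf$x0 + t * (cf$x1 - cf$x0))
    py <- round(cf$y0 + t * (cf$y1 - cf$y0))
    pts <- NULL
    for (dt in seq_len(thick) - 1L) {
      pts <- rbind(pts, cbind(py + dt, px))   # thickened toward larger depth
    }
    ok <- pts[, 1L] >= 1L & pts[, 1L] <= nr & pts[, 2L] >= 1L & pts[, 2L] <= nc
    pts <- unique(pts[ok, , drop = FALSE])
    if (nrow(pts) > 0L) out$pixels[pts] <- out$pixels[pts] * cf$gain
  }
  out
}

#' Render one phantom with its ground truth
#'
#' Runs background, stone, shadow and confounders in a single seeded RNG
#' stream and quantizes the result to the 16-bit integer grid (so frames
#' written to TIFF read back pixel-exact). All truth fields are analytic.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `frame`, `truth` (NULL when
#'   `with_stone = FALSE`), `spec`.
#' @export
generate_phantom <- function(spec) {
  frame <- speckle_background(spec)
  frame <- add_anechoic_pocket(frame, spec)
  truth <- NULL
  if (spec$with_stone) {
    st <- add_stone(frame, spec)
    sh <- add_shadow(st$frame, spec, st$truth)
    frame <- sh$frame
    truth <- sh$truth
  }
  frame <- add_confounders(frame, spec)
  frame$pixels <- pmin(pmax(round(frame$pixels), 0), 65535)
  structure(list(frame = frame, truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, grade %s, stone %s, seed %d\n",
              x$spec$height, x$spec$width, x$spec$shadow_grade,
              if (x$spec$with_stone) "yes" else "no", x$spec$seed))
  invisible(x)
}

# Per-frame jittered spec; jitters are a deterministic function of
# (seed, index) only, so grades can be compared pairwise on identical
# speckle and stone geometry.
jittered_spec <- function(base_spec, grade, index, seed,
                          with_confounder = FALSE, with_stone = TRUE) {
  sub_seed <- (abs(seed) %% 1000000L) * 1000L + index
  set.seed(sub_seed)
  cx <- stats::runif(1, base_spec$width / 2 - 15, base_spec$width / 2 + 15)
  cy <- stats::runif(1, 50, 70)
  th <- stats::runif(1, -0.3, 0.3)
  confs <- list()
  if (with_confounder) {
    confs <- list(list(
      x0 = stats::runif(1, 30, base_spec$width / 2),
      y0 = stats::runif(1, base_spec$height - 35, base_spec$height - 25),
      gain = stats::runif(1, 2.6, 3.0), thickness = 2L))
    confs[[1]]$x1 <- confs[[1]]$x0 + 40
    confs[[1]]$y1 <- confs[[1]]$y0
  }
  phantom_spec(
    height = base_spec$height, width = base_spec$width,
    background_mean = base_spec$background_mean,
    speckle_scale = base_spec$speckle_scale,
    smoothing_sigma = base_spec$smoothing_sigma,
    stone_center = c(cx, cy), stone_axes = base_spec$stone_axes,
    stone_orientation = th, stone_gain = base_spec$stone_gain,
    shadow_grade = grade, with_stone = with_stone, confounders = confs,
    pixel_spacing_mm = base_spec$pixel_spacing_mm, seed = sub_seed)
}

default_dataset_roi <- function(spec) {
  roi_box(20, 20, spec$height - 40L, spec$width - 40L)
}

#' Generate a phantom dataset manifest
#'
#' Renders `n_per_grade` phantoms per shadow grade with per-frame jittered
#' stone position and orientation, emulating a confidence-stratified cohort.
#' With `paired = TRUE` the i-th frame of every grade shares its speckle
#' field and stone geometry, so grades differ only in the shadow — the
#' design used by the difficulty experiment. When `out_dir` is given, 16-bit
#' TIFF frames, an ROI/annotation CSV (`manifest.csv`) and a truth JSON are
#' written there; otherwise everything stays in memory.
#'
#' @param n_per_grade Named counts, e.g. `c(weak = 5, moderate = 5, strong = 5)`.
#' @param base_spec A [phantom_spec()] supplying the shared geometry.
#' @param seed Master seed; frame i of grade g gets a sub-seed derived from
#'   `(seed, g, i)` (or `(seed, i)` when paired).
#' @param out_dir Output directory, or `NULL` for in-memory.
#' @param with_confounder Add one shadow-free bright line per frame.
#' @param paired Share sub-seeds across grades (see above).
#' @return A tibble manifest: `image_id`, `grade`, `group_label`, `seed`,
#'   ROI columns, annotation columns (`xa`..`yb`, `observer_id`), `path`
#'   (NA in memory), and list-columns `frame`, `truth`.
#' @export
generate_dataset <- function(n_per_grade = c(weak = 5, moderate = 5, strong = 5),
                             base_spec = phantom_spec(), seed = 1L,
                             out_dir = NULL, with_confounder = FALSE,
                             paired = FALSE) {
  if (is.null(names(n_per_grade)) ||
      !all(names(n_per_grade) %in% c("weak", "moderate", "strong", "none"))) {
    abort("`n_per_grade` must be named with shadow grades.")
  }
  rows <- list()
  idx <- 0L
  for (g in names(n_per_grade)) {
    ng <- n_per_grade[[g]]
    if (ng == 0L) next
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      jit_index <- if (paired) i else idx
      spec_i <- jittered_spec(base_spec, g, jit_index, seed,
                              with_confounder = with_confounder,
                              with_stone = g != "none")
      ph <- generate_phantom(spec_i)
      roi <- default_dataset_roi(spec_i)
      tr <- ph$truth
      rows[[idx]] <- tibble::tibble(
        image_id = sprintf("phantom_%s_%03d", g, i),
        grade = g, group_label = grade_group_label(g),
        seed = spec_i$seed,
        row0 = roi$row0, col0 = roi$col0,
        n_rows = roi$n_rows, n_cols = roi$n_cols,
        xa = if (is.null(tr)) NA_real_ else tr$axis_a[["x"]],
        ya = if (is.null(tr)) NA_real_ else tr$axis_a[["y"]],
        xb = if (is.null(tr)) NA_real_ else tr$axis_b[["x"]],
        yb = if (is.null(tr)) NA_real_ else tr$axis_b[["y"]],
        observer_id = "truth", path = NA_character_,
        frame = list(ph$frame), truth = list(tr))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0L) {
    warn("empty dataset requested; returning an empty manifest.")
    return(manifest)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, paste0(manifest$image_id, ".tif"))
    for (i in seq_len(nrow(manifest))) {
      px <- manifest$frame[[i]]$pixels
      atomic_write(manifest$path[i], function(p) {
        tiff::writeTIFF(px / 65535, p, bits.per.sample = 16L)
      })
    }
    csv <- dplyr::select(manifest, -"frame", -"truth")
    atomic_write(file.path(out_dir, "manifest.csv"), function(p) {
      readr::write_csv(csv, p)
    })
    truths <- purrr::map(manifest$truth, function(tr) {
      if (is.null(tr)) return(NULL)
      list(stone_centroid = unname(tr$stone_centroid),
           axis_a = unname(tr$axis_a), axis_b = unname(tr$axis_b),
           group_label = tr$group_label, seed = tr$seed,
           gap_rows = tr$gap_rows)
    })
    names(truths) <- manifest$image_id
    atomic_write(file.path(out_dir, "truth.json"), function(p) {
      jsonlite::write_json(truths, p, auto_unbox = TRUE, digits = NA)
    })
  }
  manifest
}
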