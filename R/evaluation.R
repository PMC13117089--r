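#' Expert stone-axis annotation
#'
#' Two expert-marked endpoints along the stone's visually estimated long
#' axis define the reference line used by the localization-error metric and
#' the acceptance rule.
#'
#' @param xa,ya,xb,yb Endpoint coordinates (frame pixels).
#' @param observer_id Annotator identifier.
#' @return An object of class `axis_annotation` with the endpoints, the
#'   general-form line coefficients `(a, b, c)` with `a*x + b*y + c = 0`,
#'   the midpoint `center`, and `axis_length = |AB|` in pixels.
#' @export
axis_annotation <- function(xa, ya, xb, yb, observer_id = "obs1") {
  line <- line_from_endpoints(c(xa, ya), c(xb, yb))
  structure(list(
    a_pt = c(x = xa, y = ya), b_pt = c(x = xb, y = yb),
    line = line,
    center = c(x = (xa + xb) / 2, y = (ya + yb) / 2),
    axis_length = sqrt((xb - xa)^2 + (yb - ya)^2),
    observer_id = observer_id), class = "axis_annotation")
}

#' @export
print.axis_annotation <- function(x, ...) {
  cat(sprintf("<axis_annotation> %s: (%g, %g) -- (%g, %g), length %.2f px\n",
              x$observer_id, x$a_pt[1], x$a_pt[2], x$b_pt[1], x$b_pt[2],
              x$axis_length))
  invisible(x)
}

#' Line through two points, general form
#'
#' Coefficients `a = yb - ya`, `b = xa - xb`, `c = -(a*xa + b*ya)`, so both
#' endpoints satisfy `a*x + b*y + c = 0`.
#'
#' @param a_pt,b_pt Numeric `(x, y)` pairs; must be distinct.
#' @return Named numeric vector `c(a, b, c)`.
#' @export
line_from_endpoints <- function(a_pt, b_pt) {
  if (all(a_pt == b_pt)) {
    abort("annotation endpoints are coincident; a reference axis needs two distinct points.")
  }
  a <- b_pt[2] - a_pt[2]
  b <- a_pt[1] - b_pt[1]
  c(a = unname(a), b = unname(b), c = unname(-(a * a_pt[1] + b * a_pt[2])))
}

#' Perpendicular distance from a point to the reference axis
#'
#' `|a*xo + b*yo + c| / sqrt(a^2 + b^2)`: the shortest Euclidean distance
#' between the predicted stone location and the expert-defined stone axis.
#' Invariant to rescaling the coefficients by any nonzero factor.
#'
#' @param point Numeric `(x, y)`.
#' @param line Coefficients `c(a, b, c)` from [line_from_endpoints()].
#' @return Distance in pixels.
#' @export
centroid_distance <- function(point, line) {
  if (line[["a"]] == 0 && line[["b"]] == 0) {
    abort("degenerate line: a and b are both zero.")
  }
  abs(line[["a"]] * point[1] + line[["b"]] * point[2] + line[["c"]]) /
    sqrt(line[["a"]]^2 + line[["b"]]^2)
}

#' Convert a pixel distance to millimetres
#'
#' @param d_px Distance in pixels.
#' @param spacing mm per pixel (default 0.35).
#' @return Distance in mm.
#' @export
px_to_mm <- function(d_px, spacing = 0.35) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    abort("`spacing` must be a single positive number.")
  }
  d_px * spacing
}

#' Acceptance rule for a predicted stone point
#'
#' The expert protocol records only the two axis endpoints, so the accepted
#' region is a capsule built from them: the prediction is correct when its
#' orthogonal projection onto segment AB falls within the segment extended
#' by `long_margin * |AB|` beyond each end, and its perpendicular distance
#' to the axis is at most `dist_factor * |AB|`. Both boundaries are
#' inclusive, and the region scales with the annotated stone size.
#'
#' @param pred Numeric `(x, y)` predicted stone location.
#' @param annotation An [axis_annotation()].
#' @param dist_factor Lateral tolerance as a fraction of `|AB|`, default 0.5.
#' @param long_margin Longitudinal margin fraction, default 0.25.
#' @return Logical.
#' @export
is_correct <- function(pred, annotation, dist_factor = 0.5,
                       long_margin = 0.25) {
  stopifnot(inherits(annotation, "axis_annotation"))
  ab <- annotation$b_pt - annotation$a_pt
  t <- sum((pred - annotation$a_pt) * ab) / sum(ab^2)
  d <- centroid_distance(pred, annotation$line)
  t >= -long_margin && t <= 1 + long_margin &&
    d <= dist_factor * annotation$axis_length
}

#' Detection accuracy
#'
#' Fraction of images whose predicted stone point satisfied the acceptance
#' rule: `N_correct / N_total`.
#'
#' @param flags Logical vector, one entry per image (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
detection_accuracy <- function(flags) {
  if (length(flags) == 0L) abort("`flags` must be non-empty.")
  mean(flags)
}

#' Representative annotation parameters
#'
#' Midpoint and axis length of an annotation, the quantities compared
#' between observers in the agreement analysis.
#'
#' @param annotation An [axis_annotation()].
#' @return Tibble with `center_x`, `center_y`, `axis_length`.
#' @export
annotation_params <- function(annotation) {
  stopifnot(inherits(annotation, "axis_annotation"))
  tibble::tibble(center_x = annotation$center[["x"]],
                 center_y = annotation$center[["y"]],
                 axis_length = annotation$axis_length)
}

#' Group summary of localization errors
#'
#' Mean, sample SD (n - 1 denominator) and t-based 95% confidence interval
#' of the distances, plus the acceptance accuracy, for one confidence
#' stratum. Distances may contain `NA` (frames without an accepted
#' detection); these are excluded from the distance statistics but counted
#' in the accuracy denominator. The CI requires at least two distances and
#' is reported as `NA` otherwise.
#'
#' @param distances_mm Numeric vector of per-image distances (mm).
#' @param flags Logical acceptance flags, same length.
#' @param label Group tag.
#' @return One-row tibble: `group`, `n`, `n_correct`, `accuracy`, `n_dist`,
#'   `mean_d`, `sd_d`, `ci_low`, `ci_high`.
#' @export
summarize_group <- function(distances_mm, flags, label = "all") {
  if (length(flags) == 0L) abort("empty group.")
  if (length(distances_mm) != length(flags)) {
    abort("`distances_mm` and `flags` must have equal length.")
  }
  d <- distances_mm[!is.na(distances_mm)]
  n_d <- length(d)
  mean_d <- if (n_d >= 1L) mean(d) else NA_real_
  sd_d <- if (n_d >= 2L) sd(d) else NA_real_
  if (n_d >= 2L) {
    half <- qt(0.975, n_d - 1L) * sd_d / sqrt(n_d)
    ci <- c(mean_d - half, mean_d + half)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble::tibble(group = label, n = length(flags), n_correct = sum(flags),
                 accuracy = detection_accuracy(flags), n_dist = n_d,
                 mean_d = mean_d, sd_d = sd_d,
                 ci_low = ci[1], ci_high = ci[2])
}

#' Two-observer agreement (intraclass correlation)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC — the
#' standard form for duplicate continuous annotations — computed from the
#' subject-by-rater ANOVA mean squares. The interpretation band follows the
#' 0.75 (good) and 0.90 (excellent) cut-offs.
#'
#' @param obs1,obs2 Numeric vectors of the same length (>= 3): the two
#'   observers' measurements on the same subjects.
#' @return One-row tibble: `icc`, `band` (`"poor_to_moderate"`, `"good"`,
#'   `"excellent"`), `n`, `form`.
#' @export
icc_agreement <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) abort("observer vectors differ in length.")
  n <- length(obs1)
  if (n < 3L) abort("at least 3 subjects are required.")
  if (all(obs1 == obs2)) {
    # perfect agreement; bypass the mean squares, which are 0/0-unstable
    # when the between-subject variance is also (near) zero
    return(tibble::tibble(icc = 1, band = "excellent", n = n,
                          form = "ICC(A,1) two-way random"))
  }
  dat <- data.frame(y = c(obs1, obs2),
                    subject = factor(rep(seq_len(n), 2L)),
                    rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subject + rater, data = dat))[[1L]][["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  k <- 2
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (!is.finite(icc)) icc <- 1  # all measurements identical: zero variance everywhere
  band <- if (icc >= 0.90) "excellent" else if (icc >= 0.75) "good" else "poor_to_moderate"
  tibble::tibble(icc = icc, band = band, n = n, form = "ICC(A,1) two-way random")
}

#' Evaluate detections against annotations
#'
#' Joins per-image detection records to expert annotations and computes the
#' per-image acceptance flag and point-to-axis distance (px and mm). Frames
#' without an accepted detection get `correct = FALSE` and `NA` distances.
#'
#' @param detections Tibble with columns `image_id`, `status`, `stone_x`,
#'   `stone_y` (e.g. bound [glance()] rows).
#' @param annotations Tibble with columns `image_id`, `xa`, `ya`, `xb`,
#'   `yb`, `group_label` (the annotation-manifest format).
#' @param pixel_spacing_mm mm per pixel, default 0.35.
#' @param dist_factor,long_margin Acceptance-rule factors, see
#'   [is_correct()].
#' @return Per-image tibble with `correct`, `d_px`, `d_mm`, `group_label`.
#' @export
evaluate_detections <- function(detections, annotations,
                                pixel_spacing_mm = 0.35,
                                dist_factor = 0.5, long_margin = 0.25) {
  joined <- dplyr::inner_join(detections, annotations, by = "image_id")
  if (nrow(joined) == 0L) abort("no image_id matches between detections and annotations.")
  res <- purrr::map(seq_len(nrow(joined)), function(i) {
    r <- joined[i, ]
    ann <- axis_annotation(r$xa, r$ya, r$xb, r$yb)
    if (!identical(r$status, "detected") || is.na(r$stone_x)) {
      return(list(correct = FALSE, d_px = NA_real_))
    }
    pred <- c(r$stone_x, r$stone_y)
    list(correct = is_correct(pred, ann, dist_factor, long_margin),
         d_px = centroid_distance(pred, ann$line))
  })
  dplyr::mutate(joined,
    correct = purrr::map_lgl(res, "correct"),
    d_px = purrr::map_dbl(res, "d_px"),
    d_mm = px_to_mm(.data$d_px, pixel_spacing_mm))
}

#' Group summaries of an evaluation table
#'
#' @param per_image Output of [evaluate_detections()].
#' @return One row per `group_label`, columns as in [summarize_group()].
#' @export
summarize_groups <- function(per_image) {
  per_image |>
    dplyr::group_by(.data$group_label) |>
    dplyr::group_modify(~ summarize_group(.x$d_mm, .x$correct,
                                          label = .y$group_label)) |>
    dplyr::ungroup() |>
    dplyr::select(-"group")
}
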