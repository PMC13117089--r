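#' Composite-score weights
#'
#' Weights of the total score over brightness, local contrast, shadow region
#' and (subtracted) shape penalty. Defaults: wB = 0.35, wC = 0.25,
#' wS = 0.25, wP = 0.15.
#'
#' @param w_b,w_c,w_s,w_p Non-negative weights.
#' @return A list of class `score_weights`.
#' @export
score_weights <- function(w_b = 0.35, w_c = 0.25, w_s = 0.25, w_p = 0.15) {
  v <- c(w_b = w_b, w_c = w_c, w_s = w_s, w_p = w_p)
  if (!all(is.finite(v)) || any(v < 0)) {
    abort("score weights must be finite and non-negative.")
  }
  structure(as.list(v), class = "score_weights")
}

# Per-image min-max feature normalization across surviving candidates.
# Zero-range (including single-candidate) convention: ordinary features map
# to 1; the penalty maps to 1 unless its raw value is 0, in which case 0.
# NA raw values (a screen was disabled and its statistic was not computable)
# map to 0: absent evidence contributes nothing.
norm_feature <- function(x, penalty = FALSE) {
  ok <- !is.na(x)
  out <- numeric(length(x))
  if (!any(ok)) return(out)
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi > lo) {
    out[ok] <- (x[ok] - lo) / (hi - lo)
  } else if (penalty) {
    out[ok] <- ifelse(x[ok] > 0, 1, 0)
  } else {
    out[ok] <- 1
  }
  out
}

#' Total composite score
#'
#' `w_b * brightness + w_c * local_contrast + w_s * shadow_region -
#' w_p * shape_penalty`. Because the raw features live on incommensurate
#' scales (integrated intensity ~10^3-10^4 SIU px, contrasts ~10^2-10^3 SIU,
#' penalty ~0-1), each feature is first min-max normalized across the
#' surviving candidates of the image, which preserves the ranking intent of
#' the weights while making them commensurable. With a single candidate each
#' normalized feature is 1 (penalty 0 when its raw value is 0). Raw
#' summation is available with `normalize = FALSE`.
#'
#' @param screened Candidate tibble from [screen_candidates()] (columns
#'   `brightness`, `local_contrast`, `shadow_region`, `shape_penalty`).
#' @param weights A [score_weights()].
#' @param normalize Min-max normalize features per image (default TRUE).
#' @return `screened` with appended columns `score_brightness`,
#'   `score_contrast`, `score_shadow`, `score_penalty` (the weighted inputs
#'   on their final scale) and `total_score`.
#' @export
score_candidates <- function(screened, weights = score_weights(),
                             normalize = TRUE) {
  if (nrow(screened) == 0L) {
    return(dplyr::mutate(screened, score_brightness = double(),
                         score_contrast = double(), score_shadow = double(),
                         score_penalty = double(), total_score = double()))
  }
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  if (normalize) {
    fb <- norm_feature(screened$brightness)
    fc <- norm_feature(screened$local_contrast)
    fs <- norm_feature(screened$shadow_region)
    fp <- norm_feature(screened$shape_penalty, penalty = TRUE)
  } else {
    fb <- zero_na(screened$brightness)
    fc <- zero_na(screened$local_contrast)
    fs <- zero_na(screened$shadow_region)
    fp <- zero_na(screened$shape_penalty)
  }
  dplyr::mutate(screened,
    score_brightness = fb, score_contrast = fc,
    score_shadow = fs, score_penalty = fp,
    total_score = weights$w_b * fb + weights$w_c * fc +
      weights$w_s * fs - weights$w_p * fp)
}

#' Estimate the shadow onset row
#'
#' The first row after the steepest decrease of the centre profile. If the
#' profile never decreases the shadow is assumed to begin immediately at the
#' first profile row, with a warning.
#'
#' @param profile A `shadow_profile`.
#' @return Row index (in the coordinates of the image the profile was
#'   extracted from).
#' @export
estimate_shadow_onset <- function(profile) {
  stopifnot(inherits(profile, "shadow_profile"))
  if (length(profile$diffs) == 0L || min(profile$diffs) >= 0) {
    warn("centre profile never decreases; shadow onset set to the first profile row.")
    return(profile$y_start)
  }
  profile$y_start + profile$i_drop
}

#' Extract the posterior shadow ROI
#'
#' A rectangular box directly beneath the selected stone: same column span
#' as the winner's bounding box, starting at the estimated shadow onset row,
#' extending `params$depth` rows (clipped to the image).
#'
#' @param winner One-row candidate tibble (the selected stone).
#' @param onset_row Shadow onset row, same coordinates as `image`.
#' @param params A [screen_params()] (supplies the depth).
#' @param image The `siu_image` (or frame) the box is clipped to.
#' @return A [roi_box], or `NULL` when no rows remain below the onset.
#' @export
extract_shadow_roi <- function(winner, onset_row, params, image) {
  n_row <- nrow(image$pixels)
  if (onset_row > n_row || onset_row < 1L) return(NULL)
  n_rows <- min(params$depth, n_row - onset_row + 1L)
  roi_box(onset_row, winner$col0, n_rows, winner$n_cols)
}

select_ranked <- function(scored) {
  dplyr::arrange(scored, dplyr::desc(.data$total_score),
                 dplyr::desc(ifelse(is.na(.data$shadow_region), -Inf,
                                    .data$shadow_region)),
                 .data$yc, .data$xc)
}

#' Run the full detection pipeline on one frame
#'
#' Crop to the operator ROI, min-max normalize to SIU, median-denoise,
#' top-hat enhance, percentile-threshold, remove small components, gate on
#' regional maxima, extract region descriptors, compute shape penalty and
#' brightness, keep the brightest K, apply the two screens, combine into the
#' composite score, select the winner, estimate the shadow onset, and box
#' the posterior shadow. A pure function of (pixels, roi, config): rerunning
#' with identical inputs reproduces the result exactly.
#'
#' All coordinates in the result are reported in full-frame coordinates.
#'
#' @param frame A [us_frame].
#' @param roi A [roi_box]; `NULL` analyses the whole frame.
#' @param config A [detect_config()].
#' @return An object of class `stone_detection`: `status` ("detected" or
#'   "no_candidate"), `winner` (one-row tibble or `NULL`), `total_score`,
#'   `component_scores`, `shadow_onset_row`, `shadow_roi`,
#'   `ranked_alternates`, `candidates` (all scored survivors),
#'   `screen_log` (all top-K candidates with screen reasons), plus the ROI,
#'   config and normalized ROI image for plotting.
#' @export
detect_stone <- function(frame, roi = NULL, config = detect_config()) {
  stopifnot(inherits(frame, "us_frame"))
  if (is.null(roi)) roi <- roi_box(1, 1, nrow(frame$pixels), ncol(frame$pixels))
  cropped <- crop_roi(frame, roi)
  img <- normalize_minmax(cropped, config$scale_max)
  img <- median_denoise(img, config$median_kernel)
  cp <- config$candidates
  enh <- tophat_enhance(img, cp$se_radius)
  mask <- threshold_candidates(enh, cp$percentile_q)
  mask <- remove_small(mask, cp$min_area)
  mask <- regional_maxima_gate(mask, enh)
  regions <- extract_regions(mask, img)
  dr <- roi$row0 - 1L; dc <- roi$col0 - 1L
  to_frame_coords <- function(tb) {
    if (nrow(tb) == 0L) return(tb)
    dplyr::mutate(tb, xc = .data$xc + dc, yc = .data$yc + dr,
                  row0 = .data$row0 + dr, col0 = .data$col0 + dc)
  }
  base <- list(roi = roi, config = config, roi_image = img,
               source_id = frame$source_id,
               pixel_spacing_mm = frame$pixel_spacing_mm)
  if (nrow(regions) == 0L) {
    return(structure(c(list(status = "no_candidate", winner = NULL,
                            total_score = NA_real_, component_scores = NULL,
                            shadow_onset_row = NA_integer_, shadow_roi = NULL,
                            ranked_alternates = tibble::tibble(label = integer(),
                                                               total_score = double()),
                            candidates = regions, screen_log = regions), base),
                     class = "stone_detection"))
  }
  regions <- regions |>
    shape_penalty(cp) |>
    candidate_brightness(cp) |>
    select_top_k(cp$k_max)
  screened_all <- screen_candidates(img, regions, config$screens,
                                    enable_lc = config$enable_lc,
                                    enable_sr = config$enable_sr,
                                    keep_rejected = TRUE)
  screened <- dplyr::filter(screened_all, .data$reason == "ok")
  scored <- score_candidates(screened, config$weights, config$normalize_scores)
  if (nrow(scored) == 0L) {
    return(structure(c(list(status = "no_candidate", winner = NULL,
                            total_score = NA_real_, component_scores = NULL,
                            shadow_onset_row = NA_integer_, shadow_roi = NULL,
                            ranked_alternates = tibble::tibble(label = integer(),
                                                               total_score = double()),
                            candidates = to_frame_coords(scored),
                            screen_log = to_frame_coords(screened_all)), base),
                     class = "stone_detection"))
  }
  ranked <- select_ranked(scored)
  win <- ranked[1L, ]
  prof <- win$profile[[1L]]
  onset_roi <- if (!is.null(prof)) {
    suppressWarnings(estimate_shadow_onset(prof))
  } else {
    win$row0 + win$n_rows  # no evaluable profile: first row below the box
  }
  sroi <- extract_shadow_roi(win, onset_roi, config$screens, img)
  if (!is.null(sroi)) sroi <- roi_box(sroi$row0 + dr, sroi$col0 + dc,
                                      sroi$n_rows, sroi$n_cols)
  structure(c(list(
    status = "detected",
    winner = to_frame_coords(win),
    total_score = win$total_score,
    component_scores = list(brightness = win$brightness,
                            local_contrast = win$local_contrast,
                            shadow_region = win$shadow_region,
                            shape_penalty = win$shape_penalty),
    shadow_onset_row = onset_roi + dr,
    shadow_roi = sroi,
    ranked_alternates = tibble::tibble(label = ranked$label,
                                       total_score = ranked$total_score),
    candidates = to_frame_coords(ranked),
    screen_log = to_frame_coords(screened_all)), base),
    class = "stone_detection")
}

#' @export
print.stone_detection <- function(x, ...) {
  if (x$status == "detected") {
    cat(sprintf(
      "<stone_detection> %s: detected at (x = %.2f, y = %.2f), total score %.4f\n",
      x$source_id, x$winner$xc, x$winner$yc, x$total_score))
    if (!is.null(x$shadow_roi)) {
      cat(sprintf("  shadow onset row %d; shadow ROI rows %d..%d, cols %d..%d\n",
                  x$shadow_onset_row, x$shadow_roi$row0,
                  x$shadow_roi$row0 + x$shadow_roi$n_rows - 1L,
                  x$shadow_roi$col0, x$shadow_roi$col0 + x$shadow_roi$n_cols - 1L))
    }
  } else {
    cat(sprintf("<stone_detection> %s: no candidate passed the screens\n",
                x$source_id))
  }
  invisible(x)
}

#' @rdname tidy.stone_detection
#' @export
glance.stone_detection <- function(x, ...) {
  tibble::tibble(
    source_id = x$source_id,
    status = x$status,
    stone_x = if (x$status == "detected") x$winner$xc else NA_real_,
    stone_y = if (x$status == "detected") x$winner$yc else NA_real_,
    total_score = x$total_score,
    shadow_onset_row = x$shadow_onset_row,
    n_candidates = nrow(x$screen_log),
    n_survivors = nrow(x$candidates)
  )
}

#' Tidy a detection result
#'
#' `tidy()` returns one row per screened candidate (with screen statistics,
#' pass flags and composite scores, full-frame coordinates); `glance()`
#' returns a one-row summary of the detection.
#'
#' @param x A `stone_detection`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stone_detection <- function(x, ...) {
  tb <- x$screen_log
  if (nrow(tb) == 0L) return(tb)
  scored <- x$candidates
  tb <- dplyr::select(tb, -dplyr::any_of(c("pixels", "profile")))
  if (nrow(scored) > 0L) {
    tb <- dplyr::left_join(
      tb, dplyr::select(scored, "label", dplyr::starts_with("score_"),
                        "total_score"),
      by = "label")
  }
  dplyr::mutate(tb, source_id = x$source_id, .before = 1L)
}
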