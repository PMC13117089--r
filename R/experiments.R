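#' Run detection over a dataset manifest
#'
#' Applies [detect_stone()] to every row of a manifest. Frames may be held
#' in a `frame` list-column (in-memory datasets) or referenced by `path`
#' (files from [generate_dataset()] or clinical exports). Unreadable files
#' are reported and skipped; the remaining frames still produce records.
#'
#' @param manifest Tibble with `image_id`, ROI columns (`row0`, `col0`,
#'   `n_rows`, `n_cols`) and either a `frame` list-column or a `path`
#'   column.
#' @param config A [detect_config()].
#' @return Tibble with one record per processed image: `image_id`,
#'   `status`, `stone_x`, `stone_y`, `total_score`, `shadow_onset_row`,
#'   shadow-box columns, `reason` (winner reason or the failure note) and a
#'   `detection` list-column holding the full `stone_detection`.
#' @export
detect_manifest <- function(manifest, config = detect_config()) {
  stopifnot(nrow(manifest) > 0L)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    fr <- if ("frame" %in% names(manifest) && !is.null(r$frame[[1L]])) {
      r$frame[[1L]]
    } else {
      tryCatch(read_frame(r$path, pixel_spacing_mm = config$pixel_spacing_mm,
                          source_id = r$image_id),
               error = function(e) e)
    }
    if (inherits(fr, "error")) {
      return(tibble::tibble(image_id = r$image_id, status = "error",
                            stone_x = NA_real_, stone_y = NA_real_,
                            total_score = NA_real_,
                            shadow_onset_row = NA_integer_,
                            shadow_row0 = NA_integer_, shadow_col0 = NA_integer_,
                            shadow_n_rows = NA_integer_, shadow_n_cols = NA_integer_,
                            reason = conditionMessage(fr),
                            detection = list(NULL)))
    }
    fr$source_id <- r$image_id
    roi <- roi_box(r$row0, r$col0, r$n_rows, r$n_cols)
    det <- detect_stone(fr, roi, config)
    sb <- det$shadow_roi
    tibble::tibble(
      image_id = r$image_id, status = det$status,
      stone_x = if (det$status == "detected") det$winner$xc else NA_real_,
      stone_y = if (det$status == "detected") det$winner$yc else NA_real_,
      total_score = det$total_score,
      shadow_onset_row = det$shadow_onset_row,
      shadow_row0 = if (is.null(sb)) NA_integer_ else sb$row0,
      shadow_col0 = if (is.null(sb)) NA_integer_ else sb$col0,
      shadow_n_rows = if (is.null(sb)) NA_integer_ else sb$n_rows,
      shadow_n_cols = if (is.null(sb)) NA_integer_ else sb$n_cols,
      reason = if (det$status == "detected") "ok" else
        paste(unique(det$screen_log$reason), collapse = ";"),
      detection = list(det))
  })
  dplyr::bind_rows(rows)
}

#' Standard ablation variants
#'
#' The four cumulative score configurations of the ablation protocol:
#' brightness alone; + local contrast; + shadow region; + shape penalty.
#' Each variant zeroes the weights of absent features and disables the
#' screens of absent features (the penalty has no screen).
#'
#' @param config Base [detect_config()] supplying every other parameter.
#' @return Named list of `stone_config` objects, in table column order.
#' @export
ablation_variants <- function(config = detect_config()) {
  w <- config$weights
  variant <- function(wc, ws, wp, lc, sr) {
    cfg <- config
    cfg$weights <- score_weights(w$w_b, wc, ws, wp)
    cfg$enable_lc <- lc
    cfg$enable_sr <- sr
    cfg
  }
  list(
    B = variant(0, 0, 0, FALSE, FALSE),
    BC = variant(w$w_c, 0, 0, TRUE, FALSE),
    BCS = variant(w$w_c, w$w_s, 0, TRUE, TRUE),
    BCSP = variant(w$w_c, w$w_s, w$w_p, TRUE, TRUE))
}

#' Ablation study over an annotated dataset
#'
#' Runs every variant through detection and evaluation on the same frames
#' and reports acceptance accuracy per (variant, confidence group), plus
#' the localization-error summaries of the full variant.
#'
#' @param manifest Annotated manifest (see [generate_dataset()]): needs
#'   frames/paths, ROI columns, `xa`..`yb` and `group_label`.
#' @param config Base [detect_config()].
#' @param variants Named list of configs, default [ablation_variants()].
#' @return A list of class `ablation_result`: `accuracy` (long tibble:
#'   `variant`, `group_label`, `n`, `accuracy`), `table` (groups wide,
#'   variants in protocol row order), `distance` (group summaries for the
#'   last variant), `per_image`.
#' @export
run_ablation_study <- function(manifest, config = detect_config(),
                               variants = ablation_variants(config)) {
  if (nrow(manifest) == 0L) abort("empty dataset.")
  annotations <- dplyr::select(manifest, "image_id", "xa", "ya", "xb", "yb",
                               "group_label")
  per_image <- purrr::imap_dfr(variants, function(cfg, nm) {
    det <- detect_manifest(manifest, cfg)
    ev <- evaluate_detections(dplyr::select(det, "image_id", "status",
                                            "stone_x", "stone_y"),
                              annotations,
                              pixel_spacing_mm = cfg$pixel_spacing_mm,
                              dist_factor = cfg$accept_dist_factor,
                              long_margin = cfg$accept_long_margin)
    dplyr::mutate(ev, variant = nm, .before = 1L)
  })
  accuracy <- per_image |>
    dplyr::group_by(.data$variant, .data$group_label) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = detection_accuracy(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(variant = factor(.data$variant, levels = names(variants))) |>
    dplyr::arrange(.data$variant)
  table <- tidyr::pivot_wider(accuracy, id_cols = "variant",
                              names_from = "group_label",
                              values_from = "accuracy")
  last <- names(variants)[length(variants)]
  distance <- summarize_groups(dplyr::filter(per_image, .data$variant == last))
  structure(list(accuracy = accuracy, table = table, distance = distance,
                 per_image = per_image), class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> accuracy by variant and confidence group:\n")
  print(x$table)
  invisible(x)
}

#' Difficulty study across shadow grades
#'
#' Renders `n_seeds` paired phantoms per grade (identical speckle and stone
#' per seed; only the shadow grade varies), runs the full pipeline and
#' summarizes per grade: acceptance accuracy, mean point-to-axis distance
#' over accepted detections, and a combined localization error in which a
#' frame with no accepted candidate is scored at a nominal worst-case error
#' of half the ROI diagonal ("penalized" mean). The penalized mean keeps
#' grades comparable when they accept different subsets of frames.
#'
#' @param n_seeds Frames per grade.
#' @param base_spec A [phantom_spec()].
#' @param config A [detect_config()].
#' @param seed Master seed.
#' @param grades Grade ordering, easiest first.
#' @return A list of class `difficulty_result`: `summary` (tibble, one row
#'   per grade in the given order: `grade`, `n`, `accuracy`, `n_detected`,
#'   `mean_d_detected_px`, `mean_d_penalized_px`, mm analogues) and
#'   `per_image`.
#' @export
run_difficulty_study <- function(n_seeds = 30, base_spec = phantom_spec(),
                                 config = detect_config(), seed = 1L,
                                 grades = c("strong", "moderate", "weak")) {
  counts <- stats::setNames(rep(n_seeds, length(grades)), grades)
  manifest <- generate_dataset(counts, base_spec, seed = seed, paired = TRUE)
  det <- detect_manifest(manifest, config)
  ev <- evaluate_detections(
    dplyr::select(det, "image_id", "status", "stone_x", "stone_y"),
    dplyr::select(manifest, "image_id", "grade", "xa", "ya", "xb", "yb",
                  "group_label"),
    pixel_spacing_mm = config$pixel_spacing_mm,
    dist_factor = config$accept_dist_factor,
    long_margin = config$accept_long_margin)
  roi <- default_dataset_roi(base_spec)
  miss_penalty_px <- sqrt(roi$n_rows^2 + roi$n_cols^2) / 2
  summary <- purrr::map_dfr(grades, function(g) {
    sub <- dplyr::filter(ev, .data$grade == g)
    d_pen <- ifelse(is.na(sub$d_px), miss_penalty_px, sub$d_px)
    tibble::tibble(
      grade = g, n = nrow(sub),
      accuracy = detection_accuracy(sub$correct),
      n_detected = sum(!is.na(sub$d_px)),
      mean_d_detected_px = if (any(!is.na(sub$d_px)))
        mean(sub$d_px, na.rm = TRUE) else NA_real_,
      mean_d_penalized_px = mean(d_pen),
      mean_d_detected_mm = px_to_mm(if (any(!is.na(sub$d_px)))
        mean(sub$d_px, na.rm = TRUE) else NA_real_, config$pixel_spacing_mm),
      mean_d_penalized_mm = px_to_mm(mean(d_pen), config$pixel_spacing_mm))
  })
  structure(list(summary = summary, per_image = ev,
                 miss_penalty_px = miss_penalty_px),
            class = "difficulty_result")
}

#' @export
print.difficulty_result <- function(x, ...) {
  cat("<difficulty_result> per-grade summary (easiest first):\n")
  print(x$summary)
  invisible(x)
}

#' Interobserver agreement report
#'
#' Computes the two-observer ICC of the annotation-derived parameters
#' (centre x, centre y, axis length) from a duplicate-observer annotation
#' table.
#'
#' @param annotations Tibble with `image_id`, `observer_id`, `xa`..`yb`;
#'   exactly two observers, every image annotated by both.
#' @return Tibble with one row per parameter: `parameter`, `icc`, `band`,
#'   `n`, `form`.
#' @export
icc_report <- function(annotations) {
  obs <- sort(unique(annotations$observer_id))
  if (length(obs) != 2L) abort("icc_report needs exactly two observers.")
  params <- annotations |>
    dplyr::mutate(center_x = (.data$xa + .data$xb) / 2,
                  center_y = (.data$ya + .data$yb) / 2,
                  axis_length = sqrt((.data$xb - .data$xa)^2 +
                                     (.data$yb - .data$ya)^2)) |>
    dplyr::select("image_id", "observer_id", "center_x", "center_y",
                  "axis_length") |>
    dplyr::arrange(.data$image_id)
  o1 <- dplyr::filter(params, .data$observer_id == obs[1L])
  o2 <- dplyr::filter(params, .data$observer_id == obs[2L])
  if (!identical(o1$image_id, o2$image_id)) {
    abort("both observers must annotate the same images.")
  }
  purrr::map_dfr(c("center_x", "center_y", "axis_length"), function(p) {
    dplyr::mutate(icc_agreement(o1[[p]], o2[[p]]), parameter = p,
                  .before = 1L)
  })
}
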