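# Workflow commands behind the command-line tool (inst/cli/echolith).
# Each writes its reports atomically (write-then-rename) and stamps them
# with the configuration hash, so identical config + inputs give identical
# outputs.

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  needed <- c("image_id", "row0", "col0", "n_rows", "n_cols")
  missing <- setdiff(needed, names(manifest))
  if (length(missing) > 0L) {
    abort(sprintf("manifest lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  manifest
}

#' Detect stones for every image in a manifest
#'
#' @param manifest Manifest CSV path or tibble: `image_id`, `path`, ROI
#'   columns `row0`, `col0`, `n_rows`, `n_cols` (an in-memory `frame`
#'   list-column also works).
#' @param config A [detect_config()].
#' @param out_dir If non-NULL, writes `detections.json` (one record per
#'   image, including the config hash) and `screen_log.csv` (per-candidate
#'   screen statistics and reason codes) there.
#' @return The detection tibble from [detect_manifest()], invisibly when
#'   writing.
#' @export
run_detect <- function(manifest, config = detect_config(), out_dir = NULL) {
  manifest <- read_manifest(manifest)
  det <- detect_manifest(manifest, config)
  if (is.null(out_dir)) return(det)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- purrr::map(seq_len(nrow(det)), function(i) {
    r <- det[i, ]
    list(image_id = r$image_id, status = r$status,
         stone_x = r$stone_x, stone_y = r$stone_y,
         total_score = r$total_score,
         shadow_onset_row = r$shadow_onset_row,
         shadow_roi = if (is.na(r$shadow_row0)) NULL else
           list(row0 = r$shadow_row0, col0 = r$shadow_col0,
                n_rows = r$shadow_n_rows, n_cols = r$shadow_n_cols),
         reason = r$reason)
  })
  payload <- list(config_hash = config_hash(config), detections = records)
  atomic_write(file.path(out_dir, "detections.json"), function(p) {
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA, null = "null")
  })
  logs <- purrr::map_dfr(det$detection, function(d) {
    if (is.null(d)) return(NULL)
    tidy(d)
  })
  atomic_write(file.path(out_dir, "screen_log.csv"), function(p) {
    readr::write_csv(logs, p, na = "")
  })
  invisible(det)
}

#' Evaluate detections against an annotation file
#'
#' Joins detection records to annotations, writes the per-image evaluation,
#' the group-stratified summary (mean +/- SD and t-based 95% CI of the
#' localization error, acceptance accuracy), and — when the annotation file
#' carries two observers — the interobserver ICC report.
#'
#' @param detections `detections.json` path (from [run_detect()]) or a
#'   detection tibble.
#' @param annotations Annotation CSV path or tibble: `image_id`,
#'   `observer_id`, `xa`, `ya`, `xb`, `yb`, `group_label`.
#' @param config A [detect_config()].
#' @param out_dir If non-NULL, writes `evaluation.csv`,
#'   `group_summary.csv` and (two observers) `icc.json`.
#' @return List with `per_image`, `groups`, `icc` (NULL if one observer).
#' @export
run_evaluate <- function(detections, annotations, config = detect_config(),
                         out_dir = NULL) {
  if (is.character(detections)) {
    raw <- jsonlite::read_json(detections)
    detections <- purrr::map_dfr(raw$detections, function(r) {
      tibble::tibble(image_id = r$image_id, status = r$status,
                     stone_x = r$stone_x %||% NA_real_,
                     stone_y = r$stone_y %||% NA_real_)
    })
  }
  if (is.character(annotations)) {
    annotations <- readr::read_csv(annotations, show_col_types = FALSE)
  }
  primary <- annotations
  icc <- NULL
  if ("observer_id" %in% names(annotations)) {
    obs <- sort(unique(annotations$observer_id))
    if (length(obs) == 2L) icc <- icc_report(annotations)
    primary <- dplyr::filter(annotations, .data$observer_id == obs[1L])
  }
  per_image <- evaluate_detections(
    dplyr::select(detections, "image_id", "status", "stone_x", "stone_y"),
    primary, pixel_spacing_mm = config$pixel_spacing_mm,
    dist_factor = config$accept_dist_factor,
    long_margin = config$accept_long_margin)
  groups <- summarize_groups(per_image)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    atomic_write(file.path(out_dir, "evaluation.csv"), function(p) {
      readr::write_csv(dplyr::select(per_image, -dplyr::any_of(c("frame", "truth"))), p, na = "")
    })
    atomic_write(file.path(out_dir, "group_summary.csv"), function(p) {
      readr::write_csv(groups, p, na = "")
    })
    if (!is.null(icc)) {
      atomic_write(file.path(out_dir, "icc.json"), function(p) {
        jsonlite::write_json(list(config_hash = config_hash(config),
                                  icc = icc), p, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
      })
    }
  }
  list(per_image = per_image, groups = groups, icc = icc)
}

#' Simulate a phantom dataset to disk
#'
#' @param out_dir Output directory.
#' @param n_per_grade Named counts per shadow grade.
#' @param base_spec A [phantom_spec()].
#' @param seed Master seed.
#' @param with_confounder Add one shadow-free bright line per frame.
#' @return The manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir,
                         n_per_grade = c(weak = 5, moderate = 5, strong = 5),
                         base_spec = phantom_spec(), seed = 1L,
                         with_confounder = FALSE) {
  manifest <- generate_dataset(n_per_grade, base_spec, seed = seed,
                               out_dir = out_dir,
                               with_confounder = with_confounder)
  invisible(manifest)
}

#' Run the ablation protocol and write its table
#'
#' @param manifest Annotated manifest (CSV path or tibble; frames via
#'   `path` or `frame` list-column).
#' @param config Base [detect_config()].
#' @param out_dir If non-NULL, writes `ablation.csv` (variants as rows,
#'   confidence groups as columns) and `ablation_distance.csv`.
#' @param variants Named list of configs, default [ablation_variants()].
#' @return The `ablation_result`, invisibly when writing.
#' @export
run_ablate <- function(manifest, config = detect_config(), out_dir = NULL,
                       variants = ablation_variants(config)) {
  manifest <- read_manifest(manifest)
  res <- run_ablation_study(manifest, config, variants)
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atomic_write(file.path(out_dir, "ablation.csv"), function(p) {
    readr::write_csv(res$table, p, na = "")
  })
  atomic_write(file.path(out_dir, "ablation_distance.csv"), function(p) {
    readr::write_csv(res$distance, p, na = "")
  })
  invisible(res)
}
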