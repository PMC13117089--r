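#' Full run configuration
#'
#' Bundles every tunable of the pipeline with its published default, plus
#' the evaluation acceptance-rule factors and the random seed used by
#' simulation commands. Serializes losslessly to YAML via [write_config()] /
#' [read_config()].
#'
#' @param scale_max SIU scale ceiling after min-max normalization.
#' @param median_kernel Median-filter kernel side (odd).
#' @param candidates A [candidate_params()].
#' @param screens A [screen_params()].
#' @param weights A [score_weights()].
#' @param enable_lc,enable_sr Screen gates.
#' @param normalize_scores Per-image feature normalization in the composite
#'   score (see [score_candidates()]).
#' @param accept_dist_factor,accept_long_margin Acceptance-rule capsule
#'   factors (see [is_correct()]).
#' @param pixel_spacing_mm Default mm-per-pixel conversion.
#' @param seed Integer seed for simulation commands.
#' @return A list of class `stone_config`.
#' @export
detect_config <- function(scale_max = 1000, median_kernel = 3,
                          candidates = candidate_params(),
                          screens = screen_params(),
                          weights = score_weights(),
                          enable_lc = TRUE, enable_sr = TRUE,
                          normalize_scores = TRUE,
                          accept_dist_factor = 0.5, accept_long_margin = 0.25,
                          pixel_spacing_mm = 0.35, seed = 1L) {
  stopifnot(inherits(candidates, "candidate_params"),
            inherits(screens, "screen_params"),
            inherits(weights, "score_weights"))
  structure(list(
    scale_max = scale_max, median_kernel = median_kernel,
    candidates = candidates, screens = screens, weights = weights,
    enable_lc = isTRUE(enable_lc), enable_sr = isTRUE(enable_sr),
    normalize_scores = isTRUE(normalize_scores),
    accept_dist_factor = accept_dist_factor,
    accept_long_margin = accept_long_margin,
    pixel_spacing_mm = pixel_spacing_mm, seed = as.integer(seed)),
    class = "stone_config")
}

#' @export
print.stone_config <- function(x, ...) {
  cat("<stone_config>", config_hash(x), "\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Serialize / restore a run configuration
#'
#' YAML round-trip. `read_config()` rejects files containing keys the
#' configuration does not define, naming the offending key.
#'
#' @param config A [detect_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   [detect_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "stone_config"))
  plain <- rapply(unclass(config), f = identity, how = "list")
  atomic_write(path, function(p) yaml::write_yaml(plain, p))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- unclass(detect_config())
  check_keys <- function(got, ref, where) {
    extra <- setdiff(names(got), names(ref))
    if (length(extra) > 0L) {
      abort(sprintf("unknown configuration key: %s%s", where, extra[1L]))
    }
  }
  check_keys(raw, def, "")
  for (nm in intersect(names(raw), c("candidates", "screens", "weights"))) {
    check_keys(raw[[nm]], unclass(def[[nm]]), paste0(nm, "$"))
  }
  cand <- do.call(candidate_params, raw$candidates %||% list())
  scr <- do.call(screen_params, raw$screens %||% list())
  wts <- do.call(score_weights, raw$weights %||% list())
  top <- raw[setdiff(names(raw), c("candidates", "screens", "weights"))]
  do.call(detect_config, c(top, list(candidates = cand, screens = scr,
                                     weights = wts)))
}

#' Stable hash of a configuration
#'
#' Recorded in every report so outputs can be traced to the exact parameter
#' set that produced them.
#'
#' @param config A [detect_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(rapply(unclass(config), f = identity, how = "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write-then-rename so interrupted runs never leave truncated files
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
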