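#' Screening parameters
#'
#' Defaults are the published operating point: ring margin 5 px, local
#' contrast threshold `tau_lc` = 300 SIU, central band width 5 px
#' (`band_halfwidth` h = 2), vertical analysis depth 30 px, lateral offset
#' 10 px, profile balance `rho` = 0.5, shadow-region threshold `tau_sr` =
#' 100 SIU. Thresholds are absolute on the SIU scale (see
#' [normalize_minmax()]), and a candidate passes a screen when its statistic
#' is `>=` the threshold.
#'
#' @param ring_margin Ring expansion around the candidate box, px.
#' @param tau_lc Local-contrast rejection threshold, SIU.
#' @param band_halfwidth Half-width h of the profile bands (band width 2h+1).
#' @param depth Vertical analysis depth below the candidate, px.
#' @param lateral_offset Lateral gap between centre and reference bands, px.
#' @param rho Weight of the drop-segment median difference in the
#'   shadow-region score.
#' @param tau_sr Shadow-region rejection threshold, SIU.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(ring_margin = 5, tau_lc = 300, band_halfwidth = 2,
                          depth = 30, lateral_offset = 10, rho = 0.5,
                          tau_sr = 100) {
  v <- c(ring_margin = ring_margin, band_halfwidth = band_halfwidth,
         depth = depth, lateral_offset = lateral_offset, rho = rho)
  if (!all(is.finite(v)) || any(v <= 0)) {
    abort("screen_params: ring_margin, band_halfwidth, depth, lateral_offset and rho must be positive.")
  }
  structure(list(ring_margin = as.integer(ring_margin), tau_lc = tau_lc,
                 band_halfwidth = as.integer(band_halfwidth),
                 depth = as.integer(depth),
                 lateral_offset = as.integer(lateral_offset),
                 rho = rho, tau_sr = tau_sr),
            class = "screen_params")
}

#' Candidate-box and surrounding-ring mean intensities
#'
#' The ring is the candidate bounding box expanded by `ring_margin` on every
#' side, clipped to the image, minus the box itself. If clipping leaves the
#' ring empty (the box spans the whole image) the ring mean is `NA` and the
#' candidate is reported as "ring undefined" downstream.
#'
#' @param image A `siu_image`.
#' @param bbox A [roi_box] for the candidate (within the image).
#' @param ring_margin Expansion in pixels, default 5.
#' @return Named numeric vector `c(inside = , ring = )`.
#' @export
ring_means <- function(image, bbox, ring_margin = 5) {
  stopifnot(inherits(image, c("us_frame", "siu_image")), inherits(bbox, "roi_box"))
  m <- image$pixels
  check_roi_within(bbox, nrow(m), ncol(m))
  inside <- mean(m[roi_rows(bbox), roi_cols(bbox)])
  r1 <- max(1L, bbox$row0 - ring_margin)
  r2 <- min(nrow(m), bbox$row0 + bbox$n_rows - 1L + ring_margin)
  c1 <- max(1L, bbox$col0 - ring_margin)
  c2 <- min(ncol(m), bbox$col0 + bbox$n_cols - 1L + ring_margin)
  sel <- matrix(FALSE, nrow(m), ncol(m))
  sel[r1:r2, c1:c2] <- TRUE
  sel[roi_rows(bbox), roi_cols(bbox)] <- FALSE
  ring <- if (any(sel)) mean(m[sel]) else NA_real_
  c(inside = inside, ring = ring)
}

#' Local contrast
#'
#' Difference between the candidate-box mean and the surrounding-ring mean.
#' May be negative (a dark box in a bright surround).
#'
#' @param is_bar Mean intensity inside the candidate box, SIU.
#' @param ir_bar Mean intensity of the surrounding ring, SIU.
#' @return `is_bar - ir_bar`, SIU.
#' @export
local_contrast <- function(is_bar, ir_bar) is_bar - ir_bar

round_half_up <- function(x) floor(x + 0.5)

band_cols <- function(center, halfwidth, n_col) {
  cols <- (center - halfwidth):(center + halfwidth)
  cols[cols >= 1L & cols <= n_col]
}

#' Axial intensity profiles beneath a candidate
#'
#' Builds the centre profile PC(y) (mean over a narrow band centred at the
#' candidate centroid) and the lateral reference profile PL(y) (mean over
#' left and right bands offset laterally) for up to `depth` rows starting
#' just below the candidate bounding box. A lateral band that falls entirely
#' outside the image is dropped; if both are lost the shadow test is not
#' evaluable. The steepest-descent row (`y_drop`, the most negative forward
#' difference of PC) and the steepest subsequent rise (`y_rise`) delimit the
#' pre-drop segment PCe and the post-drop segment PCl.
#'
#' @param image A `siu_image`.
#' @param xc Candidate centroid lateral coordinate (real-valued; the band
#'   centre is its half-away-from-zero rounding).
#' @param bbox_bottom Last row of the candidate bounding box.
#' @param params A [screen_params()].
#' @return An object of class `shadow_profile` (elements `y_start`, `pc`,
#'   `pl`, `valid_rows`, `i_drop`, `i_rise`, `pce`, `pcl`), or `NULL` when no
#'   in-bounds rows exist below the candidate or both lateral bands are out
#'   of bounds.
#' @export
axial_profiles <- function(image, xc, bbox_bottom, params = screen_params()) {
  stopifnot(inherits(image, c("us_frame", "siu_image")))
  m <- image$pixels
  n_row <- nrow(m); n_col <- ncol(m)
  y_start <- as.integer(bbox_bottom) + 1L
  if (y_start > n_row) return(NULL)
  ys <- y_start:min(n_row, y_start + params$depth - 1L)
  cx <- round_half_up(xc)
  h <- params$band_halfwidth
  cc <- band_cols(cx, h, n_col)
  lc <- band_cols(cx - params$lateral_offset, h, n_col)
  rc <- band_cols(cx + params$lateral_offset, h, n_col)
  lat <- union(lc, rc)
  if (length(cc) == 0L || length(lat) == 0L) return(NULL)
  pc <- rowMeans(m[ys, cc, drop = FALSE])
  pl <- rowMeans(m[ys, lat, drop = FALSE])
  n <- length(ys)
  if (n >= 2L) {
    d <- pc[-1L] - pc[-n]
    i_drop <- which.min(d)
    if (i_drop < n - 1L) {
      rest <- d[(i_drop + 1L):(n - 1L)]
      i_rise <- i_drop + which.max(rest)
    } else {
      i_rise <- NA_integer_
    }
  } else {
    d <- numeric(0)
    i_drop <- NA_integer_
    i_rise <- NA_integer_
  }
  pce <- if (!is.na(i_drop)) pc[seq_len(i_drop)] else pc
  pcl <- if (!is.na(i_drop) && !is.na(i_rise)) pc[(i_drop + 1L):i_rise] else numeric(0)
  structure(
    list(y_start = y_start, pc = as.numeric(pc), pl = as.numeric(pl),
         valid_rows = n, diffs = as.numeric(d),
         i_drop = i_drop, i_rise = i_rise,
         pce = as.numeric(pce), pcl = as.numeric(pcl)),
    class = "shadow_profile"
  )
}

#' @export
print.shadow_profile <- function(x, ...) {
  cat(sprintf("<shadow_profile> %d rows from y = %d; drop at %s, rise at %s\n",
              x$valid_rows, x$y_start,
              if (is.na(x$i_drop)) "-" else x$y_start + x$i_drop - 1L,
              if (is.na(x$i_rise)) "-" else x$y_start + x$i_rise - 1L))
  invisible(x)
}

#' Shadow-region score
#'
#' `mean(PL - PC) + rho * (median(PCe) - median(PCl))`, SIU. The first term
#' measures selective beam attenuation in the centre band relative to the
#' laterally adjacent tissue; the second rewards a sharp bright-to-dark
#' transition at the stone site, so the score grows rather than vanishes for
#' genuine stones. When the post-drop segment is degenerate (the steepest
#' drop sits at the last profile row, or the profile has a single row) the
#' second term is 0 and a warning is issued.
#'
#' @param profile A `shadow_profile` from [axial_profiles()].
#' @param rho Balance between the two terms, default 0.5.
#' @return The score in SIU.
#' @export
shadow_region_score <- function(profile, rho = 0.5) {
  stopifnot(inherits(profile, "shadow_profile"))
  base <- mean(profile$pl - profile$pc)
  if (length(profile$pcl) == 0L || length(profile$pce) == 0L) {
    warn("degenerate profile segments; shadow-region median term set to 0.")
    return(base)
  }
  base + rho * (median(profile$pce) - median(profile$pcl))
}

#' Screen candidates by local contrast and posterior shadow
#'
#' Evaluates each candidate independently: the local contrast test rejects
#' candidates with `local_contrast < tau_lc`, the shadow-region test rejects
#' candidates with `shadow_region < tau_sr`. A disabled screen neither
#' rejects nor contributes, but its statistic is still computed and recorded
#' when computable (for ablation reporting). Candidates whose ring is
#' undefined, or whose shadow profile is not evaluable, fail the respective
#' screen with a reason code.
#'
#' @param image A `siu_image` (the ROI the candidates came from).
#' @param regions Candidate tibble (from [select_top_k()]).
#' @param params A [screen_params()].
#' @param enable_lc,enable_sr Enable the local-contrast / shadow-region gate.
#' @param keep_rejected Keep rejected rows (flagged) instead of dropping them.
#' @return `regions` with columns `is_bar`, `ir_bar`, `local_contrast`,
#'   `shadow_region`, `passed_lc`, `passed_sr`, `reason`, and a list-column
#'   `profile`; rejected rows dropped unless `keep_rejected`.
#' @export
screen_candidates <- function(image, regions, params = screen_params(),
                              enable_lc = TRUE, enable_sr = TRUE,
                              keep_rejected = FALSE) {
  if (nrow(regions) == 0L) {
    return(dplyr::mutate(regions, is_bar = double(), ir_bar = double(),
                         local_contrast = double(), shadow_region = double(),
                         passed_lc = logical(), passed_sr = logical(),
                         reason = character(), profile = list()))
  }
  res <- purrr::map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    bbox <- roi_box(r$row0, r$col0, r$n_rows, r$n_cols)
    rm <- ring_means(image, bbox, params$ring_margin)
    lc <- if (is.na(rm[["ring"]])) NA_real_ else local_contrast(rm[["inside"]], rm[["ring"]])
    prof <- axial_profiles(image, r$xc, r$row0 + r$n_rows - 1L, params)
    sr <- if (is.null(prof)) NA_real_ else suppressWarnings(shadow_region_score(prof, params$rho))
    passed_lc <- !is.na(lc) && lc >= params$tau_lc
    passed_sr <- !is.na(sr) && sr >= params$tau_sr
    reason <- if (enable_lc && is.na(lc)) "ring_undefined"
      else if (enable_lc && !passed_lc) "low_contrast"
      else if (enable_sr && is.null(prof)) "shadow_not_evaluable"
      else if (enable_sr && !passed_sr) "low_shadow"
      else "ok"
    list(is_bar = rm[["inside"]], ir_bar = rm[["ring"]],
         local_contrast = lc, shadow_region = sr,
         passed_lc = passed_lc, passed_sr = passed_sr,
         reason = reason, profile = prof)
  })
  out <- dplyr::mutate(regions,
    is_bar = purrr::map_dbl(res, "is_bar"),
    ir_bar = purrr::map_dbl(res, "ir_bar"),
    local_contrast = purrr::map_dbl(res, "local_contrast"),
    shadow_region = purrr::map_dbl(res, "shadow_region"),
    passed_lc = purrr::map_lgl(res, "passed_lc"),
    passed_sr = purrr::map_lgl(res, "passed_sr"),
    reason = purrr::map_chr(res, "reason"),
    profile = purrr::map(res, "profile"))
  if (keep_rejected) out else dplyr::filter(out, .data$reason == "ok")
}
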