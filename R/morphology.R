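# Grayscale morphology on plain matrices.
#
# Erosion uses +Inf outside the image (restriction to valid pixels), dilation
# uses -Inf; under these conventions opening(I) <= I holds everywhere, so the
# white top-hat is exactly non-negative.

shift_fill <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  if (any(ok_r) && any(ok_c)) {
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  }
  out
}

disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

erode_gray <- function(m, offsets) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (j in seq_len(nrow(offsets))) {
    out <- pmin(out, shift_fill(m, offsets$dr[j], offsets$dc[j], Inf))
  }
  out
}

dilate_gray <- function(m, offsets) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (j in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_fill(m, offsets$dr[j], offsets$dc[j], -Inf))
  }
  out
}

#' White top-hat enhancement
#'
#' Subtracts the morphological opening by a disc-shaped structuring element
#' from the image, isolating locally bright structures narrower than the disc
#' (the hyperechoic stone surface) while suppressing slowly varying background
#' echogenicity. The disc of radius `se_radius` contains the pixel offsets
#' with `dr^2 + dc^2 <= se_radius^2`.
#'
#' @param image A `siu_image` (or `us_frame`).
#' @param se_radius Structuring-element radius in pixels, default 5.
#' @return Object of the same class; all pixels `>= 0`.
#' @export
tophat_enhance <- function(image, se_radius = 5L) {
  stopifnot(inherits(image, c("us_frame", "siu_image")))
  if (length(se_radius) != 1L || !is.finite(se_radius) || se_radius < 1L) {
    abort("`se_radius` must be a single integer >= 1.")
  }
  offs <- disc_offsets(as.integer(se_radius))
  opened <- dilate_gray(erode_gray(image$pixels, offs), offs)
  out <- image
  out$pixels <- image$pixels - opened
  out
}

# Regional maxima: connected plateaus (8-connectivity) all of whose outside
# neighbours are strictly lower. Returns a logical matrix.
#
# Seed with pixels having no strictly higher 8-neighbour, then iteratively
# drop pixels whose equal-valued neighbour has already been disqualified
# (propagates "touches something higher" through plateaus).
regional_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nb_max <- matrix(-Inf, nr, nc)
  for (j in seq_len(nrow(offs))) {
    nb_max <- pmax(nb_max, shift_fill(m, offs$dr[j], offs$dc[j], -Inf))
  }
  p <- m >= nb_max
  repeat {
    drop <- matrix(FALSE, nr, nc)
    for (j in seq_len(nrow(offs))) {
      nb_val <- shift_fill(m, offs$dr[j], offs$dc[j], NA)
      nb_in <- shift_fill(p * 1, offs$dr[j], offs$dc[j], 1) > 0
      drop <- drop | (!is.na(nb_val) & nb_val == m & !nb_in)
    }
    drop <- drop & p
    if (!any(drop)) break
    p[drop] <- FALSE
  }
  p
}
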