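# Independent brute-force reference implementations used as oracles.
# These deliberately use plain per-pixel loops and sorting, sharing no code
# with the package internals they check.

siu <- function(m, scale_max = 1000) {
  structure(list(pixels = m, scale_max = scale_max, pixel_spacing_mm = 0.35,
                 source_id = "test"), class = "siu_image")
}

# median filter: per-pixel neighbourhood sort with edge replication
oracle_median <- function(m, k) {
  r <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- sort(vals)[(length(vals) + 1) %/% 2]
  }
  out
}

# grayscale opening by a disc: exhaustive-loop erosion then dilation,
# restricted to in-bounds neighbours
oracle_opening <- function(m, radius) {
  offs <- list()
  for (di in -radius:radius) for (dj in -radius:radius) {
    if (di^2 + dj^2 <= radius^2) offs[[length(offs) + 1]] <- c(di, dj)
  }
  nr <- nrow(m); nc <- ncol(m)
  er <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) v <- min(v, m[ii, jj])
    }
    er[i, j] <- v
  }
  di_ <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- -Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) v <- max(v, er[ii, jj])
    }
    di_[i, j] <- v
  }
  di_
}

# linear-interpolation percentile over sorted values (type-7 definition,
# written out explicitly)
oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# regional maxima by exhaustive plateau flood fill (for small grids)
oracle_regional_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seen[i, j]) next
    # flood the plateau of equal value containing (i, j)
    val <- m[i, j]
    stack <- list(c(i, j))
    plateau <- list()
    mark <- matrix(FALSE, nr, nc)
    mark[i, j] <- TRUE
    is_max <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      plateau[[length(plateau) + 1]] <- p
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (m[ii, jj] > val) is_max <- FALSE
        if (m[ii, jj] == val && !mark[ii, jj]) {
          mark[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
    for (p in plateau) {
      seen[p[1], p[2]] <- TRUE
      out[p[1], p[2]] <- is_max
    }
  }
  out
}

# area of the convex hull of pixel corner points by fine-grid rasterization
oracle_hull_area <- function(rows, cols, step = 0.05) {
  x <- c(cols - 0.5, cols + 0.5, cols + 0.5, cols - 0.5)
  y <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  gx <- seq(min(x) + step / 2, max(x), by = step)
  gy <- seq(min(y) + step / 2, max(y), by = step)
  pts <- expand.grid(px = gx, py = gy)
  # point-in-convex-polygon via sign of cross products
  n <- length(hx)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    cr <- (hx[k2] - hx[k]) * (pts$py - hy[k]) - (hy[k2] - hy[k]) * (pts$px - hx[k])
    inside <- inside & (cr <= 1e-9)
  }
  if (sum(inside) == 0) {
    # hull orientation was counter-clockwise; flip the test
    inside <- rep(TRUE, nrow(pts))
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      cr <- (hx[k2] - hx[k]) * (pts$py - hy[k]) - (hy[k2] - hy[k]) * (pts$px - hx[k])
      inside <- inside & (cr >= -1e-9)
    }
  }
  sum(inside) * step^2
}

# shortest point-to-line distance by dense sampling along the segment's
# carrier line
oracle_line_distance <- function(point, a_pt, b_pt, n = 1e6) {
  t <- seq(-50, 51, length.out = n)
  px <- a_pt[1] + t * (b_pt[1] - a_pt[1])
  py <- a_pt[2] + t * (b_pt[2] - a_pt[2])
  sqrt(min((px - point[1])^2 + (py - point[2])^2))
}

# shadow-region score recomputed with explicit loops and sorts
oracle_shadow_score <- function(pc, pl, rho) {
  n <- length(pc)
  diffs <- numeric(n - 1)
  for (i in seq_len(n - 1)) diffs[i] <- pc[i + 1] - pc[i]
  i_drop <- 1
  for (i in seq_len(n - 1)) if (diffs[i] < diffs[i_drop]) i_drop <- i
  pce <- pc[1:i_drop]
  med <- function(v) {
    s <- sort(v); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  term1 <- sum(pl - pc) / n
  if (i_drop >= n - 1) return(term1)
  rest <- diffs[(i_drop + 1):(n - 1)]
  i_rise <- i_drop + which(rest == max(rest))[1]
  pcl <- pc[(i_drop + 1):i_rise]
  term1 + rho * (med(pce) - med(pcl))
}

# two-way ANOVA mean squares written out from sums of squares
oracle_icc2_1 <- function(o1, o2) {
  n <- length(o1); k <- 2
  y <- cbind(o1, o2)
  grand <- mean(y)
  row_m <- rowMeans(y); col_m <- colMeans(y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

make_frame <- function(m, spacing = 0.35) us_frame(m, pixel_spacing_mm = spacing)
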