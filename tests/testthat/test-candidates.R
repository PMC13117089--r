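test_that("top-hat enhancement matches the loop-based opening oracle", {
  expect_equal(tophat_enhance(siu(matrix(400, 8, 8)), 3)$pixels,
               matrix(0, 8, 8))

  imp <- matrix(0, 13, 13); imp[7, 7] <- 1000
  th <- tophat_enhance(siu(imp), 5)$pixels
  expect_equal(th[7, 7], 1000)
  expect_equal(sum(th), 1000)

  # filled disc of radius 12 vs SE radius 5: interior suppressed
  g <- expand.grid(r = 1:31, c = 1:31)
  disc <- matrix(1000 * ((g$r - 16)^2 + (g$c - 16)^2 <= 144), 31, 31)
  th2 <- tophat_enhance(siu(disc), 5)$pixels
  expect_equal(th2[16, 16], 0)
  expect_equal(th2, disc - oracle_opening(disc, 5))

  set.seed(9)
  r <- matrix(stats::runif(15 * 15, 0, 1000), 15, 15)
  expect_equal(tophat_enhance(siu(r), 2)$pixels, r - oracle_opening(r, 2))
  # invariant to adding a constant
  expect_equal(tophat_enhance(siu(r + 123), 2)$pixels,
               tophat_enhance(siu(r), 2)$pixels)
  expect_true(all(tophat_enhance(siu(r), 5)$pixels >= 0))
})

test_that("percentile thresholding uses strict exceedance of the type-7 quantile", {
  m <- matrix(1:100, 10, 10)
  mask <- threshold_candidates(siu(m), 99)
  thr <- oracle_percentile(1:100, 99)
  expect_identical(mask, m > thr)

  expect_false(any(threshold_candidates(siu(matrix(0, 5, 5)), 99)))
  one <- matrix(0, 9, 9); one[5, 5] <- 1000
  expect_identical(which(threshold_candidates(siu(one), 90)), which(one > 0))

  set.seed(3)
  r <- matrix(stats::runif(64, 0, 1000), 8, 8)
  expect_identical(threshold_candidates(siu(r), 75),
                   r > oracle_percentile(as.vector(r), 75))
})

test_that("small components are removed at the 8-connected area threshold", {
  m <- matrix(FALSE, 12, 24)
  m[2:5, 2:6] <- TRUE                  # 20 px, kept at threshold
  m[8:11, 8:12] <- TRUE; m[11, 12] <- FALSE  # 19 px, removed
  out <- remove_small(m, 20)
  expect_true(all(out[2:5, 2:6]))
  expect_false(any(out[8:11, 8:12]))

  mixed <- matrix(FALSE, 30, 30)
  mixed[1:1, 1:5] <- TRUE              # 5 px
  mixed[5:9, 10:14] <- TRUE            # 25 px
  mixed[15:24, 15:24] <- TRUE          # 100 px
  out2 <- remove_small(mixed, 20)
  expect_false(any(out2[1, 1:5]))
  expect_true(all(out2[5:9, 10:14]))
  expect_true(all(out2[15:24, 15:24]))

  # diagonal touching counts as connected (8-connectivity)
  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_true(all(remove_small(diag2, 2) == diag2))
})

test_that("regional-maxima gate matches the exhaustive plateau oracle", {
  # smooth bump retains its own peak
  g <- expand.grid(r = 1:11, c = 1:11)
  bump <- matrix(exp(-((g$r - 6)^2 + (g$c - 6)^2) / 8) * 1000, 11, 11)
  mask <- bump > 400
  expect_identical(regional_maxima_gate(mask, siu(bump)), mask)

  # pure ramp: no interior regional maximum, mid-mask removed
  ramp <- matrix(rep(1:15, each = 15), 15, 15)
  mid <- matrix(FALSE, 15, 15); mid[6:9, 6:9] <- TRUE
  expect_false(any(regional_maxima_gate(mid, siu(ramp))))

  # package's maxima agree with the oracle on random small grids
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(sample(0:6, 100, replace = TRUE), 10, 10)
    expect_identical(echolith:::regional_maxima(m), oracle_regional_maxima(m))
  }

  # two bumps, mask covering only one: locality
  two <- matrix(0, 11, 21)
  two[, 1:11] <- bump
  two[, 11:21] <- pmax(two[, 11:21], bump)
  m1 <- matrix(FALSE, 11, 21); m1[4:8, 4:8] <- TRUE
  expect_identical(regional_maxima_gate(m1, siu(two)), m1)
})

test_that("region descriptors follow the moment-ellipse and corner-hull definitions", {
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  img <- siu(matrix(100, 9, 9))
  r <- extract_regions(sq, img)
  expect_equal(r$area, 25L)
  expect_equal(r$mu, 100)
  expect_equal(c(r$xc, r$yc), c(5, 5))
  expect_equal(r$eccentricity, 0)
  expect_equal(r$solidity, 1)
  expect_equal(r$l_max / r$l_min, 1)
  expect_equal(unlist(r[, c("row0", "col0", "n_rows", "n_cols")]),
               c(row0 = 3, col0 = 3, n_rows = 5, n_cols = 5),
               ignore_attr = TRUE)

  line <- matrix(FALSE, 5, 11); line[3, 2:10] <- TRUE
  rl <- extract_regions(line, siu(matrix(1, 5, 11)))
  expect_gt(rl$eccentricity, 0.99)
  expect_gt(rl$l_max / rl$l_min, 5)
  expect_equal(rl$solidity, 1)

  # plus pentomino: solidity = 5 / corner-hull area, vs rasterization oracle
  plus <- matrix(FALSE, 5, 5)
  plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  rp <- extract_regions(plus, siu(matrix(1, 5, 5)))
  pix <- rp$pixels[[1]]
  expect_equal(rp$solidity, 5 / 7)
  expect_equal(rp$solidity,
               5 / oracle_hull_area(pix[, "row"], pix[, "col"], step = 0.02),
               tolerance = 0.01)
  expect_lt(rp$solidity, 1)

  # recomputing descriptors from the stored pixel set reproduces them
  set.seed(5)
  noise <- matrix(stats::runif(400, 0, 1000), 20, 20)
  mask <- noise > 600
  regs <- extract_regions(mask, siu(noise))
  for (i in seq_len(nrow(regs))) {
    pix <- regs$pixels[[i]]
    expect_equal(regs$area[i], nrow(pix))
    expect_equal(regs$mu[i], mean(noise[pix]))
    expect_equal(regs$xc[i], mean(pix[, "col"]))
    expect_equal(regs$yc[i], mean(pix[, "row"]))
  }
  expect_equal(nrow(extract_regions(matrix(FALSE, 4, 4), siu(matrix(0, 4, 4)))), 0L)
})

test_that("shape penalty follows the tolerance-gated three-term form", {
  p <- candidate_params()
  reg <- tibble::tibble(eccentricity = 0, solidity = 1, l_max = 2, l_min = 2)
  expect_equal(shape_penalty(reg, p)$shape_penalty, 0)
  reg2 <- tibble::tibble(eccentricity = 1, solidity = 1, l_max = 4, l_min = 2)
  expect_equal(shape_penalty(reg2, p)$shape_penalty, 0.4)
  reg3 <- tibble::tibble(eccentricity = 0.8, solidity = 0.9, l_max = 6, l_min = 2)
  expect_equal(shape_penalty(reg3, p)$shape_penalty,
               0.4 * 0.8 + 0.3 * 0.1 + 0.3 * 1)
  # degenerate minor axis saturates the elongation term at the cap of 10
  reg4 <- tibble::tibble(eccentricity = 1, solidity = 1, l_max = 3, l_min = 0)
  expect_equal(shape_penalty(reg4, p)$shape_penalty, 0.4 + 0.3 * 10)
})

test_that("brightness is integrated intensity with a mean-mode switch", {
  reg <- tibble::tibble(mu = 500, area = 20L)
  expect_equal(candidate_brightness(reg)$brightness, 10000)
  expect_equal(candidate_brightness(tibble::tibble(mu = 0, area = 50))$brightness, 0)
  expect_equal(candidate_brightness(reg, candidate_params(brightness_mode = "mean"))$brightness, 500)

  # uniform region: product equals the direct pixel sum
  m <- matrix(0, 8, 8); m[2:4, 2:5] <- 440
  regs <- extract_regions(m > 0, siu(m)) |> candidate_brightness()
  expect_equal(regs$brightness, sum(m))
})

test_that("top-K selection sorts by brightness with deterministic tie-breaks", {
  regs <- tibble::tibble(brightness = c(5, 9, 1, 7, 3, 8, 6),
                         yc = 1:7, xc = 1:7)
  expect_equal(select_top_k(regs, 5)$brightness, c(9, 8, 7, 6, 5))
  expect_equal(nrow(select_top_k(regs[1:3, ], 5)), 3L)
  ties <- tibble::tibble(brightness = c(4, 4), yc = c(10, 2), xc = c(1, 1))
  expect_equal(select_top_k(ties, 1)$yc, 2)
})
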