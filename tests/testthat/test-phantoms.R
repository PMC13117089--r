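test_that("speckle background is seeded, Rayleigh-based and mean-calibrated", {
  sp <- phantom_spec(seed = 5)
  f1 <- speckle_background(sp)
  f2 <- speckle_background(sp)
  expect_identical(f1$pixels, f2$pixels)
  f3 <- speckle_background(phantom_spec(seed = 6))
  expect_false(identical(f1$pixels, f3$pixels))

  big <- speckle_background(phantom_spec(height = 256, width = 256, seed = 1))
  expect_lt(abs(mean(big$pixels) / 120 - 1), 0.02)
})

test_that("the stone renders a proximal-bright ellipse with analytic truth", {
  sp <- phantom_spec(stone_center = c(40, 40), stone_axes = c(9, 6),
                     stone_orientation = 0, stone_gain = 3,
                     stone_distal_gain = 1.2, height = 80, width = 80)
  bg <- us_frame(matrix(200, 80, 80))
  st <- add_stone(bg, sp)
  # proximal interior near the gain, distal pole near the distal gain
  expect_equal(st$frame$pixels[36, 40], 3 * 200, tolerance = 0.15)
  expect_gt(st$frame$pixels[36, 40], st$frame$pixels[44, 40])
  expect_equal(st$frame$pixels[20, 20], 200)  # outside untouched

  # truth centroid equals mask moments to < 0.5 px
  idx <- which(st$truth$stone_mask, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2]) - st$truth$stone_centroid[["x"]]), 0.5)
  expect_lt(abs(mean(idx[, 1]) - st$truth$stone_centroid[["y"]]), 0.5)
  # axis endpoints sit on the ellipse boundary along the major axis
  expect_equal(unname(st$truth$axis_a), c(31, 40))
  expect_equal(unname(st$truth$axis_b), c(49, 40))

  # orientation 0 vs pi give identical masks
  sp_pi <- phantom_spec(stone_center = c(40, 40), stone_axes = c(9, 6),
                        stone_orientation = pi, height = 80, width = 80)
  expect_equal(add_stone(bg, sp_pi)$truth$stone_mask, st$truth$stone_mask)

  expect_error(add_stone(us_frame(matrix(1, 20, 20)), sp), "beyond the frame")
})

test_that("shadow grades attenuate, feather and (weak) interrupt the column", {
  bg <- us_frame(matrix(200, 120, 80))
  sp_s <- phantom_spec(stone_center = c(40, 40), shadow_grade = "strong",
                       height = 120, width = 80, seed = 2)
  st <- add_stone(bg, sp_s)
  sh <- add_shadow(st$frame, sp_s, st$truth)
  inside <- mean(sh$frame$pixels[sh$truth$shadow_mask])
  rows <- which(rowSums(sh$truth$shadow_mask) > 0)
  lateral <- mean(sh$frame$pixels[rows, 5:15])
  expect_lte(inside, 0.35 * lateral)

  set.seed(1)
  sp_w <- phantom_spec(stone_center = c(40, 40), shadow_grade = "weak",
                       height = 120, width = 80, seed = 2)
  stw <- add_stone(bg, sp_w)
  shw <- add_shadow(stw$frame, sp_w, stw$truth)
  expect_gte(length(shw$truth$gap_rows), 2L)
  expect_true(all(shw$truth$gap_rows %in% which(rowSums(shw$truth$shadow_mask) > 0)))
  # gap rows are unattenuated in the core columns
  core <- which(colSums(shw$truth$shadow_mask) > 0)
  expect_equal(mean(shw$frame$pixels[shw$truth$gap_rows[1], core]), 200)

  sp_n <- phantom_spec(stone_center = c(40, 40), shadow_grade = "none",
                       height = 120, width = 80)
  stn <- add_stone(bg, sp_n)
  shn <- add_shadow(stn$frame, sp_n, stn$truth)
  expect_identical(shn$frame$pixels[60:120, ], stn$frame$pixels[60:120, ])
  expect_false(any(shn$truth$shadow_mask))
})

test_that("confounders are bright lines with no posterior attenuation", {
  bg <- us_frame(matrix(200, 60, 60))
  sp <- phantom_spec(height = 60, width = 60, with_stone = FALSE,
                     confounders = list(list(x0 = 10, y0 = 20, x1 = 40,
                                             y1 = 20, gain = 3, thickness = 2)))
  out <- add_confounders(bg, sp)
  expect_equal(out$pixels[20, 25], 600)
  expect_equal(out$pixels[21, 25], 600)
  expect_equal(out$pixels[22:60, ], bg$pixels[22:60, ])

  none <- phantom_spec(height = 60, width = 60, with_stone = FALSE)
  expect_identical(add_confounders(bg, none)$pixels, bg$pixels)
})

test_that("confounder candidates fail the shadow screen in most frames", {
  fails <- 0
  for (s in 1:20) {
    sp <- echolith:::jittered_spec(phantom_spec(), "none", s, 400,
                                   with_confounder = TRUE, with_stone = FALSE)
    ph <- generate_phantom(sp)
    det <- detect_stone(ph$frame, roi_box(20, 20, 120, 120),
                        detect_config(enable_lc = FALSE, enable_sr = FALSE))
    lg <- det$screen_log
    if (nrow(lg) == 0L) { fails <- fails + 1; next }
    conf_like <- lg[lg$yc > 100, ]
    if (nrow(conf_like) == 0L || all(is.na(conf_like$shadow_region)) ||
        all(conf_like$shadow_region < 100, na.rm = TRUE)) {
      fails <- fails + 1
    }
  }
  expect_gte(fails, 18L)
})

test_that("dataset generation is reproducible with balanced labels", {
  man <- generate_dataset(c(weak = 5, moderate = 5, strong = 5), seed = 8)
  expect_equal(nrow(man), 15L)
  expect_equal(unname(table(man$group_label)[c("50to60", "60to80", "ge80")]),
               rep(5L, 3), ignore_attr = TRUE)
  expect_false(any(is.na(man$xa)))

  man2 <- generate_dataset(c(weak = 5, moderate = 5, strong = 5), seed = 8)
  expect_identical(purrr::map(man$frame, "pixels"),
                   purrr::map(man2$frame, "pixels"))

  # written datasets are byte-identical across runs
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(c(strong = 2), seed = 4, out_dir = d1)
  generate_dataset(c(strong = 2), seed = 4, out_dir = d2)
  f1 <- list.files(d1, pattern = "\\.(tif|json)$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "\\.(tif|json)$", full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
  # manifests agree apart from the output directory in the path column
  m1 <- readr::read_csv(file.path(d1, "manifest.csv"), show_col_types = FALSE)
  m2 <- readr::read_csv(file.path(d2, "manifest.csv"), show_col_types = FALSE)
  expect_identical(dplyr::select(m1, -"path"), dplyr::select(m2, -"path"))

  expect_warning(empty <- generate_dataset(c(weak = 0, moderate = 0, strong = 0),
                                           seed = 1), "empty")
  expect_equal(nrow(empty), 0L)

  # paired mode shares speckle and stone geometry across grades
  pm <- generate_dataset(c(weak = 2, strong = 2), seed = 5, paired = TRUE)
  expect_equal(pm$seed[pm$grade == "weak"], pm$seed[pm$grade == "strong"])
  expect_equal(pm$xa[pm$grade == "weak"], pm$xa[pm$grade == "strong"])
})

test_that("strong-grade phantoms are recovered end to end", {
  man <- generate_dataset(c(strong = 10), seed = 31)
  det <- detect_manifest(man)
  expect_gte(sum(det$status == "detected"), 9L)
  hits <- 0
  for (i in which(det$status == "detected")) {
    tr <- man$truth[[i]]
    px <- round(c(det$stone_y[i], det$stone_x[i]))
    hits <- hits + tr$stone_mask[px[1], px[2]]
  }
  expect_gte(hits, 9L)
})
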