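test_that("the general-form line passes through both endpoints", {
  l1 <- line_from_endpoints(c(0, 0), c(10, 0))
  expect_equal(l1[["a"]] * 0 + l1[["b"]] * 0 + l1[["c"]], 0)
  expect_equal(l1[["a"]] * 10 + l1[["b"]] * 0 + l1[["c"]], 0)
  expect_equal(centroid_distance(c(5, 3), l1), 3)

  l2 <- line_from_endpoints(c(0, 0), c(0, 5))
  expect_equal(centroid_distance(c(4, 2), l2), 4)

  l3 <- line_from_endpoints(c(1, 1), c(4, 5))
  expect_lt(abs(l3[["a"]] * 1 + l3[["b"]] * 1 + l3[["c"]]), 1e-12)
  expect_lt(abs(l3[["a"]] * 4 + l3[["b"]] * 5 + l3[["c"]]), 1e-12)

  expect_error(line_from_endpoints(c(2, 2), c(2, 2)), "coincident")
})

test_that("point-to-axis distance matches the dense-sampling oracle", {
  l <- line_from_endpoints(c(0, 0), c(3, 4))
  expect_equal(centroid_distance(c(4, -3), l), 5)
  expect_equal(centroid_distance(c(4, -3), l),
               oracle_line_distance(c(4, -3), c(0, 0), c(3, 4)),
               tolerance = 1e-6)

  set.seed(19)
  for (i in 1:100) {
    a <- stats::runif(2, -50, 50); b <- stats::runif(2, -50, 50)
    if (all(a == b)) next
    o <- stats::runif(2, -50, 50)
    d <- centroid_distance(o, line_from_endpoints(a, b))
    expect_equal(d, oracle_line_distance(o, a, b, n = 2e5), tolerance = 1e-4)
    # endpoint swap and rigid translation invariance
    expect_equal(d, centroid_distance(o, line_from_endpoints(b, a)))
    sh <- c(3.7, -2.2)
    expect_equal(d, centroid_distance(o + sh,
                                      line_from_endpoints(a + sh, b + sh)))
    # invariant to coefficient rescaling
    expect_equal(d, centroid_distance(o, 2.5 * line_from_endpoints(a, b)))
  }
})

test_that("pixel distances convert to millimetres by the spacing", {
  expect_equal(px_to_mm(10, 0.35), 3.5)
  expect_equal(px_to_mm(0), 0)
  expect_equal(px_to_mm(3.6, 0.35), 1.26)
  expect_error(px_to_mm(1, 0), "positive")
})

test_that("the capsule acceptance rule is inclusive at its boundaries", {
  ann <- axis_annotation(0, 0, 10, 0)
  expect_true(is_correct(c(5, 0), ann))
  expect_false(is_correct(c(5, 100), ann))
  # exactly at distance 0.5 * |AB| on the mid perpendicular: inclusive
  expect_true(is_correct(c(5, 5), ann))
  expect_false(is_correct(c(5, 5.0001), ann))
  # longitudinal margin 0.25 * |AB| beyond each end
  expect_true(is_correct(c(-2.5, 0), ann))
  expect_false(is_correct(c(-2.6, 0), ann))
})

test_that("accuracy is the accepted fraction", {
  expect_equal(detection_accuracy(c(rep(TRUE, 14), FALSE)), 14 / 15)
  expect_equal(detection_accuracy(rep(FALSE, 4)), 0)
  expect_equal(detection_accuracy(c(rep(TRUE, 6), rep(FALSE, 4))), 0.6)
  expect_error(detection_accuracy(logical(0)), "non-empty")
})

test_that("annotation parameters are the midpoint and axis length", {
  a <- axis_annotation(0, 0, 10, 0)
  expect_equal(unlist(annotation_params(a)),
               c(center_x = 5, center_y = 0, axis_length = 10))
  b <- axis_annotation(0, 0, 3, 4)
  expect_equal(unlist(annotation_params(b)),
               c(center_x = 1.5, center_y = 2, axis_length = 5))
  swapped <- axis_annotation(3, 4, 0, 0)
  expect_equal(annotation_params(swapped), annotation_params(b))
})

test_that("group summaries use sample SD and the t-based 95% interval", {
  g0 <- summarize_group(c(1, 1, 1, 1), rep(TRUE, 4), "flat")
  expect_equal(c(g0$mean_d, g0$sd_d, g0$ci_low, g0$ci_high), c(1, 0, 1, 1))

  g1 <- summarize_group(c(1, 2, 3), c(TRUE, TRUE, FALSE), "abc")
  expect_equal(g1$mean_d, 2)
  expect_equal(g1$sd_d, 1)
  # t_{0.975, 2} = 4.3027 from an independent statistical table
  expect_equal(g1$ci_low, 2 - 4.3027 / sqrt(3), tolerance = 1e-4)
  expect_equal(g1$ci_high, 2 + 4.3027 / sqrt(3), tolerance = 1e-4)
  expect_equal(g1$accuracy, 2 / 3)

  g2 <- summarize_group(5, TRUE, "single")
  expect_equal(g2$mean_d, 5)
  expect_true(is.na(g2$ci_low) && is.na(g2$ci_high))
  expect_error(summarize_group(numeric(0), logical(0)), "empty")

  # CI width shrinks as n grows on a fixed distance distribution
  set.seed(4)
  widths <- sapply(c(10, 100, 1000), function(n) {
    d <- stats::rnorm(n, 2, 0.5)
    g <- summarize_group(d, rep(TRUE, n), "w")
    g$ci_high - g$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("ICC(A,1) matches the ANOVA oracle with the stated bands", {
  x <- c(9, 6, 8, 7, 10, 6)
  dup <- icc_agreement(x, x)
  expect_equal(dup$icc, 1)
  expect_equal(dup$band, "excellent")

  # hand-built 6-subject table vs explicit sums-of-squares computation
  y1 <- c(9, 6, 8, 7, 10, 6)
  y2 <- c(2, 1, 4, 1, 5, 2)
  got <- icc_agreement(y1, y2)
  expect_equal(got$icc, oracle_icc2_1(y1, y2))
  # symmetry in the observers
  expect_equal(icc_agreement(y2, y1)$icc, got$icc)

  # noise-dominated pairs: near-zero agreement
  set.seed(2024)
  subj <- stats::rnorm(200, 50, 1)
  o1 <- subj + stats::rnorm(200, 0, 20)
  o2 <- subj + stats::rnorm(200, 0, 20)
  noisy <- icc_agreement(o1, o2)
  expect_lt(noisy$icc, 0.2)
  expect_equal(noisy$band, "poor_to_moderate")

  # band edges at 0.75 / 0.90
  mid <- icc_agreement(seq(1, 20), seq(1, 20) + stats::rnorm(20, 0, 2))
  expect_true(mid$band %in% c("poor_to_moderate", "good", "excellent"))
  expect_error(icc_agreement(1:5, 1:4), "length")
  expect_error(icc_agreement(1:2, 1:2), "3 subjects")
})

test_that("evaluation joins detections to annotations and stratifies groups", {
  ann <- tibble::tibble(image_id = c("a", "b", "c"),
                        xa = c(10, 10, 10), ya = c(10, 30, 50),
                        xb = c(20, 20, 20), yb = c(10, 30, 50),
                        group_label = c("ge80", "ge80", "50to60"))
  det <- tibble::tibble(image_id = c("a", "b", "c"),
                        status = c("detected", "detected", "no_candidate"),
                        stone_x = c(15, 15, NA), stone_y = c(11, 300, NA))
  ev <- evaluate_detections(det, ann)
  expect_equal(ev$correct, c(TRUE, FALSE, FALSE))
  expect_equal(ev$d_px, c(1, 270, NA))
  expect_equal(ev$d_mm, c(0.35, 94.5, NA))
  gs <- summarize_groups(ev)
  expect_equal(sort(gs$group_label), c("50to60", "ge80"))
  expect_equal(gs$accuracy[gs$group_label == "ge80"], 0.5)
  expect_equal(gs$n_dist[gs$group_label == "50to60"], 0L)

  expect_error(evaluate_detections(det,
    dplyr::mutate(ann, image_id = paste0("x", image_id))), "no image_id")
})

test_that("icc_report scores both observers' annotation parameters", {
  base <- tibble::tibble(image_id = sprintf("i%02d", 1:8),
                         xa = stats::runif(8, 0, 50), ya = stats::runif(8, 0, 50),
                         xb = stats::runif(8, 50, 100), yb = stats::runif(8, 50, 100))
  dup <- dplyr::bind_rows(dplyr::mutate(base, observer_id = "o1"),
                          dplyr::mutate(base, observer_id = "o2"))
  rep <- icc_report(dup)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$icc, rep(1, 3))
  expect_equal(unique(rep$band), "excellent")
  expect_error(icc_report(dplyr::mutate(base, observer_id = "only")),
               "two observers")
})
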