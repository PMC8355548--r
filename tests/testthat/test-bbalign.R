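# small hand-built image: two separated 5-pixel plus-shaped blobs in one cell
two_blob_fixture <- function() {
  img <- matrix(0, 32, 32)
  for (c0 in list(c(8, 8), c(24, 24))) {
    img[c0[1], c0[2]] <- 100
    img[c0[1] + c(-1, 1), c0[2]] <- 100
    img[c0[1], c0[2] + c(-1, 1)] <- 100
  }
  mask <- matrix(1L, 32, 32)
  list(img = cq_channel(img, "bb"), mask = cq_mask(mask))
}

test_that("segmentation counts separated blobs and respects min_area", {
  fx <- two_blob_fixture()
  px <- segment_bb_rois(fx$img, fx$mask, threshold = 50)
  expect_equal(dplyr::n_distinct(px$roi_id), 2)
  expect_equal(as.integer(table(px$roi_id)), c(5L, 5L))
  # min_area above blob size drops everything, silently
  none <- segment_bb_rois(fx$img, fx$mask, threshold = 50, min_area = 10)
  expect_equal(nrow(none), 0)
  blank <- cq_channel(matrix(1, 32, 32), "bb")
  expect_equal(nrow(segment_bb_rois(blank, fx$mask, threshold = 50)), 0)
  empty_mask <- cq_mask(matrix(0L, 32, 32))
  expect_error(segment_bb_rois(fx$img, empty_mask), "no cells")
})

test_that("components straddling a cell border are clipped by the mask", {
  img <- matrix(0, 16, 16)
  img[8, 6:11] <- 100                      # one bar crossing the border
  mask <- matrix(0L, 16, 16)
  mask[, 1:8] <- 1L; mask[, 9:16] <- 2L
  px <- segment_bb_rois(cq_channel(img, "bb"), cq_mask(mask), threshold = 50)
  expect_equal(dplyr::n_distinct(px$roi_id), 2)
  expect_equal(sort(unique(px$cell_id)), c(1L, 2L))
  expect_true(all(px$x[px$cell_id == 1] <= 8))
})

test_that("aligned synthetic cells give one elongated ROI per row", {
  sim <- make_bb_image(n_cells = 4, frac_aligned = 1, row_spread = 0.5,
                       frame_shape = c(200, 200), seed = 3)
  res <- bb_alignment(sim$image, sim$mask)
  per_cell <- dplyr::count(res$rois, .data$cell_id)
  expect_true(all(per_cell$n <= 4))         # at most rows_per_cell ROIs
  expect_true(all(res$cells$mean_mm_ratio > 2))
  # containment invariant on every fitted ellipse
  px <- segment_bb_rois(sim$image, sim$mask)
  for (id in unique(px$roi_id)) {
    d <- px[px$roi_id == id, ]
    fit <- min_enclosing_ellipse(roi_corner_points(d$x, d$y))
    expect_true(ellipse_contains(fit, roi_corner_points(d$x, d$y)))
  }
})

test_that("per-cell aggregation is an unweighted mean and logs empty cells", {
  ell <- tibble::tibble(roi_id = 1:3, cell_id = c(1L, 1L, 2L),
                        cx = 0, cy = 0, a = c(2, 4, 3), b = 1,
                        orientation = 0,
                        eccentricity = c(0.1, 0.3, 0.2),
                        mm_ratio = c(2, 4, 3), n_pixels = 5L)
  cells <- aggregate_cells(ell, group_label = "ctrl")
  expect_equal(cells$mean_mm_ratio[cells$cell_id == 1], 3)
  expect_equal(cells$mean_eccentricity[cells$cell_id == 1], 0.2)
  expect_equal(cells$group, c("ctrl", "ctrl"))
  mask <- cq_mask(matrix(c(1L, 2L, 3L, 3L), 2, 2))
  expect_message(aggregate_cells(ell, mask, "ctrl"), "without ROIs")
  expect_equal(nrow(aggregate_cells(ell[0, ])), 0)
})

test_that("group comparison is a Welch t-test with sane degenerate handling", {
  a <- tibble::tibble(cell_id = 1:10, mean_eccentricity = 0.5,
                      mean_mm_ratio = c(2, 3, 2.5, 2.2, 2.8, 3.1, 2.4, 2.6, 2.9, 2.3),
                      n_rois = 3L, group = "a")
  cmp_null <- compare_groups(a, dplyr::mutate(a, group = "b"))
  expect_equal(cmp_null$p_value[cmp_null$metric == "mm_ratio"], 1)
  expect_equal(cmp_null$mean_a, cmp_null$mean_b)
  set.seed(8)
  big <- tibble::tibble(cell_id = 1:60, mean_eccentricity = rnorm(60, 0.9, 0.05),
                        mean_mm_ratio = rnorm(60, 3, 0.5), n_rois = 3L, group = "a")
  small <- tibble::tibble(cell_id = 1:60, mean_eccentricity = rnorm(60, 0.6, 0.05),
                          mean_mm_ratio = rnorm(60, 1.5, 0.5), n_rois = 3L, group = "b")
  cmp <- compare_groups(big, small)
  expect_lt(cmp$p_value[cmp$metric == "mm_ratio"], 1e-6)
  expect_gt(cmp$t_statistic[cmp$metric == "mm_ratio"], 0)
  expect_error(compare_groups(a[1, ], small), "at least 2")
})

test_that("tighter rows never decrease the aligned cells' Mm ratio", {
  for (seed in c(2, 9)) {
    mm <- vapply(c(1.6, 0.8, 0.4), function(spread) {
      sim <- make_bb_image(n_cells = 6, frac_aligned = 1, row_spread = spread,
                           frame_shape = c(260, 260), seed = seed)
      mean(bb_alignment(sim$image, sim$mask)$cells$mean_mm_ratio)
    }, numeric(1))
    expect_true(all(diff(mm) > -0.1))
  }
})

test_that("aligned and non-aligned cells separate on the Mm-ratio scale", {
  sim <- make_bb_image(n_cells = 16, frac_aligned = 0.5,
                       frame_shape = c(320, 320), seed = 7)
  cells <- bb_alignment(sim$image, sim$mask)$cells |>
    dplyr::left_join(sim$ground_truth, by = "cell_id")
  mw <- stats::wilcox.test(mean_mm_ratio ~ aligned, data = cells,
                           alternative = "less", exact = FALSE)
  expect_lt(mw$p.value, 0.01)
  acc <- mean((cells$mean_mm_ratio >= 2) == cells$aligned)
  expect_gte(acc, 0.9)
})
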