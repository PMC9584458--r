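# Morphometry against analytic shapes, an independent region-properties
# implementation, and the bundled reference table.

disc_mask <- function(n, r, cy = n / 2, cx = n / 2) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

ellipse_mask_t <- function(n, a, b, rot = 0) {
  m <- matrix(FALSE, n, n)
  dy <- row(m) - n / 2; dx <- col(m) - n / 2
  u <- dx * cos(rot) + dy * sin(rot); v <- -dx * sin(rot) + dy * cos(rot)
  m[(u / a)^2 + (v / b)^2 <= 1] <- TRUE
  m
}

test_that("a digital disc measures as its analytic circle", {
  m <- disc_mask(128, 50)
  rec <- measure_cell(m, m, 0.1)
  expect_equal(rec$major_axis_um, 10, tolerance = 0.02)
  expect_equal(rec$minor_axis_um, 10, tolerance = 0.02)
  expect_equal(rec$cell_area_um2, pi * 25, tolerance = 0.02)
  expect_equal(rec$nucleus_area_um2, rec$cell_area_um2)   # nucleus = cell
})

test_that("axis ratio of a 2:1 ellipse is recovered within 2%", {
  m <- ellipse_mask_t(160, 60, 30)
  rec <- measure_cell(m, m, 1)
  expect_equal(rec$major_axis_um / rec$minor_axis_um, 2, tolerance = 0.02)
})

test_that("axes and area are rotation invariant within 2%", {
  vals <- sapply(c(0, 0.4, 0.9, 1.3), function(rot) {
    m <- ellipse_mask_t(160, 55, 35, rot)
    rec <- measure_cell(m, m, 1)
    c(rec$major_axis_um, rec$minor_axis_um, rec$cell_area_um2)
  })
  for (i in 1:3)
    expect_lt(diff(range(vals[i, ])) / mean(vals[i, ]), 0.02)
})

test_that("calibration scales axes linearly and areas quadratically", {
  m <- ellipse_mask_t(128, 40, 25, 0.7)
  r1 <- measure_cell(m, m, 0.1); r2 <- measure_cell(m, m, 0.2)
  expect_equal(r2$major_axis_um, 2 * r1$major_axis_um, tolerance = 1e-12)
  expect_equal(r2$minor_axis_um, 2 * r1$minor_axis_um, tolerance = 1e-12)
  expect_equal(r2$cell_area_um2, 4 * r1$cell_area_um2, tolerance = 1e-12)
})

test_that("axes agree with the independent region-moments implementation", {
  m <- ellipse_mask_t(150, 48, 29, 0.5)
  rec <- measure_cell(m, m, 1)
  ft <- EBImage::computeFeatures.moment(EBImage::Image(m * 1))
  expect_equal(rec$major_axis_um, unname(ft[1, "m.majoraxis"]),
               tolerance = 0.02)
  ecc <- unname(ft[1, "m.eccentricity"])
  minor_ebi <- unname(ft[1, "m.majoraxis"]) * sqrt(1 - ecc^2)
  expect_equal(rec$minor_axis_um, minor_ebi, tolerance = 0.02)
})

test_that("degenerate masks are rejected and nucleus is clipped to the cell", {
  m <- disc_mask(64, 20)
  expect_error(measure_cell(matrix(FALSE, 64, 64), m, 0.1), "empty")
  big_nuc <- matrix(TRUE, 64, 64)
  rec <- measure_cell(m, big_nuc, 0.1)
  expect_equal(rec$nucleus_area_um2, rec$cell_area_um2)
})

test_that("percent increase reproduces the reference discrimination figures", {
  expect_equal(percent_increase(mean(c(9.23, 9.17, 11.10)), 6.94), 41.69)
  expect_equal(percent_increase(59.11, 35.19), 67.97)
  expect_equal(percent_increase(10, 10), 0)
  expect_error(percent_increase(5, 0), "positive")
  expect_error(percent_increase(5, -1), "positive")
})

test_that("group comparison reproduces the reference cell-area increases", {
  ref <- reference_morphometry()
  nrm <- ref[ref$group == "normal" & ref$label == "lymphocyte", ]
  can <- ref[ref$group == "cancer", ]
  cmp <- compare_groups(nrm, can, "cell_area_um2")
  expect_equal(unname(cmp$per_cell), c(187.16, 67.97, 125.04))
  ax <- compare_groups(nrm, can, "minor_axis_um")
  expect_equal(ax$mean_increase, 32.97)
  maj <- compare_groups(nrm, can, "major_axis_um")
  expect_equal(maj$mean_increase, 41.69)
  same <- compare_groups(nrm, nrm, "cell_area_um2")
  expect_equal(unname(same$per_cell), 0)
  expect_error(compare_groups(nrm[0, ], can, "cell_area_um2"), "non-empty")
})

test_that("measured cancer lymphocytes come out larger than normal ones", {
  nrm <- one_cell_scene("lymphocyte", noise_sigma = 0, seed = 3)
  can <- one_cell_scene("lymphocyte", cancer = TRUE, noise_sigma = 0, seed = 3)
  rn <- measure_cell(nrm$cell_masks[[1]], nrm$nucleus_masks[[1]], 0.15)
  rc <- measure_cell(can$cell_masks[[1]], can$nucleus_masks[[1]], 0.15)
  inc <- percent_increase(rc$major_axis_um, rn$major_axis_um)
  expect_gt(inc, 30)   # built-in ~42% axis effect survives rasterization
  expect_gt(rc$cell_area_um2, rn$cell_area_um2)
})
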