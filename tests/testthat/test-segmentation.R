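# Segmentation stages against hand-built masks and synthetic ground truth.

test_that("green extraction stretches contrast and rejects non-RGB input", {
  g <- matrix(runif(64 * 64, 0.2, 0.8), 64)
  img <- array(0, c(64, 64, 3)); img[, , 2] <- g
  out <- extract_green_enhanced(img)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  # order preserved away from the clipped tails
  expect_gt(cor(as.vector(out), as.vector(g)), 0.99)
  # degenerate histogram passes through
  flat <- array(0.5, c(16, 16, 3))
  expect_equal(extract_green_enhanced(flat), matrix(0.5, 16, 16))
  expect_error(extract_green_enhanced(matrix(0.5, 16, 16)), "3-channel")
})

test_that("contrast stretching increases nucleus/background separation", {
  sc <- one_cell_scene("lymphocyte", noise_sigma = 0.01, seed = 4)
  raw <- sc$image[, , 2]
  enh <- extract_green_enhanced(sc$image)
  nuc <- sc$nucleus_masks[[1]]; bg <- !sc$cell_masks[[1]]
  expect_gt(michelson(enh, nuc, bg), michelson(raw, nuc, bg))
})

test_that("thresholding keeps the dark disc at 70% of the bright intensity", {
  gray <- matrix(0.9, 100, 100)
  disc <- (row(gray) - 50)^2 + (col(gray) - 50)^2 <= 20^2
  gray[disc] <- 0.3
  res <- binarize(gray, segmentation_config())
  expect_equal(res$i_b, 0.9, tolerance = 1e-6)
  expect_identical(res$mask, disc)   # brute-force pixel comparison
  # boundary setting: threshold_fraction 1 selects everything below I_B
  res1 <- binarize(gray, segmentation_config(threshold_fraction = 1))
  expect_identical(res1$mask, gray < res1$i_b)
  expect_error(binarize(matrix(0, 10, 10)), "constant zero")
})

test_that("mask cleaning removes small components and fills holes", {
  m <- matrix(FALSE, 300, 300)
  m[(row(m) - 150)^2 + (col(m) - 150)^2 <= 140^2] <- TRUE   # ~61k px blob
  blob_area <- sum(m)
  # five 100-px specks
  for (ctr in list(c(10, 10), c(10, 290), c(290, 10), c(290, 290), c(20, 150)))
    m[ctr[1] + 0:9, ctr[2] + 0:9] <- TRUE
  # a 500-px interior hole
  m[141:160, 141:165] <- FALSE
  cfg <- segmentation_config(min_component_px = 50000)
  out <- clean_mask(m, cfg)
  expect_equal(sum(out), blob_area)        # specks gone, hole refilled exactly
  expect_identical(clean_mask(out, cfg), out)   # idempotent
  expect_error(clean_mask(matrix(FALSE, 10, 10), cfg), "empty")
  expect_error(clean_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10), cfg), "below")
})

test_that("component labeling is 8-connected", {
  # two solid squares touching only at one corner count as a single region:
  # with 4-connectivity each 1600-px half would fall below the 2000-px cut
  m <- matrix(FALSE, 80, 80)
  m[1:40, 1:40] <- TRUE
  m[41:80, 41:80] <- TRUE
  out <- clean_mask(m, segmentation_config(min_component_px = 2000))
  expect_equal(sum(out), 3200)
})

test_that("Gaussian smoothing rounds corners but keeps interiors and planes", {
  cfg <- segmentation_config()
  ones <- matrix(TRUE, 40, 40)
  expect_identical(smooth_mask(ones, cfg), ones)
  # isolated pixel disappears: the window-15 kernel center weight is << 0.5
  single <- matrix(FALSE, 41, 41); single[21, 21] <- TRUE
  expect_false(any(smooth_mask(single, cfg)))
  # rectangle: corners shaved, deep interior untouched
  rect <- matrix(FALSE, 80, 80); rect[20:60, 15:65] <- TRUE
  sm <- smooth_mask(rect, cfg)
  expect_false(sm[20, 15])                    # corner rounded off
  expect_true(all(sm[28:52, 23:57]))          # >= 8 px inside the boundary
  # direct-convolution oracle on a row crossing the boundary
  k <- holocyte:::gaussian_kernel(cfg$gaussian_window)
  conv <- holocyte:::conv2_reflect(rect * 1, k)
  expect_identical(sm, conv >= 0.5)
})

test_that("Sobel edge maps outline masks with the printed kernels", {
  cfg <- segmentation_config()
  expect_false(any(detect_edges(matrix(TRUE, 20, 20), cfg)))
  expect_false(any(detect_edges(matrix(FALSE, 20, 20), cfg)))
  # single pixel: its 8 neighbors (and itself? no - center gradient is 0) fire
  single <- matrix(FALSE, 21, 21); single[11, 11] <- TRUE
  e <- detect_edges(single, cfg)
  expect_true(all(e[10:12, 10:12][-5]))
  expect_false(e[11, 11])
  expect_equal(sum(e), 8)
  # filled square: a closed band at most 2 px wide on each side
  sq <- matrix(FALSE, 40, 40); sq[10:30, 10:30] <- TRUE
  eb <- detect_edges(sq, cfg)
  expect_true(all(eb[9:10, 10:30]))           # band present along the top edge
  expect_false(any(eb[12:28, 12:28]))         # interior clean
  # hand-convolution along a vertical edge row: Gx = [-1 0 1; -2 0 2; -1 0 1]
  # at one pixel left of the edge sees sum 1+2+1 = 4
  gx <- holocyte:::conv2_reflect(sq * 1, cfg$sobel_gx)
  expect_equal(gx[20, 9], 4)
})

test_that("full pipeline recovers synthetic ground truth across kinds", {
  for (k in c("basophil", "eosinophil", "lymphocyte", "monocyte", "neutrophil")) {
    sc <- one_cell_scene(k, noise_sigma = 0, seed = 5)
    seg <- segment_wbc(sc$image, seg_small())
    expect_gte(jaccard(seg$cell_mask, sc$cell_masks[[1]]), 0.95)
    # exactly one connected component survives
    expect_equal(max(holocyte:::label_components8(seg$cell_mask)), 1)
  }
})

test_that("mask grows monotonically as the threshold fraction rises", {
  sc <- one_cell_scene("eosinophil", noise_sigma = 0.005, seed = 6)
  green <- extract_green_enhanced(sc$image)
  fractions <- c(0.5, 0.6, 0.7, 0.8)
  masks <- lapply(fractions, function(tf)
    binarize(green, segmentation_config(threshold_fraction = tf))$mask)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]),
                info = sprintf("mask(%.1f) not nested in mask(%.1f)",
                               fractions[i], fractions[i + 1]))
  }
  # the lower threshold keeps an area at most that of the higher threshold
  areas <- sapply(masks, sum)
  expect_true(all(diff(areas) >= 0))
})

test_that("background-only scenes raise a 'no cell' error with the stage name", {
  sc <- render_scene(list(), size = c(96, 96), noise_sigma = 0.005, seed = 2)
  expect_error(segment_wbc(sc$image, seg_small()), "clean|binarize")
})

test_that("ROI cropping returns masks in ROI coordinates", {
  sc <- render_scene(list(cell_spec("lymphocyte", center = c(60, 60),
                                    cell_axes = c(46, 42))),
                     size = c(160, 160), noise_sigma = 0, seed = 9)
  seg <- segment_wbc(sc$image, seg_small(), roi = c(21, 21, 80, 80))
  expect_equal(dim(seg$cell_mask), c(80, 80))
  expect_gte(jaccard(seg$cell_mask, sc$cell_masks[[1]][21:100, 21:100]), 0.95)
  expect_error(segment_wbc(sc$image, seg_small(), roi = c(140, 140, 80, 80)),
               "roi")
})
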