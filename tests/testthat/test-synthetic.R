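# Synthetic blood-film scenes: geometry, determinism, palette contrast,
# amplitude padding.

test_that("empty scene is background plus noise only", {
  sc <- render_scene(list(), size = c(64, 64), noise_sigma = 0, seed = 1)
  expect_length(sc$cell_masks, 0)
  pal <- wbc_palette()
  for (ch in 1:3) expect_true(all(sc$image[, , ch] == pal$background[ch]))
  sc2 <- render_scene(list(), size = c(64, 64), noise_sigma = 0.02, seed = 1)
  expect_gt(sd(sc2$image), 0)
})

test_that("ground-truth mask area matches the analytic ellipse", {
  sc <- render_scene(list(cell_spec("lymphocyte", center = c(64, 64),
                                    cell_axes = c(100, 100))),
                     size = c(128, 128), noise_sigma = 0, seed = 1)
  expect_equal(sum(sc$cell_masks[[1]]), pi * 50 * 50, tolerance = 0.01)
})

test_that("scenes are bit-identical under a fixed seed", {
  specs <- list(cell_spec("neutrophil", center = c(70, 64), rotation = 1.1))
  a <- render_scene(specs, size = c(128, 128), noise_sigma = 0.01, seed = 7,
                    um_per_px = 0.15)
  b <- render_scene(specs, size = c(128, 128), noise_sigma = 0.01, seed = 7,
                    um_per_px = 0.15)
  expect_identical(a$image, b$image)
  c <- render_scene(specs, size = c(128, 128), noise_sigma = 0.01, seed = 8,
                    um_per_px = 0.15)
  expect_false(identical(a$image, c$image))
})

test_that("overlapping or out-of-frame cells are rejected", {
  s1 <- cell_spec("lymphocyte", center = c(60, 60), cell_axes = c(40, 36))
  s2 <- cell_spec("lymphocyte", center = c(70, 70), cell_axes = c(40, 36))
  expect_error(render_scene(list(s1, s2), size = c(128, 128)), "overlap")
  s3 <- cell_spec("lymphocyte", center = c(10, 64), cell_axes = c(40, 36))
  expect_error(render_scene(list(s3), size = c(128, 128)), "fit")
})

test_that("nucleus shape follows the cell kind and stays inside the cell", {
  kinds <- c("basophil", "eosinophil", "lymphocyte", "monocyte", "neutrophil")
  shapes <- sapply(kinds, function(k) cell_spec(k, center = c(64, 64))$nucleus_shape)
  expect_equal(unname(shapes),
               c("bilobed", "bilobed", "round", "kidney", "multilobed"))
  expect_equal(cell_spec("lymphocyte", cancer = TRUE,
                         center = c(64, 64))$nucleus_shape, "irregular-oval")
  for (k in kinds) {
    sc <- one_cell_scene(k, noise_sigma = 0, seed = 2)
    expect_true(all(sc$cell_masks[[1]][sc$nucleus_masks[[1]]]),
                info = paste("nucleus escapes cell for", k))
    expect_gt(sum(sc$nucleus_masks[[1]]), 0)
  }
})

test_that("cancer lymphocytes are rendered larger by the reference ratios", {
  nrm <- one_cell_scene("lymphocyte", noise_sigma = 0, seed = 1)
  can <- one_cell_scene("lymphocyte", cancer = TRUE, noise_sigma = 0, seed = 1)
  ax_n <- nrm$specs[[1]]$cell_axes
  ax_c <- can$specs[[1]]$cell_axes
  expect_equal(ax_c[1] / ax_n[1], 1.42, tolerance = 1e-9)
  expect_equal(ax_c[2] / ax_n[2], 1.33, tolerance = 1e-9)
  expect_gt(sum(can$cell_masks[[1]]), sum(nrm$cell_masks[[1]]))
})

test_that("green channel separates nucleus from background best", {
  # the premise of green-channel segmentation, across kinds and seeds
  for (k in c("basophil", "lymphocyte", "monocyte")) {
    for (seed in 1:2) {
      sc <- one_cell_scene(k, noise_sigma = 0.01, seed = seed)
      nuc <- sc$nucleus_masks[[1]]; bg <- !sc$cell_masks[[1]]
      cons <- sapply(1:3, function(ch) michelson(sc$image[, , ch], nuc, bg))
      expect_equal(which.max(cons), 2L,
                   info = sprintf("kind %s seed %d", k, seed))
    }
  }
})

test_that("amplitude padding centers, normalizes and preserves energy", {
  cfg <- optical_config(slm_shape = c(32, 48))
  x <- matrix(runif(20 * 30), 20, 30)
  out <- render_amplitude_target(x, pad_factor = 4, cfg = cfg)
  expect_equal(dim(out), c(128, 192))
  expect_equal(sum(out), sum(x / max(x)), tolerance = 1e-12)   # zero frame adds nothing
  expect_equal(max(out), 1)
  # centered: the embedded block equals the normalized input
  r0 <- floor((128 - 20) / 2); c0 <- floor((192 - 30) / 2)
  expect_equal(out[r0 + 1:20, c0 + 1:30], x / max(x))
  # identity at pad_factor 1 with SLM-sized input
  y <- matrix(runif(32 * 48), 32, 48)
  expect_equal(render_amplitude_target(y, 1, cfg), y / max(y))
  # all-zero input passes through as all-zero
  expect_true(all(render_amplitude_target(matrix(0, 8, 8), 1, cfg) == 0))
  expect_error(render_amplitude_target(matrix(0, 300, 300), 1, cfg), "larger")
})

test_that("full-scale padding frame matches the SLM geometry", {
  cfg <- optical_config()
  x <- matrix(1, 1080, 1920)
  out <- render_amplitude_target(x[1:2, 1:2, drop = FALSE], 4, cfg)
  expect_equal(dim(out), c(4320, 7680))
})
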