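# Phase ramps, defocus chirps, hologram combination, selective refocus,
# amplitude annotation.

test_that("ramps and chirps are pure phase with the right identities", {
  cfg <- opt128
  expect_true(all(phase_ramp(cfg, 0, 0, c(32, 32)) == 1 + 0i))
  r <- phase_ramp(cfg, 0.01, -0.02, c(32, 32))
  expect_lt(max(abs(Mod(r) - 1)), 1e-12)
  expect_true(all(chirp(cfg, 0, c(32, 32)) == 1 + 0i))
  ch <- chirp(cfg, 0.3, c(32, 32))
  expect_lt(max(abs(Mod(ch) - 1)), 1e-12)
})

test_that("chirps compose additively in distance", {
  cfg <- opt128
  lhs <- chirp(cfg, 0.11, c(64, 64)) * chirp(cfg, 0.27, c(64, 64))
  expect_lt(max(Mod(lhs - chirp(cfg, 0.38, c(64, 64)))), 1e-10)
})

test_that("a ramp shifts the reconstruction by the shift-theorem pixel count", {
  cfg <- opt128
  n <- 128
  tg <- matrix(0, n, n); tg[55:70, 58:72] <- 1
  hol <- run_ifta(tg, ifta_exact(20, 4))$hologram
  base <- Mod(propagate_forward(exp(1i * hol$phase_rad)))^2
  for (px in c(5, 10, -8)) {
    alpha <- asin(px * cfg$wavelength_m / (n * cfg$slm_pitch_m))
    expect_equal(ramp_shift_px(cfg, alpha, n), px, tolerance = 1e-12)
    shifted <- Mod(propagate_forward(
      exp(1i * hol$phase_rad) * phase_ramp(cfg, alpha, 0, c(n, n))))^2
    # oracle: circular shift of the unramped reconstruction
    oracle <- base[((seq_len(n) - 1 - px) %% n) + 1, ]
    d_row <- sum(row(shifted) * shifted) / sum(shifted) -
             sum(row(base) * base) / sum(base)
    expect_lt(abs(d_row - px), 1)
    expect_gt(cor(as.vector(shifted), as.vector(oracle)), 0.99)
  }
})

test_that("component geometry constraints are enforced", {
  h <- phase_hologram(matrix(0, 16, 16))
  expect_error(modulation_component(h, 0, c(1e-3, 0)), "z = 0")
  expect_error(modulation_component(h, 1e-4, c(1, 0)), "<= 1")
  cm <- modulation_component(h, 0.2, c(0.1, -0.05))
  expect_equal(sin(cm$alpha), 0.5)
  expect_equal(sin(cm$beta), -0.25)
})

test_that("combining a single unmodulated component is the identity", {
  set.seed(3)
  ph <- matrix(runif(32 * 32, 0, 2 * pi), 32)
  h <- phase_hologram(ph)
  out <- combine_holograms(list(modulation_component(h, 0)), opt128)
  expect_equal(out$phase_rad, h$phase_rad, tolerance = 1e-10)
})

test_that("exactly cancelling components fall back to phase zero", {
  h1 <- phase_hologram(matrix(0, 8, 8))
  h2 <- phase_hologram(matrix(pi, 8, 8))
  out <- combine_holograms(list(modulation_component(h1, 0),
                                modulation_component(h2, 0)), opt128)
  expect_true(all(out$phase_rad == 0))
  expect_error(combine_holograms(list(
    modulation_component(h1, 0),
    modulation_component(phase_hologram(matrix(0, 4, 4)), 0)), opt128),
    "shape")
  expect_error(combine_holograms(list(), opt128), "at least one")
})

test_that("reconstruction at z = 0 is the plain Fourier reconstruction", {
  set.seed(8)
  ph <- matrix(runif(64 * 64, 0, 2 * pi), 64)
  h <- phase_hologram(ph)
  expect_equal(reconstruct_at(h, 0, opt128),
               Mod(propagate_forward(exp(1i * ph)))^2, tolerance = 1e-12)
})

test_that("two-component holograms refocus selectively along z", {
  cfg <- opt128
  n <- 128
  mk <- function(cy, cx, r) {
    m <- matrix(0, n, n)
    m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- 1
    m
  }
  t1 <- mk(64, 45, 14); t2 <- mk(64, 85, 14)
  h1 <- run_ifta(t1, ifta_exact(25, 1))$hologram
  h2 <- run_ifta(t2, ifta_exact(25, 2))$hologram
  zs <- c(0, 0.3)
  comb <- combine_holograms(list(modulation_component(h1, zs[1]),
                                 modulation_component(h2, zs[2])), cfg)
  rois <- list(r1 = mk(64, 45, 16) > 0.5, r2 = mk(64, 85, 16) > 0.5)
  scan <- seq(-0.15, 0.45, length.out = 13)   # includes 0 and 0.3
  fs <- focal_stack(comb, scan, cfg, rois)
  expect_equal(unname(fs$best_z), zs, tolerance = 1e-9)
  # away from its own plane, a component's ROI is strictly less sharp
  i0 <- which(scan == 0); i3 <- which(abs(scan - 0.3) < 1e-9)
  expect_lt(fs$focus_scores[i3, "r1"], fs$focus_scores[i0, "r1"])
  expect_lt(fs$focus_scores[i0, "r2"], fs$focus_scores[i3, "r2"])
})

test_that("annotation stamps legible labels into the reconstruction", {
  amp <- matrix(0, 128, 128); amp[40:90, 30:100] <- 0.6
  expect_identical(annotate_target(amp, list())$amplitude, amp)
  an <- annotate_target(amp, list(list(text = "N", pos = c(50, 45), scale = 3),
                                  list(text = "C", pos = c(50, 70), scale = 3)))
  expect_true(all(an$amplitude[an$stencil] == max(amp, 1)))
  expect_error(annotate_target(amp, list(list(text = "N", pos = c(126, 126)))),
               "fit")
  expect_error(annotate_target(amp, list(list(text = "~", pos = c(5, 5)))),
               "glyph")
  # end to end: the labels survive hologram synthesis and reconstruction
  res <- run_ifta(an$amplitude, ifta_exact(40, 9))
  rec <- res$reconstruction
  thr <- rec > 0.5 * stats::median(rec[an$stencil])
  idx <- which(an$stencil, arr.ind = TRUE)
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  pred <- thr[rows[1]:rows[2], cols[1]:cols[2]]
  truth <- an$stencil[rows[1]:rows[2], cols[1]:cols[2]]
  expect_gte(jaccard(pred, truth), 0.5)
})
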