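# Shared fixtures: scaled-down optical configs and synthetic scenes.
# Desk-scale tests use a 128 x 128 "SLM" so a padded hologram is 512 x 512.

opt128 <- optical_config(slm_shape = c(128L, 128L))
seg_small <- function(...) segmentation_config(min_component_px = 300L, ...)

# One-cell scene centered in a 128 x 128 frame (0.15 um/px keeps the default
# cell sizes inside the frame).
one_cell_scene <- function(kind, cancer = FALSE, noise_sigma = 0.005,
                           seed = 3, rotation = 0.3, size = c(128L, 128L),
                           um_per_px = 0.15, ...) {
  render_scene(list(cell_spec(kind, cancer = cancer,
                              center = size / 2, rotation = rotation, ...)),
               size = size, noise_sigma = noise_sigma, seed = seed,
               um_per_px = um_per_px)
}

# Stained-cell amplitude target of SLM shape, as the pipeline builds it.
cell_amplitude_target <- function(kind, cancer = FALSE, seed = 3) {
  sc <- one_cell_scene(kind, cancer = cancer, seed = seed)
  seg <- segment_wbc(sc$image, seg_small())
  (1 - seg$green_enhanced) * seg$cell_mask
}

# Uniform bright disc target (structure-free speckle test object).
disc_target <- function(n = 192, radius = n / 4) {
  m <- matrix(0, n, n)
  m[(row(m) - n / 2)^2 + (col(m) - n / 2)^2 <= radius^2] <- 1
  m
}

# Unconstrained-convergence optimizer settings (fixed iteration count).
ifta_exact <- function(iters, seed) {
  ifta_config(max_iterations = iters, epsilon_rad = 0, error_floor = 0,
              seed = seed)
}

# Michelson contrast between the mean intensities of two regions.
michelson <- function(img_channel, region_a, region_b) {
  a <- mean(img_channel[region_a]); b <- mean(img_channel[region_b])
  abs(a - b) / (a + b)
}
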