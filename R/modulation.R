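# Multi-plane hologram modulation: per-component phase ramps (lateral
# shift) and quadratic chirps (axial shift), complex summation into one
# phase-only hologram, and focal-stack reconstruction with selective focus.
#
# Coordinate conventions. The SLM plane carries two grids derived from an
# optical_config: the metric grid `nu = (index - center) * slm_pitch`
# (meters), used by the phase ramp exp(i*k*(sin(a)*nu_i + sin(b)*nu_j)),
# and the spatial-frequency grid `f = nu / (lambda * focal_length)`
# (cycles/m at the reconstruction plane; in the Fourier-lens geometry the
# SLM plane *is* the frequency plane of the back focal plane). The defocus
# chirp is the paraxial angular-spectrum transfer function
# exp(i*pi*lambda*z*|f|^2) on that frequency grid, which makes z the
# refocusing distance in meters: reconstructing with chirp(-z) cancels the
# chirp of components placed at z and defocuses the others. Desk-scale
# grids stay alias-free for z up to about lambda*f^2/(2*x_max*pitch).

slm_coords <- function(cfg, shape = cfg$slm_shape) {
  iy <- seq_len(shape[1]) - 1 - floor(shape[1] / 2)
  ix <- seq_len(shape[2]) - 1 - floor(shape[2] / 2)
  list(nu_i = matrix(iy, shape[1], shape[2]) * cfg$slm_pitch_m,
       nu_j = matrix(ix, shape[1], shape[2], byrow = TRUE) * cfg$slm_pitch_m)
}

#' Linear phase ramp (SLM tilt)
#'
#' Unit-modulus field `exp(i*k*(sin(alpha)*nu_i + sin(beta)*nu_j))` with
#' `k = 2*pi/lambda` on the metric SLM grid. Equivalent to tilting the SLM;
#' by the Fourier shift theorem it translates the reconstruction by
#' `sin(alpha) * n * pitch / lambda` pixels along each axis (see
#' [ramp_shift_px()]).
#'
#' @param cfg an [optical_config()].
#' @param alpha,beta tilt angles (radians) along the row and column axes.
#' @param shape grid shape, default the SLM shape.
#' @return complex matrix of modulus 1.
#' @export
phase_ramp <- function(cfg, alpha, beta, shape = cfg$slm_shape) {
  g <- slm_coords(cfg, shape)
  k <- 2 * pi / cfg$wavelength_m
  exp(1i * k * (sin(alpha) * g$nu_i + sin(beta) * g$nu_j))
}

#' Predicted reconstruction-pixel shift of a phase ramp
#'
#' Discrete Fourier shift theorem: a ramp of tilt `alpha` over an `n`-sample
#' axis of pitch `p` moves the reconstruction by `n * p * sin(alpha) /
#' lambda` pixels along that axis.
#'
#' @inheritParams phase_ramp
#' @param n samples along the axis.
#' @return shift in reconstruction pixels (signed, generally fractional).
#' @export
ramp_shift_px <- function(cfg, alpha, n) {
  n * cfg$slm_pitch_m * sin(alpha) / cfg$wavelength_m
}

#' Quadratic defocus chirp
#'
#' Pure-phase propagation transfer function
#' `exp(i*pi*lambda*z*|f|^2)` evaluated on the SLM's spatial-frequency grid
#' `f = nu / (lambda * focal_length)`. `z = 0` gives the identity field and
#' chirps compose additively: `chirp(z1) * chirp(z2) = chirp(z1 + z2)`.
#'
#' @inheritParams phase_ramp
#' @param z propagation (refocus) distance in meters.
#' @return complex matrix of modulus 1.
#' @export
chirp <- function(cfg, z, shape = cfg$slm_shape) {
  g <- slm_coords(cfg, shape)
  lf <- cfg$wavelength_m * cfg$focal_length_m
  f2 <- (g$nu_i / lf)^2 + (g$nu_j / lf)^2
  exp(1i * pi * cfg$wavelength_m * z * f2)
}

#' Describe one modulated hologram component
#'
#' Attaches an axial distance and a lateral shift to a component hologram.
#' The tilt angles follow from the shift geometry: `sin(alpha) = du_i / z`,
#' `sin(beta) = du_j / z`. A component at `z = 0` cannot be shifted.
#'
#' @param hologram a [phase_hologram()] (or phase matrix).
#' @param z_m axial propagation distance in meters.
#' @param shift_u lateral shift `c(du_i, du_j)` at the reconstruction plane,
#'   meters.
#' @return list of class `modulation_component` with derived `alpha`, `beta`.
#' @export
modulation_component <- function(hologram, z_m = 0, shift_u = c(0, 0)) {
  if (!inherits(hologram, "phase_hologram")) hologram <- phase_hologram(hologram)
  stopifnot(length(shift_u) == 2)
  if (z_m == 0) {
    if (any(shift_u != 0)) stop("a component at z = 0 cannot carry a lateral shift")
    alpha <- beta <- 0
  } else {
    s <- shift_u / z_m
    if (any(abs(s) > 1)) stop("|shift/z| must be <= 1 (sin of a tilt angle)")
    alpha <- asin(s[1]); beta <- asin(s[2])
  }
  structure(list(hologram = hologram, z_m = z_m, shift_u = as.numeric(shift_u),
                 alpha = alpha, beta = beta),
            class = "modulation_component")
}

#' Combine modulated components into a single phase hologram
#'
#' Each component's unit field `exp(i*phi_m)` is multiplied by its phase
#' ramp and defocus chirp, the complex fields are summed pointwise, and the
#' argument of the sum (wrapped to `[0, 2*pi)`) becomes the single hologram
#' to display. Pixels where the sum is exactly zero get phase 0.
#'
#' @param components list of [modulation_component()] objects (>= 1), all of
#'   the same shape.
#' @param cfg an [optical_config()].
#' @return a [phase_hologram()].
#' @export
combine_holograms <- function(components, cfg = optical_config()) {
  if (length(components) < 1) stop("at least one component is required")
  for (cm in components) if (!inherits(cm, "modulation_component"))
    stop("components must be modulation_component objects")
  shp <- components[[1]]$hologram$shape
  acc <- matrix(0 + 0i, shp[1], shp[2])
  for (cm in components) {
    if (!identical(cm$hologram$shape, shp)) stop("component holograms differ in shape")
    u <- exp(1i * cm$hologram$phase_rad)
    if (cm$alpha != 0 || cm$beta != 0)
      u <- u * phase_ramp(cfg, cm$alpha, cm$beta, shp)
    if (cm$z_m != 0)
      u <- u * chirp(cfg, cm$z_m, shp)
    acc <- acc + u
  }
  ph <- Arg(acc)
  # numerically zero sums carry no usable phase; pin them to 0
  ph[Mod(acc) < 1e-9 * length(components)] <- 0
  phase_hologram(ph)
}

#' Reconstruct a hologram at an axial distance
#'
#' Intensity `|F(exp(i*phi) * chirp(-z))|^2`: multiplying by the opposite
#' chirp cancels the defocus of components placed at `z`, bringing them into
#' focus while components at other distances blur.
#'
#' @param hologram a [phase_hologram()] (or phase matrix).
#' @param z refocus distance in meters.
#' @param cfg an [optical_config()].
#' @return intensity matrix.
#' @export
reconstruct_at <- function(hologram, z = 0, cfg = optical_config()) {
  phase <- if (inherits(hologram, "phase_hologram")) hologram$phase_rad else hologram
  field <- exp(1i * phase)
  if (z != 0) field <- field * chirp(cfg, -z, dim(field))
  Mod(propagate_forward(field))^2
}

#' Sharpness of a region of interest
#'
#' Variance of the Sobel gradient magnitude inside the ROI, computed on a
#' Gaussian-smoothed copy of the intensity (`sigma = 2` px by default; the
#' smoothing suppresses speckle gradients which otherwise dominate the
#' score).
#'
#' @param intensity reconstruction intensity matrix.
#' @param roi logical matrix selecting the region.
#' @param smooth_sigma Gaussian sigma in pixels (0 disables smoothing).
#' @return non-negative sharpness score.
#' @export
focus_score <- function(intensity, roi, smooth_sigma = 2) {
  stopifnot(is.matrix(intensity), is.logical(roi))
  assert_same_shape(intensity, roi, "intensity and roi")
  if (!any(roi)) stop("empty ROI")
  stats::var(sharpness_map(intensity, smooth_sigma)[roi])
}

# Smoothed Sobel gradient magnitude, shared by focus_score and focal_stack.
sharpness_map <- function(intensity, smooth_sigma = 2) {
  if (smooth_sigma > 0) {
    w <- 2 * ceiling(2 * smooth_sigma) + 1
    intensity <- conv2_reflect(intensity, gaussian_kernel(w, smooth_sigma))
  }
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  sy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, byrow = TRUE)
  sqrt(conv2_reflect(intensity, sx)^2 + conv2_reflect(intensity, sy)^2)
}

#' Reconstruct a focal stack and score per-ROI sharpness
#'
#' Scans the refocus distance over `zs`, reconstructing the hologram at each
#' plane and scoring every ROI with [focus_score()]. For a combined
#' multi-component hologram, each component's ROI peaks at that component's
#' own `z_m` - the selective-focus display that separates cell structures
#' (or a normal from a cancer cell) in depth.
#'
#' @param hologram a [phase_hologram()].
#' @param zs numeric vector of refocus distances (meters).
#' @param cfg an [optical_config()].
#' @param rois named list of logical ROI masks.
#' @return list of class `focal_stack`: `zs`, `planes` (intensities),
#'   `focus_scores` (matrix planes x ROIs), `best_z` (per-ROI argmax).
#' @export
focal_stack <- function(hologram, zs, cfg = optical_config(), rois = list()) {
  planes <- lapply(zs, function(z) reconstruct_at(hologram, z, cfg))
  scores <- NULL
  best <- NULL
  if (length(rois)) {
    maps <- lapply(planes, sharpness_map)
    scores <- sapply(rois, function(roi)
      vapply(maps, function(g) stats::var(g[roi]), numeric(1)))
    scores <- matrix(scores, nrow = length(zs),
                     dimnames = list(NULL, names(rois)))
    best <- zs[apply(scores, 2, which.max)]
    names(best) <- colnames(scores)
  }
  structure(list(zs = zs, planes = planes, focus_scores = scores, best_z = best),
            class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  cat(sprintf("Focal stack: %d planes, z in [%.3g, %.3g] m\n",
              length(x$zs), min(x$zs), max(x$zs)))
  if (!is.null(x$best_z))
    for (nm in names(x$best_z))
      cat(sprintf("  ROI %s sharpest at z = %.3g m\n", nm, x$best_z[nm]))
  invisible(x)
}

# --- amplitude annotation ----------------------------------------------------

# 5x7 bitmap glyphs (columns of a 5-wide, 7-tall raster, row-major strings).
.glyphs <- local({
  g <- list(
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "C" = c("01110","10001","10000","10000","10000","10001","01110"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00010","00100","01000","11111"),
    "3" = c("11110","00001","00001","01110","00001","00001","11110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("01110","10000","11110","10001","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00001","01110"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    ":" = c("00000","01100","01100","00000","01100","01100","00000"),
    " " = c("00000","00000","00000","00000","00000","00000","00000")
  )
  lapply(g, function(rows) {
    do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  })
})

# Rasterize text into a 0/1 matrix at an integer scale.
render_text_stencil <- function(text, scale = 1) {
  chars <- strsplit(toupper(text), "")[[1]]
  unknown <- setdiff(chars, names(.glyphs))
  if (length(unknown))
    stop(sprintf("no glyph for character(s): %s", paste(unique(unknown), collapse = " ")))
  cols <- lapply(chars, function(ch) cbind(.glyphs[[ch]], matrix(0L, 7, 1)))
  m <- do.call(cbind, cols)
  m <- m[, seq_len(ncol(m) - 1), drop = FALSE]   # drop trailing gap
  if (scale > 1) m <- m[rep(seq_len(nrow(m)), each = scale),
                        rep(seq_len(ncol(m)), each = scale), drop = FALSE]
  m
}

#' Stamp text labels into an amplitude target
#'
#' Renders bitmap text (A/C/E/L/N/O/S/U, digits, '.', ':') at maximum
#' amplitude into the target before hologram synthesis, so cell names and
#' measured characteristics appear in the reconstruction itself.
#'
#' @param amplitude numeric matrix.
#' @param labels list of `list(text =, pos = c(row, col), scale =)` entries
#'   (`scale` optional, integer); `pos` is the top-left corner of the text
#'   block. An empty list returns the amplitude unchanged.
#' @return list: `amplitude` (labeled) and `stencil` (logical matrix of the
#'   labeled pixels).
#' @export
annotate_target <- function(amplitude, labels = list()) {
  stopifnot(is.matrix(amplitude))
  stencil <- matrix(FALSE, nrow(amplitude), ncol(amplitude))
  for (lb in labels) {
    m <- render_text_stencil(lb$text, lb$scale %||% 1)
    r0 <- lb$pos[1]; c0 <- lb$pos[2]
    if (r0 < 1 || c0 < 1 || r0 + nrow(m) - 1 > nrow(amplitude) ||
        c0 + ncol(m) - 1 > ncol(amplitude))
      stop(sprintf("label '%s' does not fit in the frame", lb$text))
    block <- stencil[r0 + seq_len(nrow(m)) - 1, c0 + seq_len(ncol(m)) - 1]
    stencil[r0 + seq_len(nrow(m)) - 1, c0 + seq_len(ncol(m)) - 1] <- block | (m > 0)
  }
  amp <- amplitude
  if (any(stencil)) amp[stencil] <- max(amplitude, 1)
  list(amplitude = amp, stencil = stencil)
}
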