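# Synthetic stained-blood-film scenes with exact ground truth.
#
# Emulates the appearance of Romanowsky-stained white blood cells under a
# bright-field microscope: near-white background, pink cytoplasm, dark
# purple nucleus, optional granules. The palette is chosen so the green
# channel carries the strongest nucleus/background contrast, which is the
# premise of the thresholding segmentation. Ground-truth masks are exact
# ellipse rasterizations, so segmentation accuracy can be scored without
# any annotated microscope data.

.wbc_kinds <- c("basophil", "eosinophil", "lymphocyte", "monocyte", "neutrophil")
.nucleus_shapes <- c("round", "bilobed", "multilobed", "kidney", "irregular-oval")

# Per-kind morphology defaults: nucleus lobation and granularity follow the
# classic hematology picture (basophil/eosinophil bilobed, neutrophil
# 4-lobed, monocyte kidney-shaped, lymphocyte round); default sizes derive
# from the bundled reference morphometry (micrometres, converted at render
# time through the scene calibration).
.kind_defaults <- list(
  basophil   = list(shape = "bilobed", lobes = 2L, gran = 0.5,
                    axes_um = c(10.22, 9.57), nuc_frac = 29.01 / 76.60),
  eosinophil = list(shape = "bilobed", lobes = 2L, gran = 0.7,
                    axes_um = c(12.76, 11.74), nuc_frac = 31.72 / 117.48),
  lymphocyte = list(shape = "round", lobes = 1L, gran = 0,
                    axes_um = c(6.94, 6.48), nuc_frac = 1.0),
  monocyte   = list(shape = "kidney", lobes = 1L, gran = 0,
                    axes_um = c(12.00, 9.66), nuc_frac = 84.39 / 89.18),
  neutrophil = list(shape = "multilobed", lobes = 4L, gran = 0.3,
                    axes_um = c(16.26, 11.15), nuc_frac = 50.70 / 141.86)
)

# Axis scaling applied to cancer lymphocytes: the mean major/minor axis
# ratios between the cancer and normal lymphocytes of the reference
# morphometry (about 1.42 and 1.33), so rendered cancer cells carry the
# documented size effect by construction.
.cancer_axis_scale <- c(1.42, 1.33)

#' Stain palette of the synthetic scenes
#'
#' RGB triples in `[0, 1]` for the background, cytoplasm and nucleus, plus
#' the granule modulation depth. The defaults make the green channel the
#' most discriminative one between nucleus and background (Michelson
#' contrast), mirroring real Romanowsky staining.
#'
#' @param background,cytoplasm,nucleus RGB triples.
#' @param granule_delta absolute intensity modulation of granules.
#' @export
wbc_palette <- function(background = c(0.95, 0.93, 0.90),
                        cytoplasm = c(0.95, 0.65, 0.75),
                        nucleus = c(0.45, 0.20, 0.55),
                        granule_delta = 0.15) {
  stopifnot(length(background) == 3, length(cytoplasm) == 3, length(nucleus) == 3)
  list(background = background, cytoplasm = cytoplasm, nucleus = nucleus,
       granule_delta = granule_delta)
}

#' Specify one synthetic white blood cell
#'
#' @param kind one of `"basophil"`, `"eosinophil"`, `"lymphocyte"`,
#'   `"monocyte"`, `"neutrophil"`.
#' @param cancer logical; cancer lymphocytes get an irregular oval nucleus
#'   and axes scaled by the reference cancer/normal ratios (~1.42 major,
#'   ~1.33 minor).
#' @param center cell center as `c(row, col)` pixels.
#' @param cell_axes full major/minor axis lengths in pixels
#'   (`c(major, minor)`); `NULL` resolves the per-kind default through the
#'   scene calibration at render time.
#' @param nucleus_lobes integer lobe count; default per kind.
#' @param nucleus_shape one of `"round"`, `"bilobed"`, `"multilobed"`,
#'   `"kidney"`, `"irregular-oval"`; default per kind (cancer lymphocyte:
#'   irregular oval).
#' @param granularity granule density in `[0, 1]`; default per kind.
#' @param rotation major-axis rotation in radians.
#' @return list of class `cell_spec`.
#' @examples
#' cell_spec("lymphocyte", center = c(64, 64), cell_axes = c(40, 36))
#' @export
cell_spec <- function(kind, cancer = FALSE, center, cell_axes = NULL,
                      nucleus_lobes = NULL, nucleus_shape = NULL,
                      granularity = NULL, rotation = 0) {
  kind <- match.arg(kind, .wbc_kinds)
  kd <- .kind_defaults[[kind]]
  if (is.null(nucleus_shape))
    nucleus_shape <- if (cancer && kind == "lymphocyte") "irregular-oval" else kd$shape
  nucleus_shape <- match.arg(nucleus_shape, .nucleus_shapes)
  nucleus_lobes <- as.integer(nucleus_lobes %||% kd$lobes)
  granularity <- granularity %||% kd$gran
  stopifnot(length(center) == 2, granularity >= 0, granularity <= 1,
            nucleus_lobes >= 1)
  if (!is.null(cell_axes)) {
    stopifnot(length(cell_axes) == 2)
    if (!(cell_axes[1] >= cell_axes[2] && cell_axes[2] > 0))
      stop("cell_axes must satisfy major >= minor > 0")
  }
  structure(list(kind = kind, cancer = isTRUE(cancer), center = as.numeric(center),
                 cell_axes = cell_axes, nucleus_lobes = nucleus_lobes,
                 nucleus_shape = nucleus_shape, granularity = granularity,
                 rotation = rotation),
            class = "cell_spec")
}

# Rasterize a rotated filled ellipse; center (row, col), axes = full lengths.
ellipse_mask <- function(size, center, axes, rotation = 0) {
  a <- axes[1] / 2; b <- axes[2] / 2
  dy <- matrix(seq_len(size[1]) - center[1], size[1], size[2])
  dx <- matrix(seq_len(size[2]) - center[2], size[1], size[2], byrow = TRUE)
  u <- dx * cos(rotation) + dy * sin(rotation)
  v <- -dx * sin(rotation) + dy * cos(rotation)
  (u / a)^2 + (v / b)^2 <= 1
}

# Nucleus rasterization per shape; returns a logical mask, later clipped to
# the cell. Multi-lobed nuclei are unions of overlapping ellipses (the
# morphology literature gives lobe counts, not exact geometry).
nucleus_mask_for <- function(spec, size, axes) {
  ctr <- spec$center; rot <- spec$rotation
  a <- axes[1] / 2
  sc <- sqrt(.kind_defaults[[spec$kind]]$nuc_frac)
  along <- function(dist, ang = 0) {
    th <- rot + ang
    ctr + dist * a * c(sin(th), cos(th))  # (row, col) step along rotated axis
  }
  switch(spec$nucleus_shape,
    "round" = ellipse_mask(size, ctr, axes * sc, rot),
    "bilobed" = {
      lob <- axes * sc * 0.72
      ellipse_mask(size, along(0.40), lob, rot) |
        ellipse_mask(size, along(-0.40), lob, rot)
    },
    "multilobed" = {
      k <- max(spec$nucleus_lobes, 2L)
      lob <- axes * sc * (1.45 / sqrt(k))
      m <- matrix(FALSE, size[1], size[2])
      for (i in seq_len(k))
        m <- m | ellipse_mask(size, along(0.42, ang = 2 * pi * (i - 1) / k), lob, rot)
      m
    },
    "kidney" = {
      body <- ellipse_mask(size, ctr, axes * 0.92, rot)
      bite <- ellipse_mask(size, along(0.55, ang = pi / 2), axes * 0.55, rot)
      body & !bite
    },
    "irregular-oval" = {
      dy <- matrix(seq_len(size[1]) - ctr[1], size[1], size[2])
      dx <- matrix(seq_len(size[2]) - ctr[2], size[1], size[2], byrow = TRUE)
      u <- dx * cos(rot) + dy * sin(rot)
      v <- -dx * sin(rot) + dy * cos(rot)
      th <- atan2(v, u)
      r <- 1 + 0.18 * sin(3 * th + 1) + 0.12 * cos(5 * th)
      sa <- axes[1] / 2 * 0.85; sb <- axes[2] / 2 * 0.85
      (u / sa)^2 + (v / sb)^2 <= r^2
    })
}

resolve_axes <- function(spec, um_per_px) {
  if (!is.null(spec$cell_axes)) return(as.numeric(spec$cell_axes))
  ax <- .kind_defaults[[spec$kind]]$axes_um / um_per_px
  if (spec$cancer && spec$kind == "lymphocyte") ax <- ax * .cancer_axis_scale
  ax
}

#' Render a synthetic stained blood-film scene
#'
#' Rasterizes the requested cells onto a bright background, with pink
#' cytoplasm, dark purple nucleus, granule speckles and additive Gaussian
#' noise (clipped to `[0, 1]`). Ground-truth cell and nucleus masks are
#' returned per cell. Overlapping cells and cells touching the frame border
#' are rejected, so the ground truth is always unambiguous.
#'
#' @param specs list of [cell_spec()] objects (may be empty).
#' @param size image size `c(H, W)`, at least 64 x 64.
#' @param noise_sigma standard deviation of the additive Gaussian intensity
#'   noise (in `[0, 1]` units).
#' @param seed integer seed; the same specs and seed give a bit-identical
#'   scene.
#' @param um_per_px calibration of the scene in micrometres per pixel. The
#'   microscope magnification of the emulated films is not part of the image
#'   files, so synthetic scenes declare their own calibration explicitly.
#' @param palette a [wbc_palette()].
#' @return list of class `wbc_scene`: `image` (H x W x 3 array),
#'   `cell_masks`, `nucleus_masks` (lists of logical matrices), `specs`
#'   (with resolved axes), `noise_sigma`, `seed`, `um_per_px`.
#' @examples
#' sc <- render_scene(list(cell_spec("lymphocyte", center = c(64, 64),
#'                                   cell_axes = c(50, 44))),
#'                    size = c(128, 128), noise_sigma = 0, seed = 1)
#' sum(sc$cell_masks[[1]])
#' @export
render_scene <- function(specs, size = c(256L, 256L), noise_sigma = 0.01,
                         seed = 1L, um_per_px = 0.1, palette = wbc_palette()) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 64)) stop("size must be at least 64 x 64")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (!is.list(specs)) stop("specs must be a list of cell_spec objects")
  for (s in specs) if (!inherits(s, "cell_spec")) stop("specs must be cell_spec objects")

  cell_masks <- list(); nucleus_masks <- list(); resolved <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ax <- resolve_axes(sp, um_per_px)
    sp$cell_axes <- ax
    cm <- ellipse_mask(size, sp$center, ax, sp$rotation)
    if (!any(cm)) stop(sprintf("cell %d rasterizes to an empty mask", i))
    if (any(cm[c(1, size[1]), ]) || any(cm[, c(1, size[2])]))
      stop(sprintf("cell %d does not fit inside the frame", i))
    nm <- nucleus_mask_for(sp, size, ax) & cm
    cell_masks[[i]] <- cm
    nucleus_masks[[i]] <- nm
    resolved[[i]] <- sp
  }
  if (length(cell_masks) > 1) {
    acc <- matrix(FALSE, size[1], size[2])
    for (i in seq_along(cell_masks)) {
      if (any(acc & cell_masks[[i]]))
        stop(sprintf("cell %d overlaps a previously placed cell", i))
      acc <- acc | cell_masks[[i]]
    }
  }

  img <- with_seed(seed, {
    im <- array(rep(palette$background, each = prod(size)), c(size, 3))
    for (i in seq_along(resolved)) {
      sp <- resolved[[i]]
      cm <- cell_masks[[i]]; nm <- nucleus_masks[[i]]
      cyto <- cm & !nm
      for (ch in 1:3) {
        pl <- im[, , ch]
        pl[cyto] <- palette$cytoplasm[ch]
        pl[nm] <- palette$nucleus[ch]
        im[, , ch] <- pl
      }
      if (sp$granularity > 0 && any(cyto)) {
        idx <- which(cyto)
        n_gran <- round(sp$granularity * length(idx) / 30)
        if (n_gran > 0) {
          pick <- sample(idx, min(n_gran, length(idx)))
          sgn <- ifelse(stats::runif(length(pick)) < 0.7, -1, 1)
          for (ch in 1:3) {
            pl <- im[, , ch]
            pl[pick] <- pl[pick] + sgn * palette$granule_delta
            im[, , ch] <- pl
          }
        }
      }
    }
    if (noise_sigma > 0)
      im <- im + array(stats::rnorm(length(im), 0, noise_sigma), dim(im))
    array(clamp01(im), dim(im))
  })

  structure(list(image = img, cell_masks = cell_masks,
                 nucleus_masks = nucleus_masks, specs = resolved,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 um_per_px = um_per_px),
            class = "wbc_scene")
}

#' @export
print.wbc_scene <- function(x, ...) {
  cat(sprintf("Synthetic blood-film scene %d x %d, %d cell(s), noise sigma %.3g, %.3g um/px\n",
              dim(x$image)[1], dim(x$image)[2], length(x$specs),
              x$noise_sigma, x$um_per_px))
  for (s in x$specs)
    cat(sprintf("  - %s%s at (%.0f, %.0f), axes %.0f x %.0f px\n",
                s$kind, if (s$cancer) " (cancer)" else "",
                s$center[1], s$center[2], s$cell_axes[1], s$cell_axes[2]))
  invisible(x)
}

#' Embed an image in a zero-padded SLM-scale amplitude frame
#'
#' Centers the input in a dark frame whose height and width are
#' `pad_factor` times the SLM window, and normalizes values to `[0, 1]`.
#' Padding the hologram optimizer's target this way is the first step of the
#' temporal-multiplexing speckle reduction: the extended hologram is later
#' cut into SLM-sized tiles. Zero padding adds no energy, and with
#' `pad_factor = 1` and an SLM-sized input the (normalized) input is
#' returned unchanged.
#'
#' @param x numeric matrix (e.g. a masked cell image) or logical mask.
#' @param pad_factor integer >= 1; 4 gives the 7680 x 4320 frame for the
#'   full-size SLM.
#' @param cfg an [optical_config()]; its `slm_shape` sets the frame size.
#' @return numeric matrix of size `pad_factor * slm_shape`.
#' @export
render_amplitude_target <- function(x, pad_factor = 4L, cfg = optical_config()) {
  if (is.logical(x)) x <- x * 1
  stopifnot(is.matrix(x))
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1) stop("pad_factor must be >= 1")
  out_dim <- pad_factor * cfg$slm_shape
  if (nrow(x) > out_dim[1] || ncol(x) > out_dim[2])
    stop(sprintf("input (%dx%d) larger than the padded frame (%dx%d)",
                 nrow(x), ncol(x), out_dim[1], out_dim[2]))
  mx <- max(x)
  if (mx > 0) x <- x / mx
  out <- matrix(0, out_dim[1], out_dim[2])
  r0 <- floor((out_dim[1] - nrow(x)) / 2)
  c0 <- floor((out_dim[2] - ncol(x)) / 2)
  out[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))] <- x
  out
}
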