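# Threshold-based extraction of a white blood cell from a stained
# blood-film image: green channel -> contrast stretch -> threshold at a
# fraction of the bright-area intensity -> component cleaning -> Gaussian
# edge smoothing -> Sobel edge map.

#' Segmentation settings
#'
#' @param threshold_fraction fraction of the bright-area intensity `I_B`
#'   below which a pixel is foreground (stained cells are darker than the
#'   background). 0.70 satisfies most cases: higher values start to discard
#'   parts of the cell, below 0.60 the mask grows past the cell.
#' @param bright_percentile percentile of the enhanced green image that
#'   defines `I_B` (99 is robust to hot pixels).
#' @param min_component_px connected components smaller than this are
#'   dropped. The default 50000 suits full-resolution microscope frames;
#'   scaled-down synthetic scenes must scale it accordingly.
#' @param gaussian_window odd window side of the mask-smoothing Gaussian
#'   (sigma is `window / 6`, so the kernel is effectively supported).
#' @param smooth_threshold re-binarization level applied to the smoothed
#'   mask.
#' @param nucleus_fraction fraction of `I_B` for the darker nucleus
#'   re-threshold inside the cell mask (used by the pipeline to measure
#'   nucleus areas).
#' @param dark_foreground if `TRUE` (default) pixels below the threshold are
#'   foreground; set `FALSE` for bright-on-dark inputs.
#' @return list of class `segmentation_config`. The Sobel kernels are fixed:
#'   `Gx = [-1 0 1; -2 0 2; -1 0 1]`, `Gy = [1 2 1; 0 0 0; -1 -2 -1]`.
#' @export
segmentation_config <- function(threshold_fraction = 0.70,
                                bright_percentile = 99,
                                min_component_px = 50000L,
                                gaussian_window = 15L,
                                smooth_threshold = 0.50,
                                nucleus_fraction = 0.35,
                                dark_foreground = TRUE) {
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  gaussian_window <- as.integer(gaussian_window)
  if (gaussian_window < 3 || gaussian_window %% 2 == 0)
    stop("gaussian_window must be odd and >= 3")
  if (smooth_threshold <= 0 || smooth_threshold >= 1)
    stop("smooth_threshold must be in (0, 1)")
  structure(list(threshold_fraction = threshold_fraction,
                 bright_percentile = bright_percentile,
                 min_component_px = as.integer(min_component_px),
                 gaussian_window = gaussian_window,
                 smooth_threshold = smooth_threshold,
                 nucleus_fraction = nucleus_fraction,
                 dark_foreground = isTRUE(dark_foreground),
                 sobel_gx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE),
                 sobel_gy = matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, byrow = TRUE)),
            class = "segmentation_config")
}

#' Contrast-enhanced green channel
#'
#' The green channel of a stained blood film has the highest contrast
#' between cell and background of the three color components; this extracts
#' it and linearly stretches the 1st..99th intensity percentiles onto
#' `[0, 1]` (a degenerate histogram passes through unchanged).
#'
#' @param image H x W x 3 array (RGB, values in `[0, 1]`).
#' @return numeric matrix in `[0, 1]`.
#' @export
extract_green_enhanced <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("a 3-channel RGB image is required (got a single-channel input?)")
  g <- image[, , 2]
  q <- stats::quantile(g, c(0.01, 0.99), names = FALSE)
  if (q[2] - q[1] < 1e-12) return(g)
  clamp01((g - q[1]) / (q[2] - q[1]))
}

#' Threshold a gray image at a fraction of the bright-area intensity
#'
#' The bright-area intensity `I_B` is the configured upper percentile of the
#' image; pixels on the dark side of `threshold_fraction * I_B` become
#' foreground (value 1).
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param cfg a [segmentation_config()].
#' @return list with `mask` (logical matrix) and `i_b` (the intensity used).
#' @export
binarize <- function(gray, cfg = segmentation_config()) {
  stopifnot(is.matrix(gray))
  if (length(gray) == 0) stop("empty image")
  if (max(gray) <= 0) stop("image is constant zero; nothing to threshold")
  i_b <- stats::quantile(gray, cfg$bright_percentile / 100, names = FALSE)
  thr <- cfg$threshold_fraction * i_b
  mask <- if (cfg$dark_foreground) gray < thr else gray > thr
  list(mask = mask, i_b = i_b)
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged through a union-find over the adjacency
# graph.
label_components8 <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n <= 1) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-H, -1]; b2 <- lab[-1, -W]    # down-left diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- lab
  out[lab > 0] <- comp[lab[lab > 0]]
  out
}

#' Remove small components and fill holes
#'
#' Drops every 8-connected foreground component smaller than
#' `min_component_px` pixels, then fills the interior holes of the surviving
#' components. Idempotent.
#'
#' @param mask logical matrix.
#' @param cfg a [segmentation_config()].
#' @return logical matrix; error if nothing survives ("no cell found").
#' @export
clean_mask <- function(mask, cfg = segmentation_config()) {
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("no cell found at this threshold (empty mask)")
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= cfg$min_component_px)
  if (length(keep) == 0)
    stop(sprintf("no cell found: all components below %d px", cfg$min_component_px))
  kept <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  filled <- EBImage::fillHull(kept * 1) > 0
  filled
}

#' Smooth a mask boundary with a Gaussian filter
#'
#' Convolves the binary mask with a normalized Gaussian of side
#' `gaussian_window` (reflective borders) and re-binarizes at
#' `smooth_threshold`, rounding boundary staircase artifacts. An isolated
#' pixel disappears (its smoothed peak falls below the threshold); the deep
#' interior of large regions is untouched.
#'
#' @inheritParams clean_mask
#' @return logical matrix.
#' @export
smooth_mask <- function(mask, cfg = segmentation_config()) {
  stopifnot(is.logical(mask))
  k <- gaussian_kernel(cfg$gaussian_window)
  conv2_reflect(mask * 1, k) >= cfg$smooth_threshold
}

#' Sobel edge map of a mask
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` using the fixed 3 x 3 Sobel
#' kernels; every pixel with non-zero magnitude is an edge pixel, giving a
#' closed band of width at most 2 px around a simply-connected region.
#'
#' @inheritParams clean_mask
#' @return logical matrix of edge pixels.
#' @export
detect_edges <- function(mask, cfg = segmentation_config()) {
  stopifnot(is.logical(mask))
  gx <- conv2_reflect(mask * 1, cfg$sobel_gx)
  gy <- conv2_reflect(mask * 1, cfg$sobel_gy)
  sqrt(gx^2 + gy^2) > 1e-9
}

#' Segment the targeted white blood cell from an RGB image
#'
#' Full segmentation chain: contrast-enhanced green channel, optional crop
#' to a region of interest, bright-area thresholding, small-component
#' removal and hole filling, Gaussian boundary smoothing, Sobel edge
#' detection. If several components survive cleaning, the largest one is
#' kept as the targeted cell. A darker re-threshold inside the cell yields a
#' nucleus mask for morphometry. A plausibility guard rejects frames where
#' the threshold selects the majority of the pixels (background-only crops
#' have no cell; their contrast-stretched noise spans the whole range).
#'
#' @param image H x W x 3 RGB array.
#' @param cfg a [segmentation_config()].
#' @param roi optional crop rectangle `c(row, col, height, width)` (1-based
#'   corner); masks are returned in ROI coordinates.
#' @return list of class `segmentation_result`: `cell_mask`, `edge_map`,
#'   `nucleus_mask`, `green_enhanced` (all in ROI coordinates), `i_b`, `roi`.
#' @examples
#' sc <- render_scene(list(cell_spec("lymphocyte", center = c(64, 64),
#'                                   cell_axes = c(50, 44))),
#'                    size = c(128, 128), noise_sigma = 0, seed = 1)
#' seg <- segment_wbc(sc$image, segmentation_config(min_component_px = 200))
#' jaccard(seg$cell_mask, sc$cell_masks[[1]])
#' @export
segment_wbc <- function(image, cfg = segmentation_config(), roi = NULL) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("segmentation stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  green <- step("green-extraction", extract_green_enhanced(image))
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4)
    r <- roi[1] + seq_len(roi[3]) - 1
    c <- roi[2] + seq_len(roi[4]) - 1
    if (max(r) > nrow(green) || max(c) > ncol(green) || min(roi[1:2]) < 1)
      stop("roi outside the image")
    green <- green[r, c]
  } else {
    roi <- c(1, 1, nrow(green), ncol(green))
  }
  bin <- step("binarize", binarize(green, cfg))
  # a stained cell is a minority of its crop; if the threshold selects most
  # of the frame the image holds no cell (pure background stretches its
  # noise across the whole range and would otherwise segment as one blob)
  if (mean(bin$mask) > 0.5)
    stop("segmentation stage 'binarize' failed: no cell found ",
         "(threshold selects most of the image)", call. = FALSE)
  cleaned <- step("clean", clean_mask(bin$mask, cfg))
  lab <- label_components8(cleaned)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    cleaned <- lab == which.max(sizes)
  }
  smoothed <- step("smooth", smooth_mask(cleaned, cfg))
  if (!any(smoothed)) stop("segmentation stage 'smooth' failed: mask vanished")
  edges <- step("edges", detect_edges(smoothed, cfg))
  nucleus <- smoothed & (green < cfg$nucleus_fraction * bin$i_b)
  structure(list(cell_mask = smoothed, edge_map = edges,
                 nucleus_mask = nucleus, green_enhanced = green,
                 i_b = bin$i_b, roi = as.integer(roi)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation result: cell %d px, edges %d px, nucleus %d px, I_B = %.3f\n",
              sum(x$cell_mask), sum(x$edge_map), sum(x$nucleus_mask), x$i_b))
  invisible(x)
}
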