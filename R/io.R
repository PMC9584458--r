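# Image and hologram I/O: PNG (primary) and TIFF, 8-bit grayscale holograms,
# 0/255 masks, JSON sidecars.

read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf("corrupt PNG file '%s': %s",
                                                    path, conditionMessage(e)))),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files")
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '%s' (PNG/TIFF supported)", ext)))
  img
}

#' Read an RGB scene image
#'
#' Reads a PNG or TIFF file as an H x W x 3 array in `[0, 1]` (an alpha
#' channel is dropped, grayscale is replicated to three channels).
#'
#' @param path file path.
#' @return H x W x 3 numeric array.
#' @export
read_scene_image <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read a grayscale image
#'
#' @param path file path (PNG/TIFF).
#' @return numeric matrix in `[0, 1]` (RGB input is converted by averaging).
#' @export
read_gray_image <- function(path) {
  img <- read_raster(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                          c(1, 2), mean)
  img
}

#' Write an RGB scene or grayscale image as PNG
#'
#' @param x H x W x 3 array or matrix, values in `[0, 1]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image_png <- function(x, path) {
  png::writePNG(clamp01(x), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @inheritParams write_image_png
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Hologram file I/O
#'
#' Holograms travel as 8-bit grayscale PNGs: phase `[0, 2*pi)` maps linearly
#' to gray 0..255 (see [quantize_phase()]). `write_hologram_png` writes an
#' SLM-ready file; `read_hologram_png` restores a [phase_hologram()].
#'
#' @param hologram a [phase_hologram()].
#' @param path file path.
#' @return `read_hologram_png`: a [phase_hologram()].
#' @export
write_hologram_png <- function(hologram, path) {
  u8 <- quantize_phase(hologram)
  png::writePNG(u8 / 255, path)
  invisible(path)
}

#' @rdname write_hologram_png
#' @export
read_hologram_png <- function(path) {
  g <- read_gray_image(path)
  dequantize_phase(matrix(as.integer(round(g * 255)), nrow(g), ncol(g)))
}

#' Write a synthetic scene to disk
#'
#' Writes the scene image (PNG), per-cell 0/255 cell and nucleus masks, and
#' a JSON sidecar with the cell specifications, seed and calibration.
#'
#' @param scene a [render_scene()] result.
#' @param prefix output path prefix (directory must exist).
#' @return named character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, prefix) {
  stopifnot(inherits(scene, "wbc_scene"))
  files <- c(image = paste0(prefix, ".png"))
  write_image_png(scene$image, files[["image"]])
  for (i in seq_along(scene$cell_masks)) {
    cf <- paste0(prefix, sprintf("_cell%d_mask.png", i))
    nf <- paste0(prefix, sprintf("_cell%d_nucleus.png", i))
    write_mask_png(scene$cell_masks[[i]], cf)
    write_mask_png(scene$nucleus_masks[[i]], nf)
    files[paste0("cell", i)] <- cf
    files[paste0("nucleus", i)] <- nf
  }
  side <- list(seed = scene$seed, noise_sigma = scene$noise_sigma,
               um_per_px = scene$um_per_px,
               specs = lapply(scene$specs, function(s) unclass(s)))
  sidef <- paste0(prefix, "_scene.json")
  jsonlite::write_json(side, sidef, auto_unbox = TRUE, digits = NA, null = "null")
  files["sidecar"] <- sidef
  invisible(files)
}
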