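# End-to-end orchestration: raw image -> segmentation -> morphometry ->
# padded hologram synthesis -> tiling/temporal multiplexing -> metrics,
# with JSON configuration and a reproducible output manifest.

#' Pipeline configuration
#'
#' Bundles the optical, segmentation and optimizer settings with the scene
#' calibration and output location. All randomness in a pipeline run flows
#' from `ifta$seed`.
#'
#' @param optical an [optical_config()].
#' @param segmentation a [segmentation_config()].
#' @param ifta an [ifta_config()].
#' @param calibration_um_per_px micrometres per pixel of the input images.
#' @param output_dir directory for the artifacts (created on demand).
#' @param log_level `"quiet"` or `"info"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(optical = optical_config(),
                            segmentation = segmentation_config(),
                            ifta = ifta_config(),
                            calibration_um_per_px = 0.1,
                            output_dir = "holocyte_out",
                            log_level = c("info", "quiet")) {
  stopifnot(inherits(optical, "optical_config"),
            inherits(segmentation, "segmentation_config"),
            inherits(ifta, "ifta_config"),
            calibration_um_per_px > 0)
  structure(list(optical = optical, segmentation = segmentation, ifta = ifta,
                 calibration_um_per_px = calibration_um_per_px,
                 output_dir = output_dir,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

.config_keys <- function() {
  list(
    optical = names(formals(optical_config)),
    segmentation = names(formals(segmentation_config)),
    ifta = names(formals(ifta_config)),
    top = c("optical", "segmentation", "ifta", "calibration_um_per_px",
            "output_dir", "log_level"))
}

#' Save / load a pipeline configuration as JSON
#'
#' Round-trip stable; unknown keys are rejected with their location so typos
#' in hand-edited files cannot silently change a run.
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @return `load_config`: a [pipeline_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- list(
    optical = unclass(cfg$optical),
    segmentation = unclass(cfg$segmentation)[
      setdiff(names(unclass(cfg$segmentation)), c("sobel_gx", "sobel_gy"))],
    ifta = unclass(cfg$ifta),
    calibration_um_per_px = cfg$calibration_um_per_px,
    output_dir = cfg$output_dir,
    log_level = cfg$log_level)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- .config_keys()
  bad <- setdiff(names(x), keys$top)
  if (length(bad)) stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  check_sub <- function(sub, allowed, where) {
    bad <- setdiff(names(sub), allowed)
    if (length(bad))
      stop(sprintf("unknown config key(s) under '%s': %s", where,
                   paste(bad, collapse = ", ")))
  }
  if (!is.null(x$optical)) check_sub(x$optical, keys$optical, "optical")
  if (!is.null(x$segmentation))
    check_sub(x$segmentation, keys$segmentation, "segmentation")
  if (!is.null(x$ifta)) check_sub(x$ifta, keys$ifta, "ifta")
  pipeline_config(
    optical = do.call(optical_config, as.list(x$optical %||% list())),
    segmentation = do.call(segmentation_config, as.list(x$segmentation %||% list())),
    ifta = do.call(ifta_config, as.list(x$ifta %||% list())),
    calibration_um_per_px = x$calibration_um_per_px %||% 0.1,
    output_dir = x$output_dir %||% "holocyte_out",
    log_level = x$log_level %||% "info")
}

#' Run the full holographic projection pipeline on one image
#'
#' Executes the complete chain on a blood-film image: cell segmentation,
#' morphometry, 4x zero-padded hologram synthesis, 4 x 4 tiling with
#' temporal-multiplexed reconstruction, and quality metrics for the
#' multiplexed versus the single-hologram baseline. Every artifact (masks,
#' holograms, tiles, reconstructions, reports) is written under
#' `cfg$output_dir` and listed in a manifest along with the seed and a hash
#' of the configuration, so reruns with the same seed and config are
#' byte-identical.
#'
#' The projected amplitude is the luminance-inverted enhanced green channel
#' masked to the segmented cell (nucleus bright, background dark), resampled
#' to the SLM shape.
#'
#' @param image_path path to a PNG/TIFF blood-film image (e.g. written by
#'   [write_scene()]).
#' @param cfg a [pipeline_config()].
#' @param roi optional crop rectangle passed to [segment_wbc()].
#' @return the manifest (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(image_path, cfg = pipeline_config(), roi = NULL) {
  t0 <- Sys.time()
  say <- function(...) if (cfg$log_level == "info") message(sprintf(...))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  manifest <- list(image = image_path, seed = cfg$ifta$seed, files = list(),
                   stages = list())
  fail <- function(stage, e) {
    manifest$error <- sprintf("stage '%s' failed: %s", stage, conditionMessage(e))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    stop(manifest$error, call. = FALSE)
  }

  cfg_path <- out("config.json")
  save_config(cfg, cfg_path)
  # hash the scientific configuration only (output location excluded)
  cfg_id <- cfg
  cfg_id$output_dir <- ""
  id_path <- tempfile(fileext = ".json")
  save_config(cfg_id, id_path)
  manifest$config_hash <- unname(tools::md5sum(id_path))
  unlink(id_path)
  manifest$files$config <- cfg_path

  img <- tryCatch(read_scene_image(image_path), error = function(e) fail("read", e))
  say("segmenting %s ...", image_path)
  seg <- tryCatch(segment_wbc(img, cfg$segmentation, roi),
                  error = function(e) fail("segment", e))
  write_mask_png(seg$cell_mask, out("cell_mask.png"))
  write_mask_png(seg$nucleus_mask, out("nucleus_mask.png"))
  write_mask_png(seg$edge_map, out("edges.png"))
  manifest$files$cell_mask <- out("cell_mask.png")
  manifest$files$nucleus_mask <- out("nucleus_mask.png")
  manifest$files$edges <- out("edges.png")
  manifest$stages$segmentation <- list(i_b = seg$i_b, roi = seg$roi,
                                       cell_px = sum(seg$cell_mask))

  morph <- tryCatch(
    measure_cell(seg$cell_mask, seg$nucleus_mask, cfg$calibration_um_per_px),
    error = function(e) fail("morphometry", e))
  utils::write.csv(as.data.frame(morph), out("morphometry.csv"), row.names = FALSE)
  manifest$files$morphometry <- out("morphometry.csv")
  manifest$stages$morphometry <- as.list(as.data.frame(morph))

  # projected amplitude: inverted enhanced green inside the cell,
  # resampled to the SLM frame
  target <- (1 - seg$green_enhanced) * seg$cell_mask
  target <- fit_to_slm(target, cfg$optical)
  say("synthesizing padded hologram (%d iterations max) ...", cfg$ifta$max_iterations)
  spk <- tryCatch(speckle_pipeline(target, cfg$optical, cfg$ifta),
                  error = function(e) fail("cgh", e))
  write_hologram_png(spk$tiled$full, out("hologram_full.png"))
  manifest$files$hologram_full <- out("hologram_full.png")
  for (i in seq_along(spk$tiled$tiles)) {
    f <- out(sprintf("tile_%02d.png", i))
    write_hologram_png(spk$tiled$tiles[[i]], f)
    manifest$files[[sprintf("tile_%02d", i)]] <- f
  }
  write_image_png(spk$average / max(spk$average), out("reconstruction_multiplexed.png"))
  write_image_png(spk$baseline_reconstruction / max(spk$baseline_reconstruction),
                  out("reconstruction_baseline.png"))
  manifest$files$reconstruction_multiplexed <- out("reconstruction_multiplexed.png")
  manifest$files$reconstruction_baseline <- out("reconstruction_baseline.png")

  report <- list(before = unclass(spk$before)[c("eq1_error", "rmse", "sigma", "mu",
                                                "contrast", "snr", "beta_scale", "psnr")],
                 after = unclass(spk$after)[c("eq1_error", "rmse", "sigma", "mu",
                                              "contrast", "snr", "beta_scale", "psnr")],
                 reduction = as.list(spk$reduction))
  jsonlite::write_json(report, out("quality.json"), auto_unbox = TRUE, digits = NA)
  manifest$files$quality <- out("quality.json")
  manifest$stages$quality <- report
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  say("done in %.1f s; manifest at %s", manifest$elapsed_s, out("manifest.json"))
  invisible(manifest)
}

# Center-crop or zero-pad a matrix to the SLM shape.
fit_to_slm <- function(x, cfg) {
  shp <- cfg$slm_shape
  H <- nrow(x); W <- ncol(x)
  if (H > shp[1]) {
    r0 <- floor((H - shp[1]) / 2)
    x <- x[r0 + seq_len(shp[1]), , drop = FALSE]
  }
  if (W > shp[2]) {
    c0 <- floor((ncol(x) - shp[2]) / 2)
    x <- x[, c0 + seq_len(shp[2]), drop = FALSE]
  }
  if (nrow(x) < shp[1] || ncol(x) < shp[2]) {
    out <- matrix(0, shp[1], shp[2])
    r0 <- floor((shp[1] - nrow(x)) / 2); c0 <- floor((shp[2] - ncol(x)) / 2)
    out[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))] <- x
    x <- out
  }
  x
}
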