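# Configuration objects: optical bench constants and optimizer settings.

#' Optical configuration of the holographic projector
#'
#' Constants of the Fourier-geometry projection bench: a phase-only SLM at
#' the front focal plane of a Fourier lens, a camera at the back focal plane.
#' Defaults describe a red laser diode with a full-HD LCOS modulator and a
#' 5-megapixel camera. Scaled-down variants (smaller `slm_shape`) are used
#' for desk-scale simulation; all plane mappings derive from these values.
#'
#' @param wavelength_m illumination wavelength in meters.
#' @param slm_shape SLM resolution as `c(rows, cols)` pixels.
#' @param slm_pitch_m SLM pixel pitch in meters.
#' @param focal_length_m focal length of the Fourier lens in meters.
#' @param ccd_shape camera resolution as `c(rows, cols)` pixels.
#' @param ccd_pitch_m camera pixel pitch in meters.
#' @return list of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' reconstruction_pitch(cfg)   # sample pitch at the reconstruction plane
#' @export
optical_config <- function(wavelength_m = 670e-9,
                           slm_shape = c(1080L, 1920L),
                           slm_pitch_m = 8e-6,
                           focal_length_m = 0.125,
                           ccd_shape = c(2054L, 2452L),
                           ccd_pitch_m = 3.35e-6) {
  slm_shape <- as.integer(slm_shape); ccd_shape <- as.integer(ccd_shape)
  if (any(c(wavelength_m, slm_pitch_m, focal_length_m, ccd_pitch_m) <= 0))
    stop("all optical lengths must be positive")
  if (length(slm_shape) != 2 || any(slm_shape < 1) ||
      length(ccd_shape) != 2 || any(ccd_shape < 1))
    stop("shapes must be two positive integers (rows, cols)")
  structure(list(wavelength_m = wavelength_m, slm_shape = slm_shape,
                 slm_pitch_m = slm_pitch_m, focal_length_m = focal_length_m,
                 ccd_shape = ccd_shape, ccd_pitch_m = ccd_pitch_m),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("Optical config: lambda %.0f nm | SLM %dx%d @ %.1f um | f %.0f mm | CCD %dx%d @ %.2f um\n",
              x$wavelength_m * 1e9, x$slm_shape[2], x$slm_shape[1], x$slm_pitch_m * 1e6,
              x$focal_length_m * 1e3, x$ccd_shape[2], x$ccd_shape[1], x$ccd_pitch_m * 1e6))
  invisible(x)
}

#' Sample pitch at the reconstruction plane
#'
#' In the Fourier-lens geometry an `n`-sample aperture of pitch `p` maps to a
#' reconstruction-plane pitch `lambda * f / (n * p)` per axis, which fixes
#' how lateral shifts in meters convert to reconstruction pixels.
#'
#' @param cfg an [optical_config()].
#' @param shape optional grid shape (defaults to the SLM shape).
#' @return numeric length-2 vector, meters per reconstruction pixel (rows, cols).
#' @export
reconstruction_pitch <- function(cfg, shape = cfg$slm_shape) {
  cfg$wavelength_m * cfg$focal_length_m / (as.numeric(shape) * cfg$slm_pitch_m)
}

#' Settings of the iterative Fourier transform optimizer
#'
#' @param max_iterations iteration cap.
#' @param epsilon_rad convergence bound on the RMS wrapped phase change
#'   between consecutive SLM-plane phase iterates, in radians. Set to 0 to
#'   disable the phase-based stop.
#' @param error_floor early-stop bound on the intensity mean squared error
#'   ([eq1_error()] after least-squares scaling). Set to 0 to disable.
#' @param seed integer seed for the random initial object phase.
#' @return list of class `ifta_config`.
#' @export
ifta_config <- function(max_iterations = 200L, epsilon_rad = 0.2,
                        error_floor = 5e-3, seed = 1L) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (epsilon_rad < 0 || error_floor < 0) stop("bounds must be non-negative")
  structure(list(max_iterations = as.integer(max_iterations),
                 epsilon_rad = epsilon_rad, error_floor = error_floor,
                 seed = as.integer(seed)),
            class = "ifta_config")
}
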