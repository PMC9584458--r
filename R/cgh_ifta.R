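# Phase-only hologram synthesis by the iterative Fourier transform algorithm
# (Gerchberg-Saxton family) in a Fourier-lens geometry.

#' Phase hologram container
#'
#' A 2D phase map in radians wrapped to `[0, 2*pi)`, the pattern a phase-only
#' SLM displays. Serializable as 8-bit grayscale via [quantize_phase()].
#'
#' @param phase_rad numeric matrix of phases; wrapped on construction.
#' @return object of class `phase_hologram`.
#' @export
phase_hologram <- function(phase_rad) {
  stopifnot(is.matrix(phase_rad), is.numeric(phase_rad))
  structure(list(phase_rad = wrap_2pi(phase_rad), shape = dim(phase_rad)),
            class = "phase_hologram")
}

#' @export
print.phase_hologram <- function(x, ...) {
  cat(sprintf("Phase hologram %d x %d, phase in [0, 2*pi)\n", x$shape[1], x$shape[2]))
  invisible(x)
}

#' Propagate a complex field between the SLM and reconstruction planes
#'
#' Centered unitary 2D discrete Fourier transform (forward: SLM plane to
#' reconstruction plane) and its exact inverse (backward). The zero-frequency
#' sample sits at the grid center in both planes; unitarity preserves energy,
#' and `propagate_backward(propagate_forward(x))` recovers `x` to machine
#' precision.
#'
#' @param field complex (or numeric) matrix.
#' @return complex matrix of the same shape.
#' @export
propagate_forward <- function(field) {
  stopifnot(is.matrix(field))
  cfft2(field, inverse = FALSE)
}

#' @rdname propagate_forward
#' @export
propagate_backward <- function(field) {
  stopifnot(is.matrix(field))
  cfft2(field, inverse = TRUE)
}

#' Compute a phase-only hologram by iterative Fourier transform
#'
#' Alternating-projection phase retrieval between the reconstruction plane
#' and the SLM plane. Starting from a seeded random object phase, each
#' iteration (i) transforms the object field backward to the SLM plane,
#' (ii) applies the plane-wave illumination constraint (amplitude 1, phase
#' kept), (iii) transforms forward to the reconstruction plane, and (iv)
#' replaces the obtained amplitude with the target amplitude, keeping the
#' propagated phase. Convergence is tracked by the intensity mean squared
#' error ([eq1_error()] of the least-squares-scaled reconstruction against
#' the target intensity) and by the RMS wrapped phase change between
#' consecutive SLM phase maps; iteration stops at whichever of the phase
#' bound, error floor or iteration cap is hit first.
#'
#' Zero-padding the target (see [render_amplitude_target()]) gives the
#' optimizer amplitude freedom in the dark frame and lowers the attainable
#' error for the same iteration count.
#'
#' @param target_amplitude non-negative matrix; internally normalized so its
#'   maximum is 1. The target intensity is its square.
#' @param cfg an [ifta_config()].
#' @return list of class `ifta_result` with elements `hologram`
#'   ([phase_hologram()]), `error_trace`, `phase_delta_trace` (first entry
#'   `NA`), `iterations_run` and `reconstruction` (the least-squares-scaled
#'   reconstructed intensity).
#' @examples
#' tg <- matrix(0, 64, 64); tg[25:40, 25:40] <- 1
#' res <- run_ifta(tg, ifta_config(max_iterations = 20, seed = 3))
#' res$iterations_run
#' all(diff(res$error_trace) <= 1e-12)   # error-reduction property
#' @export
run_ifta <- function(target_amplitude, cfg = ifta_config()) {
  stopifnot(is.matrix(target_amplitude), inherits(cfg, "ifta_config"))
  if (any(target_amplitude < 0)) stop("target amplitude must be non-negative")
  mx <- max(target_amplitude)
  if (mx == 0) stop("target amplitude is identically zero")
  A <- target_amplitude / mx
  i_ref <- A^2

  phi0 <- with_seed(cfg$seed,
                    matrix(stats::runif(length(A), 0, 2 * pi), nrow(A)))
  obj <- A * exp(1i * phi0)

  err <- numeric(0); dph <- numeric(0)
  phi_prev <- NULL; phi <- NULL; i_nr <- NULL
  for (n in seq_len(cfg$max_iterations)) {
    slm_field <- propagate_backward(obj)
    phi <- Arg(slm_field)
    rec <- propagate_forward(exp(1i * phi))
    i_nr <- Mod(rec)^2
    err[n] <- eq1_error(i_ref, i_nr, scale_ls = TRUE)
    dph[n] <- if (is.null(phi_prev)) NA_real_ else
      sqrt(mean(wrap_pi(phi - phi_prev)^2))
    phi_prev <- phi
    obj <- A * exp(1i * Arg(rec))
    if (!is.na(dph[n]) && cfg$epsilon_rad > 0 && dph[n] < cfg$epsilon_rad) break
    if (cfg$error_floor > 0 && err[n] <= cfg$error_floor) break
  }
  s <- sum(i_ref * i_nr) / sum(i_nr^2)
  structure(list(hologram = phase_hologram(phi),
                 error_trace = err,
                 phase_delta_trace = dph,
                 iterations_run = length(err),
                 reconstruction = i_nr * s),
            class = "ifta_result")
}

#' @export
print.ifta_result <- function(x, ...) {
  cat(sprintf("IFTA result: %d iterations, final intensity MSE %.3g, last phase delta %.3g rad\n",
              x$iterations_run, x$error_trace[x$iterations_run],
              x$phase_delta_trace[x$iterations_run]))
  invisible(x)
}

#' Quantize a phase hologram to 8 bits and back
#'
#' `quantize_phase` maps `[0, 2*pi)` linearly to `{0..255}` (round half up),
#' the value range of SLM-ready grayscale holograms; `dequantize_phase`
#' inverts the map. A round trip changes the phase by at most `pi/255`.
#'
#' @param hologram a [phase_hologram()] (or bare phase matrix).
#' @param u8 integer matrix with values in 0..255.
#' @return `quantize_phase`: integer matrix in 0..255;
#'   `dequantize_phase`: a [phase_hologram()].
#' @export
quantize_phase <- function(hologram) {
  phase <- if (inherits(hologram, "phase_hologram")) hologram$phase_rad else wrap_2pi(hologram)
  u8 <- floor(phase * 255 / (2 * pi) + 0.5)
  storage.mode(u8) <- "integer"
  u8
}

#' @rdname quantize_phase
#' @export
dequantize_phase <- function(u8) {
  stopifnot(is.matrix(u8), all(u8 >= 0), all(u8 <= 255))
  phase_hologram(u8 * 2 * pi / 255)
}
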