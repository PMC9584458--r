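# Scalar evaluation metrics for reconstructed intensities and masks.

#' Mean squared intensity error between a reference and a reconstruction
#'
#' The convergence figure of merit of the hologram optimizer: the mean over
#' pixels of the squared intensity difference,
#' `mean((I_ref - I_rec)^2)`. Note that, following the convention of the
#' holographic-projection literature this quantity is often *called* an RMSE
#' even though no square root is taken; [sqrt()] of the returned value gives
#' the true root-mean-square error.
#'
#' @param i_ref reference intensity matrix.
#' @param i_rec reconstructed intensity matrix, same shape.
#' @param scale_ls if `TRUE`, rescale `i_rec` by the least-squares factor
#'   `s = sum(i_ref * i_rec) / sum(i_rec^2)` before differencing, making the
#'   metric insensitive to the arbitrary energy normalization of a numerical
#'   reconstruction. Default `FALSE` (the metric exactly as defined).
#' @return single non-negative number.
#' @seealso [scaled_snr()], [psnr()]
#' @export
eq1_error <- function(i_ref, i_rec, scale_ls = FALSE) {
  stopifnot(is.matrix(i_ref), is.matrix(i_rec))
  assert_same_shape(i_ref, i_rec, "intensity images")
  if (isTRUE(scale_ls)) {
    den <- sum(i_rec^2)
    if (den > 0) i_rec <- i_rec * (sum(i_ref * i_rec) / den)
  }
  mean((i_ref - i_rec)^2)
}

#' Speckle contrast of an intensity region
#'
#' Contrast `C = sigma / mu`: the ratio of the population standard deviation
#' to the mean of the intensity over a region. Fully developed speckle has
#' `C = 1`; averaging `N` independent speckle patterns reduces `C` by about
#' `1/sqrt(N)`.
#'
#' @param image intensity matrix.
#' @param region optional logical mask selecting the statistics region
#'   (default: the whole image). Contrast over a dark region is undefined, so
#'   the region mean must be positive.
#' @return list with elements `sigma`, `mu` and `contrast`.
#' @export
speckle_contrast <- function(image, region = NULL) {
  stopifnot(is.matrix(image))
  v <- if (is.null(region)) as.vector(image) else {
    assert_same_shape(image, region, "image and region")
    image[region]
  }
  if (length(v) == 0) stop("statistics region is empty")
  mu <- mean(v)
  if (mu <= 0) stop("region mean intensity must be positive")
  sigma <- sqrt(mean((v - mu)^2))
  list(sigma = sigma, mu = mu, contrast = sigma / mu)
}

#' Scale-invariant signal-to-noise ratio of a reconstruction
#'
#' SNR between a reference intensity and a reconstructed intensity after
#' optimal rescaling of the reconstruction:
#' `beta = sqrt(||I_ref||^2 / ||I_or||^2)` and
#' `SNR = ||I_ref||^2 / ||I_ref - beta * I_or||^2`, with `||.||` the
#' Euclidean norm over all pixels. The beta factor removes the arbitrary
#' intensity scale of the reconstruction, so `I_or = c * I_ref` gives an
#' infinite SNR for any `c > 0`.
#'
#' @param i_ref reference intensity matrix.
#' @param i_or reconstructed intensity matrix, same shape, not all zero.
#' @return list with elements `snr` (may be `Inf`) and `beta`.
#' @export
scaled_snr <- function(i_ref, i_or) {
  stopifnot(is.matrix(i_ref), is.matrix(i_or))
  assert_same_shape(i_ref, i_or, "intensity images")
  n_or <- sum(i_or^2)
  if (n_or == 0) stop("reconstructed image is identically zero")
  n_ref <- sum(i_ref^2)
  beta <- sqrt(n_ref / n_or)
  den <- sum((i_ref - beta * i_or)^2)
  snr <- if (den == 0) Inf else n_ref / den
  list(snr = snr, beta = beta)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(peak^2 / MSE)` with `peak = max(i_ref)`. Identical images give
#' `Inf`.
#'
#' @inheritParams eq1_error
#' @return PSNR in dB.
#' @export
psnr <- function(i_ref, i_rec) {
  stopifnot(is.matrix(i_ref), is.matrix(i_rec))
  assert_same_shape(i_ref, i_rec, "intensity images")
  mse <- mean((i_ref - i_rec)^2)
  if (mse == 0) return(Inf)
  10 * log10(max(i_ref)^2 / mse)
}

#' Jaccard similarity between two binary masks
#'
#' `|A intersect B| / |A union B|`. Two empty masks are defined to be
#' identical (similarity 1).
#'
#' @param mask_a,mask_b logical matrices of the same shape.
#' @return number in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  stopifnot(is.logical(mask_a) || all(mask_a %in% c(0, 1)),
            is.logical(mask_b) || all(mask_b %in% c(0, 1)))
  assert_same_shape(mask_a, mask_b, "masks")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Bundle the standard quality metrics for a reconstruction
#'
#' Computes the intensity-error figure of merit (and its square root), the
#' speckle statistics over a region, the scale-invariant SNR and the PSNR in
#' one pass, with an optional mask comparison.
#'
#' @param i_ref reference intensity matrix.
#' @param i_rec reconstructed intensity matrix (same shape), rescaled by the
#'   least-squares factor against `i_ref` before the fixed-scale metrics.
#' @param region optional logical mask for the speckle statistics.
#' @param mask_a,mask_b optional binary masks for a Jaccard entry.
#' @return list of class `quality_report`.
#' @export
quality_report <- function(i_ref, i_rec, region = NULL, mask_a = NULL, mask_b = NULL) {
  s <- if (sum(i_rec^2) > 0) sum(i_ref * i_rec) / sum(i_rec^2) else 1
  i_scaled <- i_rec * s
  sc <- speckle_contrast(i_scaled, region)
  snr <- scaled_snr(i_ref, i_rec)
  rep <- list(
    eq1_error = eq1_error(i_ref, i_scaled),
    rmse = sqrt(eq1_error(i_ref, i_scaled)),
    sigma = sc$sigma, mu = sc$mu, contrast = sc$contrast,
    snr = snr$snr, beta_scale = snr$beta,
    psnr = psnr(i_ref, i_scaled),
    jaccard = if (!is.null(mask_a) && !is.null(mask_b)) jaccard(mask_a, mask_b) else NULL
  )
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Reconstruction quality report\n")
  cat(sprintf("  intensity MSE : %.6g (rmse %.6g)\n", x$eq1_error, x$rmse))
  cat(sprintf("  sigma / mu / C: %.5g / %.5g / %.4g\n", x$sigma, x$mu, x$contrast))
  cat(sprintf("  scaled SNR    : %.5g (beta %.4g)\n", x$snr, x$beta_scale))
  cat(sprintf("  PSNR          : %.4g dB\n", x$psnr))
  if (!is.null(x$jaccard)) cat(sprintf("  Jaccard       : %.4f\n", x$jaccard))
  invisible(x)
}
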