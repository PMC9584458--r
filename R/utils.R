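# Shared numerical helpers: centered unitary FFTs, border-aware convolution,
# phase wrapping, seeded RNG scopes.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded generators inside the
#' package never disturb the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Quadrant swap (zero-frequency to/from the grid center)
#'
#' `fftshift2` moves the zero-frequency sample to the grid center
#' (index `floor(n/2) + 1` on each axis); `ifftshift2` is its exact inverse,
#' also for odd dimensions.
#'
#' @param x numeric or complex matrix.
#' @return matrix of the same shape.
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  h <- floor(d / 2)
  x[c(seq(h[1] + 1, d[1]), seq_len(h[1])), c(seq(h[2] + 1, d[2]), seq_len(h[2])), drop = FALSE]
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  h <- ceiling(d / 2)
  x[c(seq(h[1] + 1, d[1]), seq_len(h[1])), c(seq(h[2] + 1, d[2]), seq_len(h[2])), drop = FALSE]
}

# Centered unitary 2D DFT: grid center is the zero-frequency sample in both
# domains and total energy is preserved (Parseval).
cfft2 <- function(x, inverse = FALSE) {
  fftshift2(stats::fft(ifftshift2(x), inverse = inverse)) / sqrt(prod(dim(x)))
}

#' Wrap phase values
#'
#' `wrap_2pi` maps phases into `[0, 2*pi)`; `wrap_pi` maps phase differences
#' into `(-pi, pi]`.
#' @param p numeric vector, matrix or array of phases in radians.
#' @return wrapped phases, same shape.
#' @export
wrap_2pi <- function(p) {
  w <- p %% (2 * pi)
  # guard against 2*pi sneaking back in through floating point
  w[w >= 2 * pi] <- 0
  w
}

#' @rdname wrap_2pi
#' @export
wrap_pi <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' 2D cross-correlation with reflected borders
#'
#' Direct (non-FFT) evaluation of `out[i,j] = sum_k k[a,b] * x[i+a-c, j+b-c]`
#' over an odd-sized kernel, with the input reflected at its borders. This is
#' the filtering convention of the usual image-processing toolboxes (the
#' kernel is not flipped), so the printed Sobel kernels act as printed.
#'
#' @param x numeric matrix.
#' @param k odd-sized numeric kernel matrix.
#' @return filtered matrix, same shape as `x`.
#' @keywords internal
conv2_reflect <- function(x, k) {
  stopifnot(is.matrix(x), is.matrix(k))
  kh <- nrow(k); kw <- ncol(k)
  if (kh %% 2 == 0 || kw %% 2 == 0) stop("kernel dimensions must be odd")
  wy <- (kh - 1) / 2; wx <- (kw - 1) / 2
  H <- nrow(x); W <- ncol(x)
  if (H <= wy || W <= wx) stop("image smaller than kernel half-width")
  # reflection without repeating the border pixel
  ry <- if (wy == 0) seq_len(H) else c(rev(seq(2, wy + 1)), seq_len(H), seq(H - 1, H - wy))
  rx <- if (wx == 0) seq_len(W) else c(rev(seq(2, wx + 1)), seq_len(W), seq(W - 1, W - wx))
  P <- x[ry, rx, drop = FALSE]
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (k[a, b] == 0) next
      out <- out + k[a, b] * P[(a - 1) + seq_len(H), (b - 1) + seq_len(W)]
    }
  }
  out
}

#' Isotropic Gaussian kernel
#'
#' Normalized 2D Gaussian on an odd `window` x `window` support.
#' @param window odd kernel side in pixels.
#' @param sigma standard deviation in pixels; default `window / 6` so the
#'   kernel is effectively supported by the window.
#' @return numeric matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(window, sigma = window / 6) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  x <- seq(-(window - 1) / 2, (window - 1) / 2)
  k <- outer(stats::dnorm(x, sd = sigma), stats::dnorm(x, sd = sigma))
  k / sum(k)
}

# Block-average a matrix by an integer factor along both axes.
block_mean <- function(x, factor) {
  H <- nrow(x); W <- ncol(x)
  if (H %% factor != 0 || W %% factor != 0)
    stop("matrix dimensions must be multiples of the downsampling factor")
  a <- array(x, c(factor, H %/% factor, factor, W %/% factor))
  apply(a, c(2, 4), mean)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
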