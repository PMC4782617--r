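#' Rotate pixel offsets into a Gabor kernel's own frame
#'
#' Applies the coordinate rotation used inside the Gabor kernel formula:
#' \code{x' = x cos(theta) + y sin(theta)}, \code{y' = y cos(theta) - x
#' sin(theta)}. Norm-preserving; vectorized over \code{x} and \code{y}.
#'
#' @param x,y numeric pixel offsets from the kernel centre.
#' @param theta rotation angle in radians.
#' @return a list with components \code{x} and \code{y} (the rotated offsets).
#' @export
rotate_coords <- function(x, y, theta) {
  stopifnot(is.finite(x), is.finite(y), is.finite(theta))
  list(x = x * cos(theta) + y * sin(theta),
       y = y * cos(theta) - x * sin(theta))
}

#' Gabor filter parameters
#'
#' The quadruple that fixes one real Gabor kernel: the Gaussian envelope
#' spreads along the rotated axes (\code{sigma_x}, \code{sigma_y}, in
#' pixels), the central frequency \code{freq} of the cosine carrier (in
#' cycles per pixel, taken literally on the integer sampling grid), and the
#' orientation \code{theta} (radians; the real kernel is even under a
#' half-turn, so theta and theta + pi describe the same filter).
#'
#' @param sigma_x,sigma_y positive Gaussian spreads (pixels).
#' @param freq positive central frequency (cycles/pixel).
#' @param theta orientation in radians.
#' @return an object of class \code{"gabor_params"}.
#' @export
gabor_params <- function(sigma_x, sigma_y, freq, theta) {
  if (!is.finite(sigma_x) || sigma_x <= 0) stop("sigma_x must be > 0")
  if (!is.finite(sigma_y) || sigma_y <= 0) stop("sigma_y must be > 0")
  if (!is.finite(freq) || freq <= 0) stop("freq must be > 0")
  if (!is.finite(theta)) stop("theta must be finite")
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y,
                 freq = freq, theta = theta),
            class = "gabor_params")
}

#' Sample the real part of a Gabor kernel
#'
#' Evaluates \deqn{G(x, y) = \exp[-\tfrac12((x'/\sigma_x)^2 +
#' (y'/\sigma_y)^2)]\,\cos(2\pi f x')} at integer pixel offsets on an
#' odd-sized square grid centred at (0, 0), where (x', y') are the
#' [rotate_coords()] rotation of (x, y). Only the real part is computed; the
#' imaginary (sine-carrier) part is a documented extension point, not needed
#' by the classification pipeline.
#'
#' The grid half-width is \code{max(3, ceiling(nsigma * max(sigma_x,
#' sigma_y)))}; the default 3-sigma truncation retains over 99 percent of
#' the Gaussian envelope mass.
#'
#' @param params a [gabor_params()].
#' @param nsigma truncation half-width in units of the larger sigma.
#' @param freq_scale multiplier applied to \code{freq} before sampling
#'   (default 1: the frequency is used literally in cycles per pixel, so
#'   values above 0.5 alias on the integer lattice; that literal form is the
#'   one this package's feature pipeline is validated with).
#' @return an object of class \code{"gabor_kernel"}: list with
#'   \code{weights} (odd square matrix, centre value exactly 1),
#'   \code{center} (index of the (0,0) sample) and \code{params}.
#' @examples
#' k <- gabor_kernel(gabor_params(1, 1, 2, 0))
#' dim(k$weights)            # 7 x 7
#' k$weights[k$center, k$center]  # exactly 1
#' @export
gabor_kernel <- function(params, nsigma = 3, freq_scale = 1) {
  stopifnot(inherits(params, "gabor_params"), nsigma > 0, freq_scale > 0)
  hw <- max(3L, as.integer(ceiling(nsigma * max(params$sigma_x, params$sigma_y))))
  off <- seq.int(-hw, hw)
  # rows index y, columns index x
  X <- matrix(off, 2L * hw + 1L, 2L * hw + 1L, byrow = TRUE)
  Y <- matrix(off, 2L * hw + 1L, 2L * hw + 1L)
  r <- rotate_coords(X, Y, params$theta)
  W <- exp(-0.5 * ((r$x / params$sigma_x)^2 + (r$y / params$sigma_y)^2)) *
    cos(2 * pi * params$freq * freq_scale * r$x)
  structure(list(weights = W, center = hw + 1L, params = params),
            class = "gabor_kernel")
}

#' 2D convolution with symmetric boundary padding
#'
#' True convolution (the kernel is flipped in both directions), output the
#' same size as the input, boundaries handled by half-sample mirror
#' extension -- the same convention the wavelet module uses. The Gabor
#' kernels produced here are symmetric under a point reflection, so for
#' them convolution and correlation coincide; the flip is applied anyway so
#' the contract holds for arbitrary kernels.
#'
#' @param image numeric matrix with finite values.
#' @param kernel a [gabor_kernel()] or a plain odd-sized numeric matrix.
#' @return filtered matrix, \code{dim(image)}.
#' @export
convolve2 <- function(image, kernel) {
  w <- if (inherits(kernel, "gabor_kernel")) kernel$weights else kernel
  stopifnot(is.matrix(w), nrow(w) %% 2L == 1L, ncol(w) %% 2L == 1L)
  check_image(image)
  hr <- (nrow(w) - 1L) %/% 2L
  hc <- (ncol(w) - 1L) %/% 2L
  wf <- w[rev(seq_len(nrow(w))), rev(seq_len(ncol(w))), drop = FALSE]
  p <- max(hr, hc)
  ext <- pad_symmetric(image, p)
  out <- matrix(0, nrow(image), ncol(image))
  ri <- seq_len(nrow(image))
  ci <- seq_len(ncol(image))
  for (a in seq_len(nrow(w))) {
    for (b in seq_len(ncol(w))) {
      if (wf[a, b] == 0) next
      out <- out + wf[a, b] *
        ext[ri + (p - hr) + (a - 1L), ci + (p - hc) + (b - 1L), drop = FALSE]
    }
  }
  out
}

#' Gabor filter bank configuration
#'
#' Enumerates one kernel per (frequency, orientation) pair. Defaults follow
#' the texture-screening design this package implements: four orientations
#' covering both axes and both diagonals, three central frequencies, hence
#' twelve kernels. Enumeration order is fixed and frequency-major
#' (frequencies ascending, orientations in listed order within each
#' frequency); feature subscripts downstream refer to this order.
#'
#' Two sigma schemes are supported: explicit \code{sigma_x}/\code{sigma_y}
#' (default unity, used for retina and brain MR imagery), or the mammogram
#' scheme via \code{fwhm}, which sets \code{sigma_x = fwhm/2.35} (2.35 is
#' the full-width-at-half-maximum to sigma conversion of a Gaussian) and
#' \code{sigma_y = 8 * sigma_x}, giving an envelope elongated across the
#' carrier direction.
#'
#' @param frequencies positive central frequencies, ascending order
#'   recommended (they are sorted internally to fix the enumeration).
#' @param orientations orientation angles in radians.
#' @param sigma_x,sigma_y explicit Gaussian spreads (pixels).
#' @param fwhm if non-NULL, overrides the sigmas with the mammogram scheme.
#' @param nsigma kernel truncation, see [gabor_kernel()].
#' @param freq_scale frequency multiplier, see [gabor_kernel()].
#' @return an object of class \code{"gabor_bank"}.
#' @export
gabor_bank <- function(frequencies = c(2, 2.5, 3),
                       orientations = c(0, pi / 4, pi / 2, 3 * pi / 4),
                       sigma_x = 1, sigma_y = 1, fwhm = NULL,
                       nsigma = 3, freq_scale = 1) {
  if (length(frequencies) == 0L || length(orientations) == 0L)
    stop("frequencies and orientations must be non-empty")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be positive and finite")
  if (any(!is.finite(orientations)))
    stop("orientations must be finite")
  if (!is.null(fwhm)) {
    sigma_x <- fwhm / 2.35
    sigma_y <- 8 * sigma_x
  }
  structure(list(frequencies = sort(frequencies),
                 orientations = orientations,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 nsigma = nsigma, freq_scale = freq_scale),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("Gabor filter bank:", length(x$frequencies), "frequencies x",
      length(x$orientations), "orientations =",
      length(x$frequencies) * length(x$orientations), "kernels\n")
  cat("  f:", paste(x$frequencies, collapse = ", "), "cycles/pixel\n")
  cat("  theta:", paste(sprintf("%.3f", x$orientations), collapse = ", "),
      "rad\n")
  cat(sprintf("  sigma_x = %.4g, sigma_y = %.4g, truncation %g sigma\n",
              x$sigma_x, x$sigma_y, x$nsigma))
  invisible(x)
}

#' Materialize the kernels of a bank, in enumeration order
#'
#' @param bank a [gabor_bank()].
#' @return named list of [gabor_kernel()] objects, frequency-major order;
#'   names encode the (f, theta) pair, e.g. \code{"f2_t0.785"}.
#' @export
bank_kernels <- function(bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  ks <- list()
  for (f in bank$frequencies) {
    for (th in bank$orientations) {
      p <- gabor_params(bank$sigma_x, bank$sigma_y, f, th)
      ks[[sprintf("f%g_t%.3f", f, th)]] <-
        gabor_kernel(p, nsigma = bank$nsigma, freq_scale = bank$freq_scale)
    }
  }
  ks
}

#' Apply every kernel of a bank to an image
#'
#' @param image numeric matrix.
#' @param bank a [gabor_bank()].
#' @return named list of filtered matrices (same size as \code{image}),
#'   one per kernel, in the bank's frequency-major enumeration order.
#' @export
apply_bank <- function(image, bank = gabor_bank()) {
  lapply(bank_kernels(bank), function(k) convolve2(image, k))
}
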