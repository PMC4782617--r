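#' Relative-frequency histogram of coefficient values
#'
#' Estimates the probability distribution p(z) of the coefficients of a
#' (sub)image by relative frequency over equal-width bins spanning the
#' observed range of that image. Binning the per-image range (rather than a
#' global range) makes the downstream entropy and uniformity statistics
#' invariant to positive rescaling of the coefficients, so images of
#' different bit depth or dynamic range are comparable.
#'
#' A constant array has no range to bin; it is returned as a degenerate
#' single-bin histogram with all mass in that bin.
#'
#' @param coeffs numeric matrix or vector of finite coefficients.
#' @param n_bins number of equal-width bins (>= 2). The default 256 matches
#'   the 8-bit gray-level convention of the texture literature.
#' @return an object of class \code{"coef_histogram"}: list with
#'   \code{breaks} (bin edges, length bins + 1) and \code{pmf}
#'   (probability masses summing to 1).
#' @export
coef_histogram <- function(coeffs, n_bins = 256L) {
  x <- as.numeric(coeffs)
  if (length(x) == 0L) stop("cannot build a histogram from an empty input")
  if (any(!is.finite(x))) stop("coefficients must be finite")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    return(structure(list(breaks = c(lo - 0.5, lo + 0.5), pmf = 1),
                     class = "coef_histogram"))
  }
  width <- (hi - lo) / n_bins
  idx <- pmin.int(floor((x - lo) / width) + 1L, n_bins)  # top edge closed
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(breaks = lo + width * (0:n_bins),
                 pmf = counts / length(x)),
            class = "coef_histogram")
}

#' @export
print.coef_histogram <- function(x, ...) {
  cat("coefficient histogram:", length(x$pmf), "bins on [",
      format(x$breaks[1]), ",", format(x$breaks[length(x$breaks)]), "]\n")
  cat(sprintf("  entropy %.4f bits, uniformity %.4f\n",
              shannon_entropy(x), uniformity(x)))
  invisible(x)
}

#' Entropy of a coefficient histogram
#'
#' \eqn{E = -\sum_z p(z) \log_2 p(z)} with the usual convention
#' \eqn{0 \log 0 = 0}. Measured in bits; ranges from 0 (all mass in one
#' bin -- a featureless, constant texture) to \eqn{\log_2 k} for k occupied
#' bins (maximally disordered texture). The logarithm base only rescales E
#' and is immaterial to the classifier.
#'
#' @param hist a [coef_histogram()].
#' @return non-negative scalar.
#' @export
shannon_entropy <- function(hist) {
  stopifnot(inherits(hist, "coef_histogram"))
  p <- hist$pmf[hist$pmf > 0]
  -sum(p * log2(p))
}

#' Uniformity (energy) of a coefficient histogram
#'
#' \eqn{U = \sum_z p(z)^2}: 1 for a degenerate one-bin distribution, 1/k for
#' a flat distribution over k bins. Inversely related to entropy -- U is
#' maximal exactly when E = 0 and minimal exactly when E is maximal.
#'
#' @param hist a [coef_histogram()].
#' @return scalar in (0, 1].
#' @export
uniformity <- function(hist) {
  stopifnot(inherits(hist, "coef_histogram"))
  sum(hist$pmf^2)
}

#' Texture feature vector of one image
#'
#' The three feature modes of the classification system:
#' \describe{
#'   \item{\code{"dwt"}}{entropy and uniformity of the HH wavelet subband at
#'     \code{level}: a 2-vector \code{[E, U]}.}
#'   \item{\code{"dwt_gabor"}}{the HH subband is filtered by every kernel of
#'     the Gabor bank; entropy and uniformity of each of the (by default 12)
#'     responses give a 24-vector \code{[E1..E12, U1..U12]} in the bank's
#'     frequency-major enumeration order.}
#'   \item{\code{"gabor"}}{the bank is applied directly to the raw image
#'     (no wavelet step, \code{level} ignored); same 24-component layout.
#'     This is the Gabor-only baseline.}
#' }
#'
#' @param image numeric matrix, intensities in any finite range.
#' @param mode feature mode, see Details.
#' @param level DWT level (1 or 2); required for the two wavelet modes.
#' @param wavelet a [wavelet_spec()].
#' @param bank a [gabor_bank()].
#' @param n_bins histogram resolution, see [coef_histogram()].
#' @return named numeric vector of length 2 (\code{"dwt"}) or
#'   2 x bank size (otherwise). Entropy components first, then uniformity
#'   components, matching subscript order.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' length(texture_features(img, "dwt", level = 1))       # 2
#' length(texture_features(img, "dwt_gabor", level = 1)) # 24
#' @export
texture_features <- function(image, mode = c("dwt_gabor", "dwt", "gabor"),
                             level = 1L, wavelet = db4_wavelet(),
                             bank = gabor_bank(), n_bins = 256L) {
  mode <- match.arg(mode)
  if (mode != "gabor" && (is.null(level) || is.na(level)))
    stop("level is required for wavelet-based feature modes")
  if (mode == "dwt") {
    h <- coef_histogram(extract_hh(image, level, wavelet), n_bins)
    return(c(E = shannon_entropy(h), U = uniformity(h)))
  }
  base <- if (mode == "dwt_gabor") extract_hh(image, level, wavelet) else image
  responses <- apply_bank(base, bank)
  hs <- lapply(responses, coef_histogram, n_bins = n_bins)
  e <- vapply(hs, shannon_entropy, numeric(1))
  u <- vapply(hs, uniformity, numeric(1))
  c(stats::setNames(e, paste0("E_", names(responses))),
    stats::setNames(u, paste0("U_", names(responses))))
}
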