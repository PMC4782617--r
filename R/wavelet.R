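#' Wavelet filter specification
#'
#' Bundles the analysis filter pair of an orthogonal wavelet together with a
#' boundary-extension rule. The decomposition routines consume only the two
#' tap sequences, so any quadrature-mirror pair can be supplied; the package
#' default (and the only pair exercised by the test suite) is Daubechies-4.
#'
#' @param name identifier for the wavelet family member.
#' @param lowpass numeric vector of low-pass (scaling) analysis taps g(n);
#'   must sum to sqrt(2) within 1e-10.
#' @param highpass numeric vector of high-pass (wavelet) analysis taps h(n),
#'   same length as \code{lowpass}; must sum to 0 within 1e-10.
#' @param boundary boundary extension rule; only \code{"symmetric"}
#'   (half-sample mirror) is currently implemented. Medical images have no
#'   natural periodicity, which is why periodization is not the default.
#' @return an object of class \code{"wavelet_spec"}.
#' @seealso [db4_wavelet()], [dwt2()], [extract_hh()]
#' @export
wavelet_spec <- function(name, lowpass, highpass, boundary = "symmetric") {
  lowpass <- as.numeric(lowpass)
  highpass <- as.numeric(highpass)
  if (length(lowpass) != length(highpass))
    stop("lowpass and highpass filters must have equal length")
  if (abs(sum(lowpass) - sqrt(2)) > 1e-10)
    stop("lowpass taps must sum to sqrt(2): not a valid scaling filter")
  if (abs(sum(highpass)) > 1e-10)
    stop("highpass taps must sum to 0: constant signals would leak into detail bands")
  boundary <- match.arg(boundary, "symmetric")
  structure(list(name = name, lowpass = lowpass, highpass = highpass,
                 boundary = boundary),
            class = "wavelet_spec")
}

#' Daubechies-4 analysis filters
#'
#' The 8-tap, 4-vanishing-moment Daubechies filter pair (standard published
#' constants). Note the naming ambiguity across communities: "Daubechies-4"
#' sometimes denotes the 4-tap filter with 2 vanishing moments. This package
#' uses the 8-tap member; substitute any other pair via [wavelet_spec()].
#'
#' @return a \code{"wavelet_spec"}.
#' @export
db4_wavelet <- function() {
  lo <- c(-0.010597401785069032, 0.0328830116668852,
          0.030841381835560764, -0.18703481171909309,
          -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
  # quadrature mirror: h[k] = (-1)^k * g[L-1-k]
  hi <- rev(lo) * (-1) ^ (seq_along(lo) - 1)
  wavelet_spec("Daubechies-4 (8 taps)", lo, hi)
}

# Filter every column of `x` with `taps` and downsample by 2.
# Columns are extended by half-sample reflection; output has ceil(n/2) rows:
# out[i, ] = sum_j taps[j] * ext[2*(i-1) + j, ]  with a left pad of L-1.
decimated_filter_cols <- function(x, taps) {
  n <- nrow(x)
  L <- length(taps)
  nc_out <- ceiling(n / 2)
  ri <- reflect_index(seq.int(-(L - 2L), 2L * (nc_out - 1L) + 1L), n)
  ext <- x[ri, , drop = FALSE]
  out <- matrix(0, nc_out, ncol(x))
  for (j in seq_len(L)) {
    out <- out + taps[j] * ext[seq.int(j, by = 2L, length.out = nc_out), ,
                               drop = FALSE]
  }
  out
}

#' One level of 2D discrete wavelet decomposition
#'
#' Separable analysis: each row of the image is filtered and decimated first,
#' then each column of the two results, yielding the four subbands LL, LH,
#' HL, HH at half resolution. Subband names give the filter applied along
#' rows then along columns (H = high-pass), so HH carries detail that is
#' high-frequency in both directions -- the carrier of abrupt local texture
#' changes that this package's features are built on.
#'
#' Boundaries are extended by half-sample mirroring, so an M x N image yields
#' four ceiling(M/2) x ceiling(N/2) subbands (exactly M/2 x N/2 for even
#' dimensions).
#'
#' @param image numeric matrix of finite intensities, at least as large as
#'   the filter length in both dimensions.
#' @param wavelet a [wavelet_spec()]; default Daubechies-4.
#' @return an object of class \code{"subband_set"}: a list with elements
#'   \code{level} (always 1 here), \code{LL}, \code{LH}, \code{HL},
#'   \code{HH}.
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' sb <- dwt2(img)
#' dim(sb$HH)  # 32 x 32
#' @export
dwt2 <- function(image, wavelet = db4_wavelet()) {
  stopifnot(inherits(wavelet, "wavelet_spec"))
  L <- length(wavelet$lowpass)
  check_image(image, min_dim = L)
  # rows first: filtering along the row variable acts on the columns of t(image)
  lo_rows <- t(decimated_filter_cols(t(image), wavelet$lowpass))
  hi_rows <- t(decimated_filter_cols(t(image), wavelet$highpass))
  structure(list(
    level = 1L,
    LL = decimated_filter_cols(lo_rows, wavelet$lowpass),
    LH = decimated_filter_cols(lo_rows, wavelet$highpass),
    HL = decimated_filter_cols(hi_rows, wavelet$lowpass),
    HH = decimated_filter_cols(hi_rows, wavelet$highpass)
  ), class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat("2D-DWT subband set, level", x$level, "\n")
  cat("  subband size:", nrow(x$LL), "x", ncol(x$LL), "\n")
  for (b in c("LL", "LH", "HL", "HH"))
    cat(sprintf("  %s: energy %.4g\n", b, sum(x[[b]]^2)))
  invisible(x)
}

#' Extract the HH detail subband at a given pyramid level
#'
#' Level 1 is the HH subband of a single decomposition; level 2 decomposes
#' the level-1 approximation (LL) again and takes its HH -- the standard
#' Mallat pyramid, which recurses on the approximation, not on a detail
#' band. Levels beyond 2 are outside the validated scope of the method and
#' require \code{allow_deep = TRUE}.
#'
#' @inheritParams dwt2
#' @param level decomposition level, 1 or 2.
#' @param allow_deep permit levels > 2 (untested territory; off by default).
#' @return numeric matrix of HH coefficients at the requested level.
#' @export
extract_hh <- function(image, level = 1L, wavelet = db4_wavelet(),
                       allow_deep = FALSE) {
  if (length(level) != 1L || level != as.integer(level) || level < 1L)
    stop("level must be a positive integer")
  if (level > 2L && !allow_deep)
    stop("level must be 1 or 2 (set allow_deep = TRUE to go deeper)")
  level <- as.integer(level)
  cur <- image
  for (l in seq_len(level - 1L)) cur <- dwt2(cur, wavelet)$LL
  dwt2(cur, wavelet)$HH
}
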