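#' Configuration of the synthetic screening-image generator
#'
#' The generator emulates the structural premise of texture-based screening:
#' normal tissue is a smooth, spatially correlated background, while
#' pathology adds abrupt, high-contrast, high-frequency structure -- small
#' bright spots (scattered or clustered, the microcalcification archetype)
#' and optionally one oriented bright streak that exercises the directional
#' selectivity of the Gabor bank. It makes no attempt at modality-specific
#' realism (film grain, vasculature, anatomy); it is the minimal texture
#' model the method claims to discriminate.
#'
#' Generation is a pure function of the configuration: image \code{index}
#' and the class stream are folded into the seed, so datasets are
#' reproducible element-wise.
#'
#' @param image_size integer (H, W) in pixels.
#' @param n_per_class images per class in [synth_dataset()].
#' @param background_smoothness Gaussian blur sd (pixels) applied to the
#'   white-noise background; larger means smoother, more correlated tissue.
#' @param spot_count bright discs per abnormal image.
#' @param spot_radius disc radius in pixels.
#' @param spot_amplitude intensity offset of anomalies, in [0, 1]
#'   (0 is the null anomaly: abnormal images then equal their normal
#'   counterparts).
#' @param streak_enabled add one oriented bright line segment per abnormal
#'   image.
#' @param streak_angle streak orientation, radians.
#' @param seed master seed; every image derives its own stream from it.
#' @return an object of class \code{"synth_config"}.
#' @export
synth_config <- function(image_size = c(128L, 128L), n_per_class = 40L,
                         background_smoothness = 4, spot_count = 5L,
                         spot_radius = 2L, spot_amplitude = 0.25,
                         streak_enabled = TRUE, streak_angle = pi / 4,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            n_per_class >= 1L, background_smoothness > 0,
            spot_count >= 0L, spot_radius >= 1L,
            spot_amplitude >= 0, spot_amplitude <= 1,
            is.logical(streak_enabled), is.finite(streak_angle))
  structure(list(image_size = image_size,
                 n_per_class = as.integer(n_per_class),
                 background_smoothness = background_smoothness,
                 spot_count = as.integer(spot_count),
                 spot_radius = as.integer(spot_radius),
                 spot_amplitude = spot_amplitude,
                 streak_enabled = streak_enabled,
                 streak_angle = streak_angle,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Separable Gaussian blur with symmetric boundary handling.
gaussian_blur <- function(x, sd) {
  hw <- max(1L, as.integer(ceiling(3 * sd)))
  k <- stats::dnorm(seq.int(-hw, hw), sd = sd)
  k <- k / sum(k)
  blur_cols <- function(m) {
    ri <- reflect_index(seq_len(nrow(m) + 2L * hw) - hw, nrow(m))
    ext <- m[ri, , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * ext[seq_len(nrow(m)) + j - 1L, , drop = FALSE]
    out
  }
  t(blur_cols(t(blur_cols(x))))
}

#' Generate one normal (smooth-background) image
#'
#' Low-pass-filtered Gaussian white noise, rescaled to the unit interval:
#' a spatially correlated field with no high-frequency anomalies.
#'
#' @param config a [synth_config()].
#' @param index image index within its class; together with the config seed
#'   it determines the image completely.
#' @return numeric matrix in [0, 1].
#' @export
synth_normal <- function(config, index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$image_size[1]
  w <- config$image_size[2]
  with_seed(derive_seed(config$seed, index, stream = 0L), {
    field <- gaussian_blur(matrix(stats::rnorm(h * w), h, w),
                           config$background_smoothness)
    rng <- range(field)
    if (diff(rng) == 0) matrix(0.5, h, w)
    else (field - rng[1]) / diff(rng)
  })
}

#' Generate one abnormal image
#'
#' The normal image of the same \code{index} plus \code{spot_count}
#' hard-edged bright discs at seeded random positions and, if enabled, one
#' bright oriented line segment; intensities are clipped to 1. Anomaly
#' placement avoids a 4-pixel border. With zero-effect settings
#' (\code{spot_count = 0}, streak disabled) the output is identical to
#' [synth_normal()].
#'
#' @inheritParams synth_normal
#' @return numeric matrix in [0, 1].
#' @export
synth_abnormal <- function(config, index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  img <- synth_normal(config, index)
  h <- nrow(img)
  w <- ncol(img)
  r <- config$spot_radius
  border <- 4L + r
  if (config$spot_count > 0L && (h - 2L * border < 1L || w - 2L * border < 1L))
    stop("spot radius too large for the image size: discs would cross the border")
  with_seed(derive_seed(config$seed, index, stream = 1L), {
    if (config$spot_count > 0L) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (s in seq_len(config$spot_count)) {
        cy <- sample.int(h - 2L * border, 1L) + border
        cx <- sample.int(w - 2L * border, 1L) + border
        disc <- (rows - cy)^2 + (cols - cx)^2 <= r^2
        img[disc] <- img[disc] + config$spot_amplitude
      }
    }
    if (config$streak_enabled) {
      len <- max(8L, as.integer(round(min(h, w) / 3)))
      margin <- 5L + len %/% 2L
      if (h - 2L * margin < 1L || w - 2L * margin < 1L)
        stop("streak too long for the image size")
      cy <- sample.int(h - 2L * margin, 1L) + margin
      cx <- sample.int(w - 2L * margin, 1L) + margin
      t_off <- seq.int(-(len %/% 2L), len %/% 2L)
      py <- round(cy + t_off * sin(config$streak_angle))
      px <- round(cx + t_off * cos(config$streak_angle))
      img[cbind(py, px)] <- img[cbind(py, px)] + config$spot_amplitude
    }
  })
  pmin(img, 1)
}

#' Generate a balanced labeled dataset
#'
#' \code{n_per_class} normal images (label -1) followed by
#' \code{n_per_class} abnormal images (label +1), with stable ids.
#'
#' @param config a [synth_config()].
#' @return list with \code{images} (list of matrices), \code{labels}
#'   (numeric -1/+1) and \code{ids} (character).
#' @export
synth_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_per_class
  normals <- lapply(seq_len(n), function(i) synth_normal(config, i))
  abnormals <- lapply(seq_len(n), function(i) synth_abnormal(config, i + n))
  list(images = c(normals, abnormals),
       labels = c(rep(-1, n), rep(1, n)),
       ids = c(sprintf("normal_%03d", seq_len(n)),
               sprintf("abnormal_%03d", seq_len(n))))
}
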