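#' Fit a wavelet-Gabor texture classifier
#'
#' The package's main modelling interface. Extracts one texture feature
#' vector per image ([texture_features()]) and trains a degree-2
#' polynomial-kernel SVM ([svm_train()]) to discriminate abnormal (+1) from
#' normal (-1) images. The default mode is the hybrid pipeline: HH wavelet
#' subband, Gabor bank, entropy/uniformity of each response.
#'
#' @param images list of numeric matrices (grayscale intensities).
#' @param labels per-image labels in \{-1, +1\} (-1 normal, +1 abnormal).
#' @param mode feature mode, see [texture_features()].
#' @param level DWT decomposition level (1 or 2; ignored for
#'   \code{mode = "gabor"}).
#' @param wavelet a [wavelet_spec()].
#' @param bank a [gabor_bank()].
#' @param n_bins histogram resolution for the entropy/uniformity features.
#' @param cost,degree SVM hyperparameters.
#' @param ids optional per-image identifiers.
#' @return an object of class \code{"dwtgabor"} with components
#'   \code{features} (matrix), \code{labels}, \code{model} (a
#'   \code{"poly_svm"}), \code{config} and \code{ids}. Methods:
#'   \code{print}, \code{summary}, \code{predict}, \code{fitted},
#'   \code{plot}.
#' @examples
#' d <- synth_dataset(synth_config(n_per_class = 12, image_size = c(64, 64)))
#' fit <- dwtgabor(d$images, d$labels, mode = "dwt", level = 1)
#' fit
#' table(truth = d$labels, fitted = fitted(fit))
#' @export
dwtgabor <- function(images, labels, mode = c("dwt_gabor", "dwt", "gabor"),
                     level = 1L, wavelet = db4_wavelet(),
                     bank = gabor_bank(), n_bins = 256L,
                     cost = 1, degree = 2L, ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(images), length(images) == length(labels))
  feats <- t(vapply(images,
                    function(im) texture_features(im, mode, level, wavelet,
                                                  bank, n_bins),
                    texture_features(images[[1]], mode, level, wavelet,
                                     bank, n_bins)))
  model <- svm_train(feats, labels, cost = cost, degree = degree)
  structure(list(features = feats,
                 labels = as.numeric(as.character(labels)),
                 model = model,
                 ids = ids %||% sprintf("img_%03d", seq_along(images)),
                 config = list(mode = mode, level = as.integer(level),
                               wavelet = wavelet, bank = bank,
                               n_bins = as.integer(n_bins),
                               cost = cost, degree = as.integer(degree))),
            class = "dwtgabor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dwtgabor <- function(x, ...) {
  cat("wavelet-Gabor texture classifier\n")
  cat(sprintf("  mode: %s%s, %d features, %d images (%d abnormal / %d normal)\n",
              x$config$mode,
              if (x$config$mode == "gabor") "" else
                paste0(" (DWT level ", x$config$level, ")"),
              ncol(x$features), nrow(x$features),
              sum(x$labels == 1), sum(x$labels == -1)))
  print(x$model)
  tr <- classification_metrics(fitted(x), x$labels)
  cat(sprintf("  training CCR %.1f%%\n", 100 * tr[["ccr"]]))
  invisible(x)
}

#' @param object,x a \code{"dwtgabor"} fit.
#' @param newdata list of image matrices, or an already-extracted feature
#'   matrix with the same columns as \code{object$features}.
#' @param ... unused.
#' @rdname dwtgabor
#' @export
predict.dwtgabor <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  feats <- if (is.list(newdata) && !is.data.frame(newdata)) {
    cfg <- object$config
    t(vapply(newdata,
             function(im) texture_features(im, cfg$mode, cfg$level,
                                           cfg$wavelet, cfg$bank,
                                           cfg$n_bins),
             numeric(ncol(object$features))))
  } else as.matrix(newdata)
  predict(object$model, feats)
}

#' @rdname dwtgabor
#' @export
fitted.dwtgabor <- function(object, ...) {
  predict(object$model, object$features)
}

#' @export
summary.dwtgabor <- function(object, ...) {
  print(object)
  cat("\nTraining confusion matrix:\n")
  print(table(truth = object$labels, predicted = fitted(object)))
  cat("\nFeature summary (per column):\n")
  print(round(apply(object$features, 2, summary), 4))
  invisible(object)
}

#' @param which_features columns of the feature matrix to plot (default the
#'   first entropy and first uniformity component).
#' @rdname dwtgabor
#' @export
plot.dwtgabor <- function(x, which_features = NULL, ...) {
  p <- ncol(x$features)
  wf <- which_features %||% if (p == 2L) 1:2 else c(1L, p %/% 2L + 1L)
  cols <- ifelse(x$labels == 1, "firebrick", "steelblue")
  graphics::plot(x$features[, wf[1]], x$features[, wf[2]], col = cols,
                 pch = ifelse(x$labels == 1, 17, 1),
                 xlab = colnames(x$features)[wf[1]],
                 ylab = colnames(x$features)[wf[2]],
                 main = sprintf("texture features (%s)", x$config$mode), ...)
  graphics::legend("topleft", legend = c("abnormal", "normal"),
                   col = c("firebrick", "steelblue"), pch = c(17, 1),
                   bty = "n")
  invisible(x)
}

#' Cross-validated evaluation of a feature mode
#'
#' Convenience wrapper: extracts features for every image once, then runs
#' [cross_validate()] on them.
#'
#' @inheritParams dwtgabor
#' @param protocol,seed,folds passed to [cross_validate()].
#' @return a \code{"cv_report"} (see [cross_validate()]) with the feature
#'   configuration attached as attribute \code{"config"}.
#' @export
cv_dwtgabor <- function(images, labels, mode = c("dwt_gabor", "dwt", "gabor"),
                        level = 1L, wavelet = db4_wavelet(),
                        bank = gabor_bank(), n_bins = 256L,
                        cost = 1, degree = 2L,
                        protocol = c("tenfold", "loocv"), seed = 1L,
                        folds = NULL) {
  mode <- match.arg(mode)
  feats <- t(vapply(images,
                    function(im) texture_features(im, mode, level, wavelet,
                                                  bank, n_bins),
                    texture_features(images[[1]], mode, level, wavelet,
                                     bank, n_bins)))
  rep <- cross_validate(feats, labels, cost = cost, degree = degree,
                        protocol = protocol, seed = seed, folds = folds)
  attr(rep, "config") <- list(mode = mode, level = as.integer(level),
                              n_bins = as.integer(n_bins))
  attr(rep, "features") <- feats
  rep
}
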