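#' Polynomial kernel
#'
#' \eqn{K(x, x_i) = (\langle x_i, x\rangle + 1)^d}. Degree 2 (the package
#' default throughout) realises quadratic decision boundaries and in
#' particular separates XOR-type configurations a linear machine cannot.
#'
#' @param x,y numeric vectors of equal length.
#' @param degree polynomial degree d >= 1.
#' @return scalar kernel value.
#' @export
poly_kernel <- function(x, y, degree = 2L) {
  if (length(x) != length(y))
    stop("kernel arguments must have equal length")
  stopifnot(degree >= 1)
  (sum(x * y) + 1)^degree
}

#' Train a soft-margin SVM with a polynomial kernel
#'
#' Solves the soft-margin dual (penalty \code{cost} on slack) for labels in
#' \{-1, +1\} via libsvm (through e1071), configured so the kernel is
#' exactly \code{(<x_i, x> + 1)^degree}. The returned object carries the
#' support vectors, dual coefficients \eqn{y_i \alpha_i^*} and bias
#' \eqn{b^*}, from which [svm_decision()] evaluates the discriminant
#' \eqn{\sum_i y_i\alpha_i^* K(x, x_i) + b^*} directly -- prediction does
#' not go back through libsvm.
#'
#' @param x numeric feature matrix, one row per sample.
#' @param y labels, coercible to \{-1, +1\}; both classes must be present.
#' @param cost penalty parameter C > 0 of the slack term.
#' @param degree polynomial kernel degree.
#' @return an object of class \code{"poly_svm"}: list with
#'   \code{support_vectors}, \code{dual_coefs}, \code{bias}, \code{cost},
#'   \code{degree}, \code{n_features}.
#' @export
svm_train <- function(x, y, cost = 1, degree = 2L) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite")
  y <- as.numeric(as.character(y))
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 (normal) or +1 (abnormal)")
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  stopifnot(cost > 0, degree >= 1)
  fy <- factor(y, levels = c(-1, 1))
  fit <- e1071::svm(x, fy, scale = FALSE, type = "C-classification",
                    kernel = "polynomial", degree = degree, gamma = 1,
                    coef0 = 1, cost = cost, tolerance = 1e-6)
  model <- structure(list(support_vectors = unname(as.matrix(fit$SV)),
                          dual_coefs = as.numeric(fit$coefs),
                          bias = -fit$rho,
                          sign = 1,
                          cost = cost, degree = as.integer(degree),
                          n_features = ncol(x)),
                     class = "poly_svm")
  # libsvm orients its decision values towards whichever class it met first;
  # fix the orientation so positive decision values mean class +1.
  raw <- svm_decision(model, x)
  agree <- mean((raw >= 0) == (predict(fit, x) == "1"))
  if (agree < 0.5) model$sign <- -1
  model
}

#' Decision values of a trained polynomial SVM
#'
#' Evaluates \eqn{g_0(x) = \sum_i y_i \alpha_i^* K(x, x_i) + b^*} for each
#' row of \code{newx}, oriented so positive values vote for class +1
#' (abnormal).
#'
#' @param model a \code{"poly_svm"} from [svm_train()].
#' @param newx numeric matrix (or single vector) of query points.
#' @return numeric vector of decision values.
#' @export
svm_decision <- function(model, newx) {
  stopifnot(inherits(model, "poly_svm"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  newx <- as.matrix(newx)
  if (ncol(newx) != model$n_features)
    stop("query dimensionality (", ncol(newx),
         ") does not match training dimensionality (", model$n_features, ")")
  gram <- (tcrossprod(newx, model$support_vectors) + 1)^model$degree
  model$sign * (as.numeric(gram %*% model$dual_coefs) + model$bias)
}

#' @param object a \code{"poly_svm"} model.
#' @param newx query matrix or vector.
#' @param ... unused.
#' @return labels in \{-1, +1\}. A decision value of exactly 0 is classified
#'   +1 (abnormal) -- the conservative tie rule for a screening setting.
#' @rdname svm_train
#' @export
predict.poly_svm <- function(object, newx, ...) {
  ifelse(svm_decision(object, newx) >= 0, 1, -1)
}

#' @export
print.poly_svm <- function(x, ...) {
  cat(sprintf(
    "polynomial-kernel SVM (degree %d, C = %g): %d support vectors, %d features\n",
    x$degree, x$cost, length(x$dual_coefs), x$n_features))
  invisible(x)
}

#' Binary screening performance metrics
#'
#' The correct classification rate, sensitivity and specificity of a set of
#' predictions, with abnormal (+1) as the positive class:
#' CCR = correct / total, sensitivity = correct positives / true positives,
#' specificity = correct negatives / true negatives. A class absent from
#' \code{truth} makes the corresponding rate undefined; it is returned as
#' \code{NA} with \code{attr(, "undefined")} naming the metric, never an
#' error.
#'
#' @param predicted,truth equal-length label vectors in \{-1, +1\}.
#' @return named numeric vector \code{c(ccr, sensitivity, specificity)}.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (length(truth) < 1L) stop("empty prediction set")
  pos <- truth == 1
  neg <- truth == -1
  out <- c(ccr = mean(predicted == truth),
           sensitivity = if (any(pos)) mean(predicted[pos] == 1) else NA_real_,
           specificity = if (any(neg)) mean(predicted[neg] == -1) else NA_real_)
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{k} folds by seeded within-class
#' shuffling followed by round-robin allocation, so every fold's class
#' ratio is within one sample of the global ratio.
#'
#' @param labels label vector in \{-1, +1\}.
#' @param k number of folds.
#' @param seed RNG seed (the caller's RNG state is left untouched).
#' @return integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  stopifnot(k >= 2L, k <= n)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated SVM evaluation
#'
#' Runs the full evaluation protocol on a precomputed feature matrix:
#' stratified tenfold cross-validation or leave-one-out, each sample tested
#' exactly once, with per-fold and aggregate (mean and sd) CCR, sensitivity
#' and specificity. Deterministic given \code{seed}.
#'
#' Per-fold sensitivity or specificity is undefined when a test fold
#' contains no sample of the relevant class (always the case under
#' leave-one-out, where each fold is a single image); undefined entries are
#' excluded from the mean and sd, and pooled whole-protocol metrics over
#' all held-out predictions are reported alongside.
#'
#' @param x feature matrix, one row per sample.
#' @param labels labels in \{-1, +1\}.
#' @param cost,degree SVM hyperparameters, see [svm_train()].
#' @param protocol \code{"tenfold"} (needs >= 10 samples per class) or
#'   \code{"loocv"} (needs >= 3 samples).
#' @param seed seed for fold construction.
#' @param folds optional precomputed fold assignment (overrides
#'   \code{protocol}'s own construction; used to evaluate several feature
#'   modes on identical folds).
#' @return an object of class \code{"cv_report"}: list with \code{per_fold}
#'   (data frame of fold metrics), \code{mean}, \code{sd}, \code{pooled},
#'   \code{predictions}, \code{protocol}, \code{seed}, \code{cost},
#'   \code{degree}, \code{folds}.
#' @export
cross_validate <- function(x, labels, cost = 1, degree = 2L,
                           protocol = c("tenfold", "loocv"), seed = 1L,
                           folds = NULL) {
  protocol <- match.arg(protocol)
  x <- as.matrix(x)
  labels <- as.numeric(as.character(labels))
  n <- length(labels)
  if (nrow(x) != n) stop("x and labels sizes disagree")
  if (is.null(folds)) {
    if (protocol == "tenfold") {
      if (min(table(labels)) < 10L)
        stop("tenfold cross-validation needs at least 10 samples per class")
      folds <- stratified_folds(labels, 10L, seed)
    } else {
      if (n < 3L) stop("leave-one-out needs at least 3 samples")
      folds <- seq_len(n)
    }
  }
  k <- max(folds)
  preds <- numeric(n)
  per_fold <- data.frame(fold = seq_len(k), n_test = 0L,
                         ccr = NA_real_, sensitivity = NA_real_,
                         specificity = NA_real_)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- svm_train(x[!test, , drop = FALSE], labels[!test],
                       cost = cost, degree = degree)
    preds[test] <- predict(model, x[test, , drop = FALSE])
    m <- classification_metrics(preds[test], labels[test])
    per_fold[f, c("n_test", "ccr", "sensitivity", "specificity")] <-
      c(sum(test), m)
  }
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0)
  mm <- vapply(per_fold[c("ccr", "sensitivity", "specificity")], agg,
               numeric(2))
  n_undef <- sum(is.na(per_fold$sensitivity)) + sum(is.na(per_fold$specificity))
  if (n_undef > 0L)
    message(n_undef,
            " undefined per-fold sensitivity/specificity value(s) excluded",
            " from the mean/sd aggregation")
  structure(list(per_fold = per_fold,
                 mean = mm["mean", ], sd = mm["sd", ],
                 pooled = classification_metrics(preds, labels),
                 predictions = preds, folds = folds,
                 protocol = protocol, seed = seed,
                 cost = cost, degree = as.integer(degree)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 2, ...) {
  cat(sprintf("%s cross-validation (%d folds, seed %d, C = %g, degree %d)\n",
              x$protocol, nrow(x$per_fold), x$seed, x$cost, x$degree))
  for (m in c("ccr", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %5.2f%% (sd %.2f)\n", m,
                100 * x$mean[[m]], 100 * x$sd[[m]]))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  cat("Per-fold metrics:\n")
  print(object$per_fold, row.names = FALSE)
  cat("\nPooled over all held-out predictions:\n")
  print(round(100 * object$pooled, 2))
  invisible(object)
}
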