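test_that("polynomial kernel matches hand computation and is a valid Mercer kernel", {
  expect_equal(poly_kernel(c(0, 0), c(0, 0), 2), 1)
  expect_equal(poly_kernel(c(1, 2), c(3, 4), 2), 144)   # (11 + 1)^2
  x <- c(0.3, -1.2, 2); y <- c(1.5, 0.4, -0.7)
  expect_equal(poly_kernel(x, y, 1), sum(x * y) + 1)
  expect_error(poly_kernel(1:3, 1:2), "equal length")
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(poly_kernel(a, b), poly_kernel(b, a))
  }
  # Gram matrix positive semidefinite on random small datasets
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    K <- (tcrossprod(X) + 1)^2
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("the degree-2 machine separates XOR and a linear toy set", {
  xor_x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_y <- c(-1, -1, 1, 1)
  m <- svm_train(xor_x, xor_y, cost = 10, degree = 2)
  expect_identical(predict(m, xor_x), xor_y)
  expect_identical(predict(m, c(0.9, 0.1)), 1)
  # linearly separable 4-point set with margin 2 about x1 = 2
  toy_x <- rbind(c(1, 0), c(1, 1), c(3, 0), c(3, 1))
  toy_y <- c(-1, -1, 1, 1)
  mt <- svm_train(toy_x, toy_y, cost = 10, degree = 2)
  expect_identical(predict(mt, toy_x), toy_y)
  expect_lte(length(mt$dual_coefs), 3)
  # a hard-margin support vector is classified as its own label
  sv1 <- mt$support_vectors[1, ]
  expect_identical(predict(mt, sv1),
                   toy_y[which.min(colSums((t(toy_x) - sv1)^2))])
})

test_that("training validates its inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(svm_train(x, rep(1, 5)), "both classes")
  expect_error(svm_train(x, c(0, 1, 1, -1, -1)), "-1")
  x[1, 1] <- Inf
  expect_error(svm_train(x, c(-1, -1, 1, 1, 1)), "finite")
  m <- svm_train(matrix(rnorm(12), 6, 2), c(-1, -1, -1, 1, 1, 1))
  expect_error(predict(m, c(1, 2, 3)), "dimensionality")
})

test_that("the in-package decision function reproduces libsvm's predictions", {
  set.seed(33)
  x <- rbind(matrix(rnorm(60, -0.4), 30, 2), matrix(rnorm(60, 0.4), 30, 2))
  y <- rep(c(-1, 1), each = 30)
  m <- svm_train(x, y, cost = 1, degree = 2)
  ref <- e1071::svm(x, factor(y, levels = c(-1, 1)), scale = FALSE,
                    type = "C-classification", kernel = "polynomial",
                    degree = 2, gamma = 1, coef0 = 1, cost = 1,
                    tolerance = 1e-6)
  probe <- matrix(rnorm(100), 50, 2)
  expect_identical(predict(m, probe),
                   as.numeric(as.character(predict(ref, probe))))
  # dual coefficients respect the box constraint 0 <= alpha <= C
  expect_true(all(abs(m$dual_coefs) <= 1 + 1e-8))
})

test_that("duplicating every sample of a hard-margin fit leaves the decision unchanged", {
  set.seed(35)
  x <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  m1 <- svm_train(x, y, cost = 10, degree = 2)
  m2 <- svm_train(rbind(x, x), c(y, y), cost = 10, degree = 2)
  probe <- as.matrix(expand.grid(seq(-4, 4, length = 7), seq(-4, 4, length = 7)))
  expect_lt(max(abs(svm_decision(m1, probe) - svm_decision(m2, probe))), 1e-6)
})

test_that("a zero decision value classifies as abnormal (tie rule)", {
  model <- structure(list(support_vectors = matrix(c(1, 0), 1, 2),
                          dual_coefs = 1, bias = -1, sign = 1,
                          cost = 1, degree = 1L, n_features = 2L),
                     class = "poly_svm")
  # decision at (0, 5): (1*0 + 0*5 + 1)^1 - 1 = 0 exactly
  expect_identical(svm_decision(model, c(0, 5)), 0)
  expect_identical(predict(model, c(0, 5)), 1)
})

test_that("screening metrics match hand-counted confusion tables", {
  expect_equal(unname(classification_metrics(c(1, 1, -1, -1), c(1, 1, -1, -1))),
               c(1, 1, 1))
  m <- classification_metrics(c(1, -1, -1, -1), c(1, 1, -1, -1))
  expect_equal(unname(m), c(0.75, 0.5, 1))
  m2 <- classification_metrics(rep(1, 4), c(1, 1, -1, -1))
  expect_equal(unname(m2), c(0.5, 1, 0))
  # class absent from truth: flagged NA, not an error
  m3 <- classification_metrics(c(1, -1), c(1, 1))
  expect_true(is.na(m3[["specificity"]]))
  expect_identical(attr(m3, "undefined"), "specificity")
  expect_error(classification_metrics(1, c(1, -1)), "equal length")
})

test_that("metric identities hold on random predictions", {
  set.seed(41)
  for (i in 1:10) {
    truth <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    pred <- sample(c(-1, 1), 30, replace = TRUE)
    m <- classification_metrics(pred, truth)
    np <- sum(truth == 1); nn <- sum(truth == -1)
    # CCR is the prevalence-weighted average of sensitivity and specificity
    expect_equal(m[["ccr"]],
                 (m[["sensitivity"]] * np + m[["specificity"]] * nn) / (np + nn))
    # negating all labels swaps sensitivity and specificity exactly
    mf <- classification_metrics(-pred, -truth)
    expect_identical(mf[["sensitivity"]], m[["specificity"]])
    expect_identical(mf[["specificity"]], m[["sensitivity"]])
  }
})

test_that("stratified folds partition each class evenly", {
  set.seed(43)
  labels <- c(rep(-1, 60), rep(1, 40))
  folds <- stratified_folds(labels, 10, seed = 5)
  expect_setequal(unique(folds), 1:10)
  expect_true(all(table(folds) == 10))
  for (f in 1:10) {
    ratio <- sum(labels[folds == f] == 1)
    expect_true(abs(ratio - 4) <= 1)
  }
  # deterministic given the seed, independent of the ambient RNG state
  set.seed(999)
  expect_identical(folds, stratified_folds(labels, 10, seed = 5))
})

test_that("cross-validation protocols test every sample exactly once", {
  set.seed(47)
  x <- rbind(matrix(rnorm(40, -1), 20, 2), matrix(rnorm(40, 1), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  r <- suppressMessages(cross_validate(x, y, protocol = "loocv"))
  expect_identical(nrow(r$per_fold), 40L)
  expect_true(all(r$per_fold$n_test == 1L))
  # tenfold on 100 samples: 10 disjoint folds of 10 covering everything
  x100 <- rbind(matrix(rnorm(100, -1), 50, 2), matrix(rnorm(100, 1), 50, 2))
  y100 <- rep(c(-1, 1), each = 50)
  r10 <- cross_validate(x100, y100, protocol = "tenfold", seed = 3)
  expect_true(all(table(r10$folds) == 10))
  expect_identical(sort(unique(r10$folds)), 1:10)
  expect_identical(nrow(r10$per_fold), 10L)
  # identical inputs and seed give identical reports
  r10b <- cross_validate(x100, y100, protocol = "tenfold", seed = 3)
  expect_identical(r10, r10b)
  # protocol sample-size preconditions
  expect_error(cross_validate(x[c(1:5, 21:25), ], y[c(1:5, 21:25)],
                              protocol = "tenfold"),
               "10 samples per class")
  expect_error(cross_validate(x[1:2, ], y[c(1, 21)], protocol = "loocv"),
               "at least 3")
})

test_that("undefined per-fold rates are excluded from aggregation with a note", {
  set.seed(53)
  x <- rbind(matrix(rnorm(20, -2), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  expect_message(r <- cross_validate(x, y, protocol = "loocv"), "undefined")
  expect_false(anyNA(r$mean))
  expect_equal(r$mean[["ccr"]], r$pooled[["ccr"]])
})
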