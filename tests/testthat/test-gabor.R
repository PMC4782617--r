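test_that("coordinate rotation matches its closed form and preserves norms", {
  r <- rotate_coords(3, 5, 0)
  expect_equal(c(r$x, r$y), c(3, 5))
  r <- rotate_coords(1, 0, pi / 2)
  expect_equal(c(r$x, r$y), c(0, -1))
  r <- rotate_coords(1, 1, pi / 4)
  expect_equal(c(r$x, r$y), c(sqrt(2), 0))
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(1); y <- rnorm(1); th <- runif(1, 0, 2 * pi)
    r <- rotate_coords(x, y, th)
    expect_equal(r$x^2 + r$y^2, x^2 + y^2)
  }
})

test_that("kernel samples equal the Gaussian-times-cosine closed form", {
  k <- gabor_kernel(gabor_params(1, 1, 2, 0))
  expect_identical(dim(k$weights), c(7L, 7L))
  expect_identical(k$weights[k$center, k$center], 1)      # exp(0) cos(0)
  # at offset (x=1, y=0), f=2: cos(4*pi) = 1, envelope exp(-1/2)
  expect_equal(k$weights[k$center, k$center + 1L], exp(-0.5))
  # at (x=0, y=2): carrier at x'=0, envelope exp(-2)
  expect_equal(k$weights[k$center + 2L, k$center], exp(-2))
  expect_true(all(abs(k$weights) <= 1))
  # rotated, anisotropic case against direct evaluation
  p <- gabor_params(1.5, 0.8, 2.5, pi / 3)
  k2 <- gabor_kernel(p)
  x <- 2; y <- -1
  xr <- x * cos(p$theta) + y * sin(p$theta)
  yr <- y * cos(p$theta) - x * sin(p$theta)
  expect_equal(k2$weights[k2$center + y, k2$center + x],
               exp(-0.5 * ((xr / 1.5)^2 + (yr / 0.8)^2)) * cos(2 * pi * 2.5 * xr))
})

test_that("kernels are even under point reflection and under a half-turn of theta", {
  for (th in c(0, pi / 4, pi / 2, 1.1)) {
    k <- gabor_kernel(gabor_params(1, 2, 2.5, th))$weights
    flipped <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))]
    expect_equal(k, flipped, tolerance = 1e-15)
    k2 <- gabor_kernel(gabor_params(1, 2, 2.5, th + pi))$weights
    expect_equal(k, k2, tolerance = 1e-12)
  }
})

test_that("invalid Gabor parameters are rejected", {
  expect_error(gabor_params(-1, 1, 2, 0), "sigma_x")
  expect_error(gabor_params(1, 0, 2, 0), "sigma_y")
  expect_error(gabor_params(1, 1, -2, 0), "freq")
  expect_error(gabor_params(1, 1, 2, NA), "finite")
})

test_that("spatial filtering equals the brute-force double-sum convolution", {
  set.seed(21)
  for (rep in 1:20) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    k <- gabor_kernel(gabor_params(runif(1, 0.5, 1.5), runif(1, 0.5, 1.5),
                                   runif(1, 1, 3), runif(1, 0, pi)))
    expect_lt(max(abs(convolve2(img, k) - oracle_conv2(img, k$weights))), 1e-10)
  }
  # asymmetric kernel exercises the flip
  w <- matrix(rnorm(15), 3, 5)
  img <- matrix(rnorm(12 * 12), 12, 12)
  expect_lt(max(abs(convolve2(img, w) - oracle_conv2(img, w))), 1e-10)
})

test_that("convolution identities: zero image, impulse image", {
  k <- gabor_kernel(gabor_params(1, 1, 2, pi / 4))
  expect_equal(convolve2(matrix(0, 10, 10), k), matrix(0, 10, 10))
  # an interior impulse reproduces the kernel, shifted to the impulse
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  out <- convolve2(img, k)
  expect_equal(out[8 + (-3:3), 8 + (-3:3)], k$weights)
  # same identity for an asymmetric kernel (true convolution, no flip in output)
  w <- matrix(seq_len(9) / 9, 3, 3)
  outw <- convolve2(img, w)
  expect_equal(outw[8 + (-1:1), 8 + (-1:1)], w)
})

test_that("bank enumeration is frequency-major with |f| x |theta| outputs", {
  img <- matrix(runif(16 * 16), 16, 16)
  out <- apply_bank(img, gabor_bank())
  expect_length(out, 12)
  expect_true(all(vapply(out, function(m) identical(dim(m), dim(img)), TRUE)))
  # frequency-major, orientation-minor order
  expect_identical(names(out)[1:4],
                   c("f2_t0.000", "f2_t0.785", "f2_t1.571", "f2_t2.356"))
  expect_identical(names(out)[5], "f2.5_t0.000")
  # arbitrary bank sizes
  b <- gabor_bank(frequencies = c(1, 2), orientations = c(0, pi / 3, 2))
  expect_length(apply_bank(img, b), 6)
  # singleton bank equals a single filter application
  b1 <- gabor_bank(frequencies = 2, orientations = pi / 4)
  k1 <- gabor_kernel(gabor_params(1, 1, 2, pi / 4))
  expect_equal(apply_bank(img, b1)[[1]], convolve2(img, k1))
  # zero image maps to 12 zero images
  zout <- apply_bank(matrix(0, 16, 16), gabor_bank())
  expect_true(all(vapply(zout, function(m) all(m == 0), TRUE)))
})

test_that("bank validation and the mammogram sigma scheme", {
  expect_error(gabor_bank(frequencies = numeric()), "non-empty")
  expect_error(gabor_bank(frequencies = -1), "positive")
  b <- gabor_bank(fwhm = 2.35)
  expect_equal(b$sigma_x, 1)
  expect_equal(b$sigma_y, 8)
  # elongated envelope enlarges the kernel support accordingly
  ks <- bank_kernels(b)
  expect_identical(dim(ks[[1]]$weights), c(49L, 49L))
})
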