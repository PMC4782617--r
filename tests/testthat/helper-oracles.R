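# Brute-force reference implementations, written as plain scalar loops and
# kept independent of the package's vectorized code paths.

# Fold an out-of-range index onto 1..n by half-sample mirror reflection.
ref_idx <- function(k, n) {
  while (k < 1L || k > n) {
    if (k < 1L) k <- 1L - k
    if (k > n) k <- 2L * n + 1L - k
  }
  k
}

# Decimated filtering of one signal: convolve with `taps` under symmetric
# extension, keep every second sample, ceil(n/2) outputs.
oracle_dwt_step <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  out <- numeric(ceiling(n / 2))
  for (i in seq_along(out)) {
    s <- 0
    for (j in seq_len(L)) s <- s + taps[j] * x[ref_idx(2L * i + j - L - 1L, n)]
    out[i] <- s
  }
  out
}

# Full separable decomposition: filter/decimate every row with g and h,
# then every column of each result.
oracle_dwt2 <- function(img, wavelet) {
  g <- wavelet$lowpass
  h <- wavelet$highpass
  step_rows <- function(m, taps) {
    out <- matrix(0, nrow(m), ceiling(ncol(m) / 2))
    for (r in seq_len(nrow(m))) out[r, ] <- oracle_dwt_step(m[r, ], taps)
    out
  }
  step_cols <- function(m, taps) {
    out <- matrix(0, ceiling(nrow(m) / 2), ncol(m))
    for (c in seq_len(ncol(m))) out[, c] <- oracle_dwt_step(m[, c], taps)
    out
  }
  lo <- step_rows(img, g)
  hi <- step_rows(img, h)
  list(LL = step_cols(lo, g), LH = step_cols(lo, h),
       HL = step_cols(hi, g), HH = step_cols(hi, h))
}

# Direct O(N^2 M^2) true 2D convolution with symmetric boundary handling.
oracle_conv2 <- function(img, w) {
  hr <- (nrow(w) - 1L) %/% 2L
  hc <- (ncol(w) - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      s <- 0
      for (a in seq_len(nrow(w))) {
        for (b in seq_len(ncol(w))) {
          s <- s + w[a, b] * img[ref_idx(i + hr + 1L - a, nrow(img)),
                                 ref_idx(j + hc + 1L - b, ncol(img))]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Count 4-connected components of a logical mask (breadth-first search).
count_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n_comp <- 0L
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (!mask[i0, j0] || seen[i0, j0]) next
      n_comp <- n_comp + 1L
      queue <- list(c(i0, j0))
      seen[i0, j0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          q <- p + d
          if (q[1] >= 1L && q[1] <= nrow(mask) && q[2] >= 1L &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  n_comp
}

# Small constructed histograms via the public API.
hist_from_pmf_thirds <- function() coef_histogram(c(0, 0, 1, 2), n_bins = 3)
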