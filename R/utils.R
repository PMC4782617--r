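# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Fold arbitrary integer positions onto 1..n by half-sample ("symmetric")
# reflection: ..., x2, x1 | x1, x2, ..., xn | xn, xn-1, ...
reflect_index <- function(k, n) {
  if (n == 1L) return(rep(1L, length(k)))
  pos <- (k - 1L) %% (2L * n)
  ifelse(pos < n, pos + 1L, 2L * n - pos)
}

# Pad a matrix by `p` samples on every side under half-sample reflection.
pad_symmetric <- function(x, p) {
  ri <- reflect_index(seq_len(nrow(x) + 2L * p) - p, nrow(x))
  ci <- reflect_index(seq_len(ncol(x) + 2L * p) - p, ncol(x))
  x[ri, ci, drop = FALSE]
}

check_image <- function(x, min_dim = 1L, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(x)))
    stop(arg, " contains non-finite values", call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(arg, " must be at least ", min_dim, "x", min_dim,
         " (got ", nrow(x), "x", ncol(x), ")", call. = FALSE)
  invisible(x)
}

# Derive a per-item RNG seed below 2^31 from (master seed, item index, stream).
derive_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + index * 69621 + stream * 16807
  as.integer(s %% 2147483629 + 1)
}
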