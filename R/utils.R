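# Internal numerical helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All package randomness funnels through this
# so fixed seeds are bit-reproducible without disturbing user sessions.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Shift a 3D array along one axis by `off` voxels with replicate (clamped)
# edge padding.
shift_clamped <- function(arr, axis, off) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])
  switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE]
  )
}

# Separable 1D filtering along `axis` with an odd-length kernel, replicate
# padding, correlation semantics: out[i] = sum_o kernel[o + r + 1] * in[i + o].
conv_axis <- function(arr, kernel, axis) {
  array(cpp_conv_axis(as.numeric(arr), as.integer(dim(arr)),
                      as.numeric(kernel), as.integer(axis)),
        dim(arr))
}

# Separable 3D convolution; any kernel may be NULL (skip that axis).
sep_conv3 <- function(arr, kx = NULL, ky = NULL, kz = NULL) {
  if (!is.null(kx)) arr <- conv_axis(arr, kx, 1L)
  if (!is.null(ky)) arr <- conv_axis(arr, ky, 2L)
  if (!is.null(kz)) arr <- conv_axis(arr, kz, 3L)
  arr
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_gaussian3 <- function(arr, sigma = c(1, 1, 1)) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    if (sigma[ax] > 0) arr <- conv_axis(arr, gaussian_kernel_1d(sigma[ax]), ax)
  }
  arr
}

# Sample skewness and excess kurtosis, Fisher definition, bias-uncorrected
# population moments; constant input maps to 0 by convention so degenerate
# texture maps never propagate NaN.
moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

# Monomial design matrix in normalized coordinates for total degree <= deg.
poly3d_design <- function(xs, ys, zs, deg = 3L) {
  cols <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) for (k in 0:(deg - i - j)) {
    cols[[length(cols) + 1L]] <- xs^i * ys^j * zs^k
  }
  do.call(cbind, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
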