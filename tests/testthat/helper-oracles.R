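# Brute-force reference implementations and shared fixtures. Every
# oracle here is an independent double-loop transcription of the
# operation it checks, deliberately avoiding the package's vectorized /
# compiled code paths.

# valid multi-channel cross-correlation + bias + ReLU
oracle_conv_relu <- function(x, kernels, biases) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  r <- dim(kernels)[1]
  oh <- dim(x)[1] - r + 1L
  ow <- dim(x)[2] - r + 1L
  out <- array(0, dim = c(oh, ow, dim(kernels)[4]))
  for (o in seq_len(dim(kernels)[4]))
    for (i in seq_len(oh))
      for (j in seq_len(ow)) {
        acc <- biases[o]
        for (ci in seq_len(dim(x)[3]))
          for (m in seq_len(r))
            for (n in seq_len(r))
              acc <- acc + x[i + m - 1L, j + n - 1L, ci] * kernels[m, n, ci, o]
        out[i, j, o] <- max(0, acc)
      }
  out
}

oracle_max_pool <- function(x, size, stride) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  oh <- (dim(x)[1] - size) %/% stride + 1L
  ow <- (dim(x)[2] - size) %/% stride + 1L
  out <- array(0, dim = c(oh, ow, dim(x)[3]))
  for (c in seq_len(dim(x)[3]))
    for (i in seq_len(oh))
      for (j in seq_len(ow)) {
        r0 <- (i - 1L) * stride + 1L
        c0 <- (j - 1L) * stride + 1L
        out[i, j, c] <- max(x[r0:(r0 + size - 1L), c0:(c0 + size - 1L), c])
      }
  out
}

# windowed RMSE with replicate padding, pixel by pixel
oracle_windowed_rmse <- function(x, y, win) {
  h <- win %/% 2L
  d <- x - y
  out <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d)))
    for (j in seq_len(ncol(d))) {
      acc <- 0
      for (di in -h:h)
        for (dj in -h:h) {
          ii <- min(max(i + di, 1L), nrow(d))
          jj <- min(max(j + dj, 1L), ncol(d))
          acc <- acc + d[ii, jj]^2
        }
      out[i, j] <- sqrt(acc / win^2)
    }
  out
}

# literal transcription of the three consistency rules on one pixel
oracle_consistency <- function(c, a, b, f) {
  h <- nrow(c); w <- ncol(c)
  f2 <- f; c2 <- c
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      s <- 0
      for (di in -1:1)
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- min(max(i + di, 1L), h)
          jj <- min(max(j + dj, 1L), w)
          s <- s + c[ii, jj]
        }
      if (s >= 5) { f2[i, j] <- a[i, j]; c2[i, j] <- 1L }
      else if (s <= 3) { f2[i, j] <- b[i, j]; c2[i, j] <- 0L }
    }
  list(f = f2, c = c2)
}

# binary erosion / dilation with a flat square SE, clipped at borders
oracle_erode <- function(m, se) {
  h <- se %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      ri <- max(1L, i - h):min(nrow(m), i + h)
      ci <- max(1L, j - h):min(ncol(m), j + h)
      out[i, j] <- as.integer(all(m[ri, ci] == 1))
    }
  out
}

oracle_dilate <- function(m, se) {
  h <- se %/% 2L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      ri <- max(1L, i - h):min(nrow(m), i + h)
      ci <- max(1L, j - h):min(ncol(m), j + h)
      out[i, j] <- as.integer(any(m[ri, ci] == 1))
    }
  out
}

oracle_open_close <- function(m, se) {
  oracle_erode(oracle_dilate(oracle_dilate(oracle_erode(m, se), se), se), se)
}

# SVD route to the same regularized least-squares system
oracle_ridge_svd <- function(H, T, C) {
  sv <- svd(H)
  d <- sv$d
  sv$v %*% ((d / (d^2 + 1 / C)) * crossprod(sv$u, T))
}

# --- shared fixtures -------------------------------------------------

# lightweight network for unit tests: 20 -> 18 -> 9 -> 7 -> 3 -> 1;
# the tiny feature space needs a weak ridge penalty to separate cleanly
small_config <- function(seed = 1L) {
  celm_config(patch_size = 20L, conv_channels = c(4L, 8L, 16L),
              elm_C = 100, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

# small trained model, built once per test run
small_model <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- small_config()
    ts <- make_training_set(80, cfg, seed = 1)
    .fixture_env$small <- suppressMessages(train_celm(ts, cfg))
  }
  .fixture_env$small
}

# full-size model under the published architecture and the synthetic
# corpus conditions (500 pairs, sigma in [2,4], seed 0)
default_model <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- celm_config(seed = 0L)
    ts <- make_training_set(500, cfg, seed = 0)
    .fixture_env$default <- suppressMessages(train_celm(ts, cfg))
  }
  .fixture_env$default
}
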