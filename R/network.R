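#' Draw a random convolution kernel bank
#'
#' The feature extractor's convolution weights are never trained: each
#' kernel entry is drawn i.i.d. from a normal distribution and kept fixed,
#' in the extreme-learning-machine spirit where only the output weights
#' are fitted. The scale is variance-preserving, `sd = 1/sqrt(fan_in)`
#' with `fan_in = in_channels * kernel_size^2`, so post-ReLU activations
#' stay in a usable range across the three layers. Biases are zero.
#'
#' @param config A [celm_config()].
#' @param seed Integer seed; the bank is a pure function of
#'   `(config, seed)`.
#' @return A `celm_kernel_bank`: list of 3 layers, each with `kernels`
#'   (array `r x r x in x out`) and `biases` (length `out`).
#' @export
init_kernel_bank <- function(config = celm_config(), seed = config$seed) {
  validate_config(config)
  r <- config$kernel_size
  in_ch <- c(1L, config$conv_channels[1:2])
  out_ch <- config$conv_channels
  layers <- withr::with_seed(seed, {
    lapply(seq_len(3L), function(l) {
      fan_in <- in_ch[l] * r^2
      k <- array(rnorm(r * r * in_ch[l] * out_ch[l], sd = 1 / sqrt(fan_in)),
                 dim = c(r, r, in_ch[l], out_ch[l]))
      list(kernels = k, biases = numeric(out_ch[l]))
    })
  })
  structure(list(layers = layers, seed = as.integer(seed),
                 kernel_size = r, conv_channels = out_ch,
                 pool_size = config$pool_size, pool_stride = config$pool_stride),
            class = "celm_kernel_bank")
}

# Kernel arrays reshaped to the (r*r*in) x out GEMM matrices the C++
# core consumes; column-major flattening of (r, r, in, out) matches the
# (kr fast, kc, cin) im2col order.
bank_mats <- function(bank) {
  lapply(bank$layers, function(l) {
    d <- dim(l$kernels)
    matrix(l$kernels, nrow = d[1] * d[2] * d[3], ncol = d[4])
  })
}

bank_biases <- function(bank) lapply(bank$layers, `[[`, "biases")

as_stack <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

#' Valid convolution with ReLU activation
#'
#' Applies one layer of the kernel bank to a feature stack: valid
#' (no-padding) 2-D cross-correlation, summed over input channels, plus
#' bias, then `max(0, .)`. A `k x k` input against an `r x r` kernel
#' yields a `(k - r + 1) x (k - r + 1)` map.
#'
#' @param x Numeric matrix or `h x w x channels` array.
#' @param layer One element of a `celm_kernel_bank`'s `layers` list.
#' @return An `h' x w' x out_channels` array, all entries `>= 0`.
#' @export
conv_relu <- function(x, layer) {
  x <- as_stack(x)
  d <- dim(layer$kernels)
  stopifnot(dim(x)[3] == d[3])
  W <- matrix(layer$kernels, nrow = d[1] * d[2] * d[3], ncol = d[4])
  cpp_conv_relu(x, W, layer$biases, d[1])
}

#' Per-channel max-pooling
#'
#' Block maximum over `size x size` windows advancing by `stride`;
#' trailing rows/columns of odd-sized inputs are dropped (floor
#' semantics).
#'
#' @param x Numeric matrix or `h x w x channels` array.
#' @param size,stride Pooling window and stride (defaults 2 and 2).
#' @return Pooled array with spatial dims `floor((dim - size)/stride) + 1`.
#' @export
max_pool <- function(x, size = 2L, stride = 2L) {
  cpp_max_pool(as_stack(x), size, stride)
}

#' Global average pooling
#'
#' Arithmetic mean over each channel's spatial extent, replacing a fully
#' connected layer; the result is the per-branch feature vector.
#'
#' @param x Numeric matrix or `h x w x channels` array.
#' @return Numeric vector, one mean per channel.
#' @export
global_avg_pool <- function(x) {
  as.numeric(cpp_gap(as_stack(x)))
}

#' Feature vector of one siamese branch
#'
#' Runs a square patch through conv/ReLU -> max-pool -> conv/ReLU ->
#' max-pool -> conv/ReLU -> global average pooling. With defaults the
#' spatial trace is 32 -> 30 -> 15 -> 13 -> 6 -> 4, ending in a
#' 256-vector of non-negative channel means.
#'
#' @param patch Numeric `patch_size x patch_size` matrix.
#' @param bank A `celm_kernel_bank`.
#' @return Numeric vector of length `conv_channels[3]`.
#' @export
branch_features <- function(patch, bank) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch))
  as.numeric(cpp_branch(patch, bank_mats(bank), bank_biases(bank),
                        bank$kernel_size, bank$pool_size, bank$pool_stride))
}

#' Concatenated siamese features of a patch pair
#'
#' Both patches pass through the same kernel bank (weight sharing); the
#' two global-average-pooled vectors are concatenated, A's half first.
#'
#' @param patch_a,patch_b Square patches of identical size.
#' @param bank A `celm_kernel_bank`.
#' @return Numeric vector of length `2 * conv_channels[3]`.
#' @export
pair_features <- function(patch_a, patch_b, bank) {
  c(branch_features(patch_a, bank), branch_features(patch_b, bank))
}
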