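#' Run configuration for the fusion pipeline
#'
#' Bundles every tunable of the network and the fusion schemes: the patch
#' size fed to the siamese branches, the per-layer channel counts, kernel
#' and pooling geometry, the ridge regularization constant of the extreme
#' learning machine head, the dense-scoring stride and the decision
#' threshold.
#'
#' The defaults mirror the published architecture: 32x32 patches, three
#' 3x3 convolution layers with 64, 128 and 256 maps, 2x2/2 max-pooling
#' after the first two convolutions, and a 256-feature global average
#' pooling per branch (512 concatenated features at the classifier).
#'
#' @param patch_size Side of the square input patch; must be divisible by
#'   `pool_stride^2` so the spatial trace stays valid.
#' @param conv_channels Integer triple of output channels per convolution
#'   layer.
#' @param kernel_size Odd side of the square convolution kernels.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @param elm_C Positive ridge regularization coefficient of the
#'   classifier head.
#' @param seed Integer seed controlling kernel-bank generation.
#' @param score_stride Grid stride of dense scoring during fusion;
#'   positions between grid points take the nearest score.
#' @param threshold Decision threshold on the classifier score in (0,1);
#'   scores at or above it select source A.
#' @return A `celm_config` list.
#' @examples
#' cfg <- celm_config()
#' cfg$conv_channels
#' @export
celm_config <- function(patch_size = 32L,
                        conv_channels = c(64L, 128L, 256L),
                        kernel_size = 3L,
                        pool_size = 2L,
                        pool_stride = 2L,
                        elm_C = 1.0,
                        seed = 0L,
                        score_stride = 4L,
                        threshold = 0.5) {
  cfg <- list(
    patch_size = as.integer(patch_size),
    conv_channels = as.integer(conv_channels),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride),
    elm_C = as.numeric(elm_C),
    seed = as.integer(seed),
    score_stride = as.integer(score_stride),
    threshold = as.numeric(threshold)
  )
  class(cfg) <- "celm_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$conv_channels) == 3L, all(cfg$conv_channels >= 1L),
    cfg$kernel_size %% 2L == 1L,
    cfg$patch_size %% (cfg$pool_stride^2L) == 0L,
    cfg$elm_C > 0,
    cfg$score_stride >= 1L,
    cfg$threshold > 0, cfg$threshold < 1
  )
  invisible(cfg)
}

#' Read a configuration file
#'
#' Loads a YAML file whose keys mirror the arguments of [celm_config()];
#' keys absent from the file keep their defaults. `overrides` (typically
#' parsed command-line flags) take precedence over file values.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list overriding file values.
#' @return A `celm_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
  }
  vals <- modifyList(vals, overrides)
  unknown <- setdiff(names(vals), names(formals(celm_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(celm_config, vals)
}

#' @export
print.celm_config <- function(x, ...) {
  cat("CELM run configuration\n")
  cat(sprintf("  patch %dx%d, conv channels %s, kernel %dx%d, pool %d/%d\n",
              x$patch_size, x$patch_size, paste(x$conv_channels, collapse = "-"),
              x$kernel_size, x$kernel_size, x$pool_size, x$pool_stride))
  cat(sprintf("  elm_C %.3g, seed %d, score stride %d, threshold %.2f\n",
              x$elm_C, x$seed, x$score_stride, x$threshold))
  invisible(x)
}
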