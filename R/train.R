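#' Train a fusion model on a patch-pair corpus
#'
#' Draws (or reuses) a random kernel bank, pushes every training pair
#' through the shared siamese branches, stacks the concatenated feature
#' vectors into `H`, and fits the output weights by regularized least
#' squares. An 80/20 train/validation split (by pair, seeded by
#' `config$seed`) provides a held-out accuracy estimate at threshold
#' `config$threshold`.
#'
#' @param train A `celm_training_set` from [make_training_set()].
#' @param config A [celm_config()].
#' @param bank Optional pre-built `celm_kernel_bank`; by default drawn
#'   from `config$seed`.
#' @param val_fraction Fraction of pairs held out for validation
#'   (default 0.2; 0 disables the split).
#' @return A `celm_model`: `bank`, `elm`, `config`, and an `accuracy`
#'   list with `train`, `validation` and split sizes.
#' @export
train_celm <- function(train, config = celm_config(), bank = NULL,
                       val_fraction = 0.2) {
  stopifnot(inherits(train, "celm_training_set"))
  n <- length(train$labels)
  if (n < 2L || length(unique(train$labels)) < 2L)
    stop("training corpus must contain both classes")
  if (is.null(bank)) bank <- init_kernel_bank(config, config$seed)

  H <- cpp_pair_features(train$patches_a, train$patches_b,
                         bank_mats(bank), bank_biases(bank),
                         bank$kernel_size, bank$pool_size, bank$pool_stride)
  y <- train$labels

  idx_val <- integer(0)
  if (val_fraction > 0 && n >= 5L) {
    idx_val <- withr::with_seed(config$seed,
      sort(sample.int(n, max(1L, round(val_fraction * n)))))
  }
  idx_tr <- setdiff(seq_len(n), idx_val)
  if (length(unique(y[idx_tr])) < 2L) stop("training split lost a class")

  elm <- elm_fit(H[idx_tr, , drop = FALSE], y[idx_tr], config$elm_C)
  score <- function(rows) pmin(1, pmax(0, as.numeric(H[rows, , drop = FALSE] %*% elm$beta)))
  acc <- function(rows) if (length(rows)) mean((score(rows) >= config$threshold) == (y[rows] == 1L)) else NA_real_

  model <- structure(list(
    bank = bank, elm = elm, config = config,
    accuracy = list(train = acc(idx_tr), validation = acc(idx_val),
                    n_train = length(idx_tr), n_validation = length(idx_val)),
    fingerprint = list(corpus_seed = train$seed, n_pairs = n,
                       blur_sigma = train$blur_sigma, bank_seed = bank$seed)
  ), class = "celm_model")
  message(sprintf("trained CELM: accuracy %.3f (train, n=%d), %.3f (validation, n=%d)",
                  model$accuracy$train, model$accuracy$n_train,
                  model$accuracy$validation, model$accuracy$n_validation))
  model
}

#' @export
print.celm_model <- function(x, ...) {
  cat("CELM fusion model\n")
  print(x$config)
  print(x$elm)
  cat(sprintf("  accuracy: train %.3f (n=%d), validation %.3f (n=%d)\n",
              x$accuracy$train, x$accuracy$n_train,
              x$accuracy$validation, x$accuracy$n_validation))
  invisible(x)
}

MODEL_FORMAT <- "celmfuse-model-v1"

#' Serialize / restore a fusion model
#'
#' The model archive is a single RDS file carrying a format-version
#' string, the kernel bank (layer shapes and float arrays), the ELM head
#' (`beta`, `C`, feature dimension) and the run configuration; a
#' write/read round trip is bit-exact.
#'
#' @param model A `celm_model`.
#' @param path Destination / source file path.
#' @return `write_model` returns `path` invisibly; `read_model` the
#'   restored `celm_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "celm_model"))
  saveRDS(list(format = MODEL_FORMAT, model = unclass(model)), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, MODEL_FORMAT))
    stop("not a celmfuse model archive: ", path)
  m <- obj$model
  class(m) <- "celm_model"
  class(m$bank) <- "celm_kernel_bank"
  class(m$elm) <- "celm_elm"
  class(m$config) <- "celm_config"
  if (m$elm$feature_dim != 2L * m$config$conv_channels[3])
    stop("corrupt model: feature dimension inconsistent with configuration")
  m
}
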