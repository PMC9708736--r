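#' Fit the extreme learning machine output weights
#'
#' Solves the regularized least-squares system
#' `beta = (I/C + H'H)^{-1} H'T` in its linear-system form
#' `(I/C + H'H) beta = H'T` by Cholesky factorization (the matrix is
#' symmetric positive definite for any `C > 0`); no explicit inverse is
#' formed. The solution is verified a posteriori against the normal
#' equations to `1e-8` relative accuracy.
#'
#' @param H Feature matrix, one row per training pair (`N x d`).
#' @param T Target vector of length `N`, labels in `{0, 1}` (any numeric
#'   targets are accepted).
#' @param C Positive regularization coefficient.
#' @return A `celm_elm` model: `beta` (length `d`), `C`, `feature_dim`.
#' @export
elm_fit <- function(H, T, C = 1.0) {
  H <- as.matrix(H)
  T <- as.numeric(T)
  if (!all(is.finite(H)) || !all(is.finite(T))) stop("non-finite entries in H or T")
  stopifnot(nrow(H) == length(T), nrow(H) >= 1L, C > 0)
  A <- crossprod(H)
  diag(A) <- diag(A) + 1 / C
  b <- as.numeric(crossprod(H, T))
  R <- chol(A)
  beta <- backsolve(R, backsolve(R, b, transpose = TRUE))
  resid <- max(abs(A %*% beta - b))
  if (resid >= 1e-8 * max(1, max(abs(b))))
    stop("ridge solve failed residual check: ", format(resid))
  structure(list(beta = as.numeric(beta), C = C, feature_dim = ncol(H)),
            class = "celm_elm")
}

#' Classifier score of a feature vector
#'
#' Raw score is the inner product `features' beta`, clamped to `[0, 1]`
#' for reporting; a score near 1 marks the first (A) patch as the
#' information-rich one, near 0 the second (B). The decision threshold is
#' applied downstream by [label_map()].
#'
#' @param features Numeric vector of length `feature_dim`.
#' @param model A `celm_elm` fit.
#' @return Scalar score in `[0, 1]`.
#' @export
elm_predict <- function(features, model) {
  stopifnot(inherits(model, "celm_elm"))
  if (length(features) != model$feature_dim)
    stop("feature length ", length(features), " != model dimension ", model$feature_dim)
  min(1, max(0, sum(features * model$beta)))
}

#' @export
print.celm_elm <- function(x, ...) {
  cat(sprintf("ELM head: %d features, C = %.3g, ||beta|| = %.4g\n",
              x$feature_dim, x$C, sqrt(sum(x$beta^2))))
  invisible(x)
}
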