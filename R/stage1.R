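#' Dense classifier score map over an image pair
#'
#' Slides the trained siamese classifier over the pair: both sources are
#' reflect-padded by half a patch, the patch pair centered on each grid
#' pixel is scored by the ELM head, and grid scores are spread to full
#' resolution by nearest-neighbor assignment. `exact = TRUE` scores
#' every pixel (stride 1); the default grid stride trades a blocky-free
#' map against running time, and grid points of the strided map agree
#' exactly with the stride-1 map.
#'
#' @param a,b Same-size numeric matrices in `[0, 1]`, each dimension at
#'   least the patch size.
#' @param model A `celm_model`.
#' @param stride Grid stride in pixels (default from the model config).
#' @param exact If `TRUE`, force stride 1.
#' @return A `celm_score_map`: `scores` (matrix sized like the inputs,
#'   values in `[0, 1]`), `stride_used`.
#' @export
score_map <- function(a, b, model, stride = model$config$score_stride,
                      exact = FALSE) {
  stopifnot(inherits(model, "celm_model"), is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) stop("source images differ in size")
  p <- model$config$patch_size
  if (nrow(a) < p || ncol(a) < p)
    stop("images must be at least ", p, "x", p)
  if (exact) stride <- 1L
  stride <- as.integer(stride)

  h <- nrow(a); w <- ncol(a); half <- p %/% 2L
  apad <- pad_reflect(a, half)
  bpad <- pad_reflect(b, half)
  gr <- seq(1L, h, by = stride)
  gc <- seq(1L, w, by = stride)
  bank <- model$bank
  grid <- cpp_dense_scores(apad, bpad, bank_mats(bank), bank_biases(bank),
                           bank$kernel_size, bank$pool_size, bank$pool_stride,
                           p, gr - 1L, gc - 1L, model$elm$beta)
  # nearest grid point per pixel
  near <- function(n, g) pmin(length(g), pmax(1L, as.integer(round((seq_len(n) - 1L) / stride)) + 1L))
  scores <- grid[near(h, gr), near(w, gc), drop = FALSE]
  structure(list(scores = scores, stride_used = stride), class = "celm_score_map")
}

#' Threshold scores into a binary decision map
#'
#' @param scores A `celm_score_map` or a bare numeric matrix in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`; a score at or above
#'   it labels the pixel 1 ("A is better here").
#' @return Integer 0/1 matrix.
#' @export
label_map <- function(scores, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  s <- if (inherits(scores, "celm_score_map")) scores$scores else scores
  m <- matrix(0L, nrow(s), ncol(s))
  m[s >= threshold] <- 1L
  m
}

#' Initial per-pixel selection fusion
#'
#' Builds the first-stage fused image by copying `a` where the label is
#' 1 and `b` elsewhere; the consistency matrix records the ownership of
#' every fused pixel (1 = taken from A).
#'
#' @param a,b Same-size source matrices.
#' @param labels 0/1 matrix from [label_map()].
#' @return List with `f` (fused matrix) and `c` (ownership 0/1 matrix).
#' @export
initial_fuse <- function(a, b, labels) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(labels)))
  f <- b
  f[labels == 1L] <- a[labels == 1L]
  list(f = f, c = matrix(as.integer(labels == 1L), nrow(a), ncol(a)))
}

#' Majority-style consistency correction of the initial fusion
#'
#' Removes isolated misclassified pixels: in a single pass over the
#' original ownership matrix (no in-place cascade), each pixel's eight
#' 3x3 neighbors are summed (replicate padding at borders) and three
#' rules apply — sum >= 5 takes the pixel from A, sum <= 3 from B, and
#' sum = 4 leaves the fused pixel unchanged.
#'
#' @param c Ownership 0/1 matrix (1 = pixel of `f` came from A).
#' @param a,b Source matrices.
#' @param f Initial fused matrix.
#' @return List with corrected `f` and updated ownership `c`.
#' @export
consistency_filter <- function(c, a, b, f) {
  stopifnot(all(dim(c) == dim(f)), all(dim(a) == dim(b)), all(dim(a) == dim(f)))
  s <- box_sum(c, 3L) - c       # the eight surrounding entries only
  take_a <- s >= 5
  take_b <- s <= 3
  f2 <- f
  f2[take_a] <- a[take_a]
  f2[take_b] <- b[take_b]
  c2 <- c
  c2[take_a] <- 1L
  c2[take_b] <- 0L
  list(f = f2, c = matrix(as.integer(c2), nrow(c), ncol(c)))
}
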