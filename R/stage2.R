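#' Windowed root-mean-square error map
#'
#' Local RMS difference between two rasters over a sliding `win x win`
#' neighborhood (replicate padding at borders):
#' `out(i,j) = sqrt(mean((x - y)^2))` over the window. The first
#' argument is typically a signed difference image (`F - A` or `F - B`),
#' the second the opposite source.
#'
#' @param x,y Same-size numeric matrices; `x` may hold signed values.
#' @param win Odd window side, default 5.
#' @return Non-negative matrix of the input size.
#' @export
windowed_rmse <- function(x, y, win = 5L) {
  stopifnot(all(dim(x) == dim(y)), win %% 2L == 1L)
  sqrt(box_sum((x - y)^2, win) / win^2)
}

#' Second-stage binary comparison map
#'
#' Decides, from the residual images `F - B` and `F - A`, which source
#' each neighborhood of the initial fusion drew its information from:
#' the map is 1 where the local RMS of `F - B` strictly exceeds that of
#' `F - A` (the fused content is farther from B than from A, so more of
#' A's information should be fused there); ties and the converse give 0.
#' Note a symmetric-looking contest of cross-residuals against the
#' opposite sources would compare `(F - B) - A` with `(F - A) - B`,
#' which are the same image — that form is identically tied and carries
#' no information, so the residual-magnitude contest is the operative
#' rule.
#'
#' @param f Initial fused matrix.
#' @param a,b Source matrices.
#' @param win RMSE window side, default 5.
#' @return Integer 0/1 matrix (the map `MF`).
#' @export
mf_map <- function(f, a, b, win = 5L) {
  zero <- matrix(0, nrow(f), ncol(f))
  r1 <- windowed_rmse(f - b, zero, win)
  r2 <- windowed_rmse(f - a, zero, win)
  m <- matrix(0L, nrow(f), ncol(f))
  m[r1 > r2] <- 1L
  m
}

#' Morphological smoothing of a binary map
#'
#' One binary opening followed by one closing with a flat all-ones
#' square structuring element, removing speckle smaller than the element
#' and sealing comparably small holes while preserving larger regions.
#'
#' @param mf Integer/logical 0/1 matrix.
#' @param se_size Side of the square structuring element, default 5.
#' @return Integer 0/1 matrix (the smoothed map `MFF`).
#' @export
smooth_mm <- function(mf, se_size = 5L) {
  kern <- EBImage::makeBrush(se_size, shape = "box")
  m <- matrix(as.numeric(mf), nrow(mf), ncol(mf))
  out <- EBImage::closing(EBImage::opening(m, kern), kern)
  matrix(as.integer(out > 0.5), nrow(mf), ncol(mf))
}

#' Final unanimity-gated selection
#'
#' Rewrites an initial fused pixel only when its whole 3x3 neighborhood
#' in the smoothed map agrees: if `mff = 1` and all eight neighbors are
#' 1, the pixel is taken from A; if `mff = 0` and all eight neighbors
#' are 0, from B; otherwise the initial fused value stands. Borders use
#' replicate padding of `mff`.
#'
#' @param f Initial fused matrix.
#' @param a,b Source matrices.
#' @param mff Smoothed 0/1 map from [smooth_mm()].
#' @return The final fused matrix `FF`.
#' @export
final_fuse <- function(f, a, b, mff) {
  stopifnot(all(dim(f) == dim(mff)), all(dim(a) == dim(b)), all(dim(a) == dim(f)))
  s <- box_sum(matrix(as.numeric(mff), nrow(mff), ncol(mff)), 3L) - mff
  ff <- f
  take_a <- mff == 1L & s == 8
  take_b <- mff == 0L & s == 0
  ff[take_a] <- a[take_a]
  ff[take_b] <- b[take_b]
  ff
}

#' Full two-stage fusion of a grayscale pair
#'
#' Runs the complete pipeline: dense classifier scoring, thresholding,
#' per-pixel selection, 3x3 consistency correction (stage 1), then the
#' windowed-RMSE comparison, morphological smoothing and unanimity-gated
#' final selection (stage 2). Every pixel of the result comes verbatim
#' from one of the two sources.
#'
#' @param a,b Co-registered same-size matrices in `[0, 1]`.
#' @param model A `celm_model`.
#' @param stride Dense-scoring grid stride (default from the model).
#' @param exact Score every pixel (stride 1) if `TRUE`.
#' @return A `celm_fusion` list: final image `ff`, initial image `f`,
#'   `scores`, `label`, filtered ownership `c`, `mf`, `mff`.
#' @export
fuse_images <- function(a, b, model, stride = model$config$score_stride,
                        exact = FALSE) {
  sm <- score_map(a, b, model, stride = stride, exact = exact)
  lab <- label_map(sm, model$config$threshold)
  st1 <- initial_fuse(a, b, lab)
  st1 <- consistency_filter(st1$c, a, b, st1$f)
  mf <- mf_map(st1$f, a, b)
  mff <- smooth_mm(mf)
  ff <- final_fuse(st1$f, a, b, mff)
  structure(list(ff = ff, f = st1$f, scores = sm$scores, label = lab,
                 c = st1$c, mf = mf, mff = mff,
                 stride_used = sm$stride_used),
            class = "celm_fusion")
}
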