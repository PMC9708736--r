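#' RGB / YUV color-space conversion
#'
#' Full-range BT.601 analog transform: `Y = 0.299 R + 0.587 G + 0.114 B`,
#' `U = 0.492 (B - Y)`, `V = 0.877 (R - Y)`; `yuv_to_rgb` is its exact
#' float inverse, with final RGB clipped to `[0, 1]` (clipping is
#' warned). Luminance can then be fused on its own while chrominance
#' passes through untouched.
#'
#' @param img For `rgb_to_yuv`: rows x cols x 3 array in `[0, 1]`. For
#'   `yuv_to_rgb`: a `celm_yuv` list.
#' @return `rgb_to_yuv` returns a `celm_yuv` list with matrices `y`
#'   (in `[0, 1]`), `u`, `v` (signed); `yuv_to_rgb` an RGB array.
#' @export
rgb_to_yuv <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- matrix(img[, , 1], h, w); g <- matrix(img[, , 2], h, w)
  b <- matrix(img[, , 3], h, w)
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  structure(list(y = y, u = 0.492 * (b - y), v = 0.877 * (r - y)),
            class = "celm_yuv")
}

#' @rdname rgb_to_yuv
#' @export
yuv_to_rgb <- function(img) {
  stopifnot(inherits(img, "celm_yuv"))
  y <- img$y; u <- img$u; v <- img$v
  r <- y + v / 0.877
  b <- y + u / 0.492
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(c(r, g, b), dim = c(dim(y), 3L))
  if (any(out < -1e-9 | out > 1 + 1e-9))
    warning("clipping RGB values outside [0,1] after YUV conversion")
  pmin(pmax(out, 0), 1)
}

as_yuv <- function(img) {
  if (length(dim(img)) == 3L) rgb_to_yuv(img)
  else structure(list(y = img, u = matrix(0, nrow(img), ncol(img)),
                      v = matrix(0, nrow(img), ncol(img))), class = "celm_yuv")
}

#' Fuse a pair with color handling
#'
#' Grayscale pairs fall through to [fuse_images()] unchanged. When at
#' least one source is RGB, both are taken to YUV (a grayscale source is
#' treated as pure luminance), the two Y planes are fused by the full
#' two-stage pipeline, and chrominance is reattached: from the single
#' color source when only one input is color, or selected per pixel by
#' the final decision (which source supplied each FF pixel) when both
#' are.
#'
#' @param a,b Same-size sources; numeric matrix or rows x cols x 3 array.
#' @param model A `celm_model`.
#' @param ... Passed to [fuse_images()] (`stride`, `exact`).
#' @return A `celm_fusion` list; for color inputs the element `rgb`
#'   holds the fused RGB array and `ff` the fused luminance.
#' @export
fuse_color <- function(a, b, model, ...) {
  a_color <- length(dim(a)) == 3L
  b_color <- length(dim(b)) == 3L
  if (!a_color && !b_color) return(fuse_images(a, b, model, ...))
  sp <- function(x) dim(x)[1:2]
  if (!all(sp(a) == sp(b))) stop("source images differ in size")

  ya <- as_yuv(a); yb <- as_yuv(b)
  fus <- fuse_images(ya$y, yb$y, model, ...)

  if (xor(a_color, b_color)) {
    src <- if (a_color) ya else yb
    u <- src$u; v <- src$v
  } else {
    # both color: chroma follows the provenance of each final pixel
    from_a <- provenance_map(fus$ff, ya$y, yb$y)
    u <- yb$u; u[from_a] <- ya$u[from_a]
    v <- yb$v; v[from_a] <- ya$v[from_a]
  }
  fus$rgb <- yuv_to_rgb(structure(list(y = fus$ff, u = u, v = v),
                                  class = "celm_yuv"))
  fus
}

# TRUE where the fused pixel equals A's (ties to A; only matters where
# the sources coincide, where either chroma choice is the same pixel of
# a genuinely shared value).
provenance_map <- function(ff, a, b) {
  abs(ff - a) <= abs(ff - b)
}
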