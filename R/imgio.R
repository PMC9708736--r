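#' Read a PNG or TIFF image as a normalized raster
#'
#' Intensities are scaled to `[0, 1]` by the bit-depth maximum (the png
#' and tiff readers do this natively for 8- and 16-bit data). Grayscale
#' files yield a plain numeric matrix (rows x cols); color files yield a
#' rows x cols x 3 array. An alpha channel, if present, is dropped with a
#' warning.
#'
#' @param path Path to an existing `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (grayscale) or a 3-slice array (RGB), values
#'   in `[0, 1]`.
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for: ", path)
  )
  if (is.list(img)) img <- img[[1]]  # multi-page TIFF: first page
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) {  # gray + alpha
      warning("dropping alpha channel of ", path)
      img <- img[, , 1L]
    } else if (dim(img)[3] == 4L) {
      warning("dropping alpha channel of ", path)
      img <- img[, , 1:3, drop = FALSE]
    } else if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    }
  }
  if (!all(is.finite(img))) stop("non-finite pixel values in ", path)
  img
}

#' Write a raster as an 8-bit PNG
#'
#' Values are quantized as `round(v * 255)`; a read/write round trip
#' therefore changes a pixel by at most 1/255. Values outside `[0, 1]`
#' are clipped with a warning.
#'
#' @param img Numeric matrix (grayscale) or rows x cols x 3 array (RGB).
#' @param path Output path; written as PNG regardless of extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (any(img < 0 | img > 1)) {
    warning("clipping pixel values outside [0,1] before writing ", path)
    img <- pmin(pmax(img, 0), 1)
  }
  quant <- round(img * 255) / 255
  png::writePNG(quant, path)
  invisible(path)
}

# Replicate-pad a matrix by `p` pixels on every side.
pad_replicate <- function(x, p) {
  ri <- c(rep(1L, p), seq_len(nrow(x)), rep(nrow(x), p))
  ci <- c(rep(1L, p), seq_len(ncol(x)), rep(ncol(x), p))
  x[ri, ci, drop = FALSE]
}

# Reflect-pad (half-sample symmetric) a matrix by `p` pixels per side.
pad_reflect <- function(x, p) {
  stopifnot(p <= nrow(x), p <= ncol(x))
  ri <- c(seq(p, 1L), seq_len(nrow(x)), seq(nrow(x), nrow(x) - p + 1L))
  ci <- c(seq(p, 1L), seq_len(ncol(x)), seq(ncol(x), ncol(x) - p + 1L))
  x[ri, ci, drop = FALSE]
}

# Sliding-window box sum over a win x win neighborhood with replicate
# padding, via two cumulative-sum passes. Returns a matrix of the input
# size.
box_sum <- function(x, win) {
  stopifnot(win %% 2L == 1L)
  h <- win %/% 2L
  xp <- pad_replicate(x, h)
  cs <- apply(xp, 2L, cumsum)
  rows <- cs[(win):nrow(xp), , drop = FALSE] -
    rbind(0, cs[seq_len(nrow(xp) - win), , drop = FALSE])
  cs2 <- t(apply(rows, 1L, cumsum))
  if (nrow(rows) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  cs2[, win:ncol(xp), drop = FALSE] -
    cbind(0, cs2[, seq_len(ncol(xp) - win), drop = FALSE])
}
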