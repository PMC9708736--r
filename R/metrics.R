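#' Spatial frequency of a fused image
#'
#' Row frequency is the RMS of horizontal neighbor differences, column
#' frequency the vertical analogue, and
#' `Q_SF = sqrt(RF^2 + CF^2)`. Computed on the 0-255 intensity scale, so
#' values for natural-image-like content land in the tens. Higher means
#' a sharper, more detailed image.
#'
#' @param f Numeric matrix in `[0, 1]` (or an RGB array; luminance is
#'   used), at least 2x2.
#' @return Non-negative scalar.
#' @export
q_sf <- function(f) {
  f <- to_luma(f) * 255
  stopifnot(nrow(f) >= 2L || ncol(f) >= 2L)
  rf2 <- if (ncol(f) >= 2L)
    mean((f[, -1L, drop = FALSE] - f[, -ncol(f), drop = FALSE])^2) else 0
  cf2 <- if (nrow(f) >= 2L)
    mean((f[-1L, , drop = FALSE] - f[-nrow(f), , drop = FALSE])^2) else 0
  sqrt(rf2 + cf2)
}

# Per-window mean / variance / covariance over win x win sliding
# windows (population moments, fully inside the image: valid windows
# only).
local_moments <- function(x, y, win) {
  n <- win * win
  sx <- valid_box(x, win); sy <- valid_box(y, win)
  sxx <- valid_box(x * x, win); syy <- valid_box(y * y, win)
  sxy <- valid_box(x * y, win)
  mx <- sx / n; my <- sy / n
  list(mx = mx, my = my,
       vx = sxx / n - mx^2, vy = syy / n - my^2,
       cxy = sxy / n - mx * my)
}

# Sliding-window sum over fully interior win x win windows (no padding):
# output (h-win+1) x (w-win+1).
valid_box <- function(x, win) {
  cs <- apply(rbind(0, x), 2L, cumsum)
  rows <- cs[(win + 1L):nrow(cs), , drop = FALSE] - cs[seq_len(nrow(x) - win + 1L), , drop = FALSE]
  cs2 <- t(apply(cbind(0, rows), 1L, cumsum))
  if (nrow(rows) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  cs2[, (win + 1L):ncol(cs2), drop = FALSE] - cs2[, seq_len(ncol(x) - win + 1L), drop = FALSE]
}

#' Piella's weighted fusion quality index
#'
#' Universal-quality-index comparison of the fused image with each
#' source over sliding 8x8 windows (stride 1),
#' `Q0(x, y) = 4 cov mx my / ((vx + vy)(mx^2 + my^2))`, combined per
#' window as `lambda Q0(A,F) + (1 - lambda) Q0(B,F)` with
#' `lambda = var(A) / (var(A) + var(B))`, and averaged with weights
#' proportional to the window's total saliency `var(A) + var(B)`.
#' Windows where a Q0 denominator vanishes contribute 1 if the window
#' pair is identical and are skipped otherwise. 1 is perfect.
#'
#' @param a,b,f Same-size matrices (or RGB arrays; luminance is used),
#'   at least 8x8.
#' @param win Window side, default 8.
#' @return Scalar in `[-1, 1]`.
#' @export
q_piella <- function(a, b, f, win = 8L) {
  a <- to_luma(a); b <- to_luma(b); f <- to_luma(f)
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(f)),
            nrow(a) >= win, ncol(a) >= win)
  maf <- local_moments(a, f, win)
  mbf <- local_moments(b, f, win)

  q0 <- function(m) {
    den <- (m$vx + m$vy) * (m$mx^2 + m$my^2)
    num <- 4 * m$cxy * m$mx * m$my
    q <- num / den
    ident <- abs(m$mx - m$my) < 1e-12 & abs(m$vx - m$vy) < 1e-12 &
      abs(m$vx - m$cxy) < 1e-12
    q[den < 1e-24] <- NA_real_
    q[den < 1e-24 & ident] <- 1
    q
  }
  qa <- q0(maf)
  qb <- q0(mbf)
  sa <- pmax(maf$vx, 0)
  sb <- pmax(mbf$vx, 0)
  tot <- sa + sb
  lam <- ifelse(tot > 0, sa / tot, 0.5)
  qw <- lam * qa + (1 - lam) * qb
  keep <- is.finite(qw)
  if (!any(keep)) stop("degenerate images: every window skipped")
  if (any(!keep)) message(sum(!keep), " degenerate windows skipped in q_piella")
  cw <- tot[keep]
  if (sum(cw) == 0) return(mean(qw[keep]))
  sum(cw * qw[keep]) / sum(cw)
}

#' Normalized mutual information of the fusion
#'
#' Entropy-normalized mutual information on 256-bin (8-bit) joint
#' histograms:
#' `Q_MI = 2 (I(A;F)/(H(A)+H(F)) + I(B;F)/(H(B)+H(F)))`, entropies in
#' bits with `0 log 0 = 0`. An identical non-constant triple scores the
#' maximum 2. A zero-entropy (constant) pair makes its normalized term 1
#' when the two images are identical and 0 otherwise.
#'
#' @param a,b,f Same-size matrices (or RGB arrays; luminance is used).
#' @param bins Histogram bins, default 256.
#' @return Scalar in `[0, 2]`.
#' @export
q_mi <- function(a, b, f, bins = 256L) {
  a <- to_luma(a); b <- to_luma(b); f <- to_luma(f)
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(f)))
  quant <- function(x) pmin(bins - 1L, pmax(0L, as.integer(round(x * (bins - 1L)))))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  term <- function(x, y) {
    qx <- quant(x); qy <- quant(y)
    joint <- tabulate(qx * bins + qy + 1L, nbins = bins * bins) / length(qx)
    hx <- ent(tabulate(qx + 1L, nbins = bins) / length(qx))
    hy <- ent(tabulate(qy + 1L, nbins = bins) / length(qy))
    hxy <- ent(joint)
    if (hx + hy == 0) {
      message("zero-entropy image pair in q_mi; term set by identity")
      return(if (all(qx == qy)) 1 else 0)
    }
    2 * (hx + hy - hxy) / (hx + hy)
  }
  term(a, f) + term(b, f)
}

#' Chen-Varshney perceptual fusion measure
#'
#' Lower is better. The residuals `A - F` and `B - F` (0-255 scale) are
#' filtered in the frequency domain by the Mannos-Sakrison contrast
#' sensitivity function
#' `H(rho) = 2.6 (0.0192 + 0.114 rho) exp(-(0.114 rho)^1.1)`, `rho` in
#' cycles/degree with the Nyquist digital frequency mapped to
#' `nyquist_cpd` (default 30). The image is split into `region x region`
#' blocks; each block's mean squared filtered residuals are combined
#' with weights given by the block's gradient-energy saliency in each
#' source, and averaged over blocks.
#'
#' @param a,b,f Same-size matrices (or RGB arrays; luminance is used),
#'   at least 16x16.
#' @param region Block side, default 16.
#' @param nyquist_cpd Viewing-geometry constant: cycles/degree assigned
#'   to the digital Nyquist frequency.
#' @return Non-negative scalar.
#' @export
q_cv <- function(a, b, f, region = 16L, nyquist_cpd = 30) {
  a <- to_luma(a) * 255; b <- to_luma(b) * 255; f <- to_luma(f) * 255
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(f)),
            nrow(a) >= region, ncol(a) >= region)

  csf_filter <- function(d) {
    h <- nrow(d); w <- ncol(d)
    fy <- c(seq(0L, floor(h / 2)), seq(ceiling(h / 2) - 1L, 1L)) / h
    fx <- c(seq(0L, floor(w / 2)), seq(ceiling(w / 2) - 1L, 1L)) / w
    rho <- sqrt(outer(fy^2, fx^2, `+`)) * (nyquist_cpd / 0.5)
    H <- 2.6 * (0.0192 + 0.114 * rho) * exp(-(0.114 * rho)^1.1)
    Re(fft(fft(d) * H, inverse = TRUE)) / (h * w)
  }
  grad_energy <- function(x) {
    gx <- matrix(0, nrow(x), ncol(x)); gy <- gx
    gx[, 2:(ncol(x) - 1)] <- (x[, 3:ncol(x)] - x[, 1:(ncol(x) - 2)]) / 2
    gy[2:(nrow(x) - 1), ] <- (x[3:nrow(x), ] - x[1:(nrow(x) - 2), ]) / 2
    gx^2 + gy^2
  }
  block_stat <- function(x, stat) {
    ri <- split(seq_len(nrow(x)), (seq_len(nrow(x)) - 1L) %/% region)
    ci <- split(seq_len(ncol(x)), (seq_len(ncol(x)) - 1L) %/% region)
    vapply(ri, function(r) vapply(ci, function(cc) stat(x[r, cc]), 0), numeric(length(ci)))
  }
  daf <- csf_filter(a - f)^2
  dbf <- csf_filter(b - f)^2
  la <- block_stat(grad_energy(a), sum)
  lb <- block_stat(grad_energy(b), sum)
  Da <- block_stat(daf, mean)
  Db <- block_stat(dbf, mean)
  if (sum(la) + sum(lb) == 0) stop("zero saliency everywhere: q_cv undefined")
  sum(la * Da + lb * Db) / sum(la + lb)
}

to_luma <- function(x) {
  if (length(dim(x)) == 3L) rgb_to_yuv(x)$y else x
}

#' Full metric report for a fusion result
#'
#' Computes all four quality measures of a fused image against its
#' sources and records the analysis windows used.
#'
#' @param a,b Source images (matrices or RGB arrays).
#' @param f Fused image.
#' @return A `celm_metrics` list: `q_sf`, `q_piella`, `q_mi`, `q_cv`,
#'   `parameters`.
#' @export
metric_report <- function(a, b, f) {
  rep <- structure(list(
    q_sf = q_sf(f),
    q_piella = q_piella(a, b, f),
    q_mi = q_mi(a, b, f),
    q_cv = q_cv(a, b, f),
    parameters = list(piella_window = 8L, mi_bins = 256L,
                      cv_region = 16L, cv_nyquist_cpd = 30)
  ), class = "celm_metrics")
  rep
}

#' @export
print.celm_metrics <- function(x, ...) {
  cat("Fusion quality metrics\n")
  cat(sprintf("  Q_SF     %10.4f  (spatial frequency, 0-255 scale; higher = sharper)\n", x$q_sf))
  cat(sprintf("  Q_Piella %10.4f  (weighted quality index; 1 = perfect)\n", x$q_piella))
  cat(sprintf("  Q_MI     %10.4f  (normalized mutual information; 2 = maximal)\n", x$q_mi))
  cat(sprintf("  Q_CV     %10.4f  (perceptual distortion; lower = better)\n", x$q_cv))
  invisible(x)
}
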