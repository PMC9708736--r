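#' Spectral-synthesis noise texture
#'
#' Generates a `1/f^gamma` random field by shaping white Gaussian noise
#' in the Fourier domain and rescaling the real part to span exactly
#' `[0, 1]`. `gamma = 0` gives flat-spectrum white noise; larger values
#' give progressively smoother, natural-image-like textures. Used as raw
#' material for training patches and phantoms.
#'
#' @param size Side of the square texture in pixels.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param spectral_exponent Power-law exponent `gamma` (default 1.5).
#' @return A `size x size` matrix with `min = 0`, `max = 1`.
#' @export
make_texture <- function(size, seed, spectral_exponent = 1.5) {
  stopifnot(size >= 2L)
  noise <- withr::with_seed(seed, matrix(rnorm(size * size), size, size))
  fr <- c(seq(0L, floor(size / 2)), seq(ceiling(size / 2) - 1L, 1L)) / size
  f <- sqrt(outer(fr^2, fr^2, `+`))
  amp <- ifelse(f > 0, f^(-spectral_exponent), 0)
  x <- Re(fft(fft(noise) * amp, inverse = TRUE)) / (size * size)
  rng <- range(x)
  if (rng[2] == rng[1]) return(matrix(0.5, size, size))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Synthetic sharp-vs-blurred training corpus
#'
#' Emulates information-rich / information-poor patch pairs: for each
#' pair a textured field is synthesized, a Gaussian-blurred copy made
#' (`sigma ~ Uniform(blur_sigma)`), and the same window is cut from
#' both. The sharp patch is the information-rich member; with
#' probability 1/2 it sits in slot A (label 1), otherwise slot B
#' (label 0). Classes are balanced to within one pair.
#'
#' @param n_pairs Number of patch pairs (`>= 2`).
#' @param config A [celm_config()]; sets the patch size.
#' @param seed Integer seed.
#' @param blur_sigma Length-2 range of the Gaussian blur sigma in
#'   pixels (default `c(2, 4)`).
#' @return A `celm_training_set`: arrays `patches_a`, `patches_b`
#'   (`patch x patch x n`), integer `labels`, `sigmas`, `seed`.
#' @export
make_training_set <- function(n_pairs, config = celm_config(), seed = 0L,
                              blur_sigma = c(2, 4)) {
  stopifnot(n_pairs >= 2L, length(blur_sigma) == 2L, blur_sigma[1] <= blur_sigma[2])
  p <- config$patch_size
  tex_size <- max(96L, p + 32L)
  margin <- 8L
  withr::with_seed(seed, {
    labels <- sample(rep_len(c(1L, 0L), n_pairs))
    sigmas <- runif(n_pairs, blur_sigma[1], blur_sigma[2])
    pa <- array(0, dim = c(p, p, n_pairs))
    pb <- array(0, dim = c(p, p, n_pairs))
    for (i in seq_len(n_pairs)) {
      tex <- make_texture(tex_size, sample.int(.Machine$integer.max, 1L) - 1L)
      blur <- EBImage::gblur(tex, sigma = sigmas[i])
      r0 <- sample(margin:(tex_size - p - margin), 1L)
      c0 <- sample(margin:(tex_size - p - margin), 1L)
      sharp <- tex[r0:(r0 + p - 1L), c0:(c0 + p - 1L)]
      soft <- blur[r0:(r0 + p - 1L), c0:(c0 + p - 1L)]
      if (labels[i] == 1L) { pa[, , i] <- sharp; pb[, , i] <- soft }
      else { pa[, , i] <- soft; pb[, , i] <- sharp }
    }
    structure(list(patches_a = pa, patches_b = pb, labels = labels,
                   sigmas = sigmas, blur_sigma = blur_sigma, seed = as.integer(seed)),
              class = "celm_training_set")
  })
}

#' Synthetic two-modality phantom pair
#'
#' Stands in for co-registered CT/MRI-like pairs with spatially
#' complementary content. Image A carries a bright, finely textured
#' skeletal ring plus thin high-frequency line spokes in the outer
#' field; image B carries smooth textured soft-tissue blobs confined to
#' the inner disk. `mask_a` and `mask_b` mark where each modality is
#' the informative one; they are disjoint by construction and together
#' cover every pixel where the two images differ appreciably.
#'
#' @param size Image side in pixels (`>= 64`).
#' @param seed Integer seed.
#' @return A `celm_phantom`: matrices `image_a`, `image_b` in `[0, 1]`,
#'   logical `mask_a`, `mask_b`, and `seed`.
#' @export
make_phantom_pair <- function(size = 128L, seed = 0L) {
  stopifnot(size >= 64L)
  ctr <- (size + 1) / 2
  rr <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)) / size

  # A: ring band 0.32 <= r <= 0.44 with near-white texture, plus two
  # thin diagonal spokes in the outer field.
  ring <- rr >= 0.32 & rr <= 0.44
  hf <- make_texture(size, seed * 13L + 1L, spectral_exponent = 0.3)
  a <- matrix(0, size, size)
  a[ring] <- 0.65 + 0.35 * hf[ring]
  spokes <- matrix(FALSE, size, size)
  ix <- which(rr > 0.48 & rr < 0.68, arr.ind = TRUE)
  d1 <- abs((ix[, 1] - ctr) - (ix[, 2] - ctr))
  d2 <- abs((ix[, 1] - ctr) + (ix[, 2] - ctr))
  spokes[ix[d1 <= 1.5 | d2 <= 1.5, , drop = FALSE]] <- TRUE
  a[spokes] <- 0.6 + 0.4 * hf[spokes]
  mask_a <- ring | spokes

  # B: smooth Gaussian bumps near the center, modulated by a smooth
  # texture, decayed far below threshold before the ring begins.
  smooth_tex <- make_texture(size, seed * 13L + 2L, spectral_exponent = 2.5)
  bumps <- withr::with_seed(seed * 13L + 3L, {
    k <- 4L
    th <- runif(k, 0, 2 * pi)
    rad <- runif(k, 0, 0.14) * size
    amp <- runif(k, 0.55, 0.85)
    sdv <- runif(k, 0.045, 0.06) * size
    bm <- matrix(0, size, size)
    for (j in seq_len(k)) {
      cy <- ctr + rad[j] * sin(th[j]); cx <- ctr + rad[j] * cos(th[j])
      g <- exp(-(outer((seq_len(size) - cy)^2, (seq_len(size) - cx)^2, `+`)) /
                 (2 * sdv[j]^2))
      bm <- pmax(bm, amp[j] * g)
    }
    bm
  })
  b <- bumps * (0.75 + 0.25 * smooth_tex)
  mask_b <- b > 0.08 & !mask_a

  structure(list(image_a = pmin(a, 1), image_b = pmin(b, 1),
                 mask_a = mask_a, mask_b = mask_b, seed = as.integer(seed)),
            class = "celm_phantom")
}
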