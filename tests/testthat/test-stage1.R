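test_that("label_map applies the >= tie rule at the threshold", {
  s <- matrix(c(0.49, 0.5, 0.51, 0, 1, 0.25), 2, 3)
  expect_equal(label_map(s, 0.5), matrix(c(0L, 1L, 1L, 0L, 1L, 0L), 2, 3))
  expect_true(all(label_map(matrix(1, 3, 3)) == 1L))
  expect_true(all(label_map(matrix(0, 3, 3)) == 0L))
  expect_error(label_map(s, 0))
})

test_that("initial_fuse is pure per-pixel selection", {
  set.seed(12)
  a <- matrix(runif(36), 6, 6)
  b <- matrix(runif(36), 6, 6)
  ones <- matrix(1L, 6, 6)
  expect_identical(initial_fuse(a, b, ones)$f, a)
  expect_identical(initial_fuse(a, b, 0L * ones)$f, b)
  lab <- matrix(rbinom(36, 1, 0.5), 6, 6)
  res <- initial_fuse(a, b, lab)
  expect_true(all(res$f == a | res$f == b))
  expect_identical(res$c, matrix(as.integer(lab), 6, 6))
  expect_identical(initial_fuse(a, a, lab)$f, a)
})

test_that("consistency filter reproduces the three-rule oracle on all 512 neighborhoods", {
  a <- matrix(2, 3, 3)
  b <- matrix(3, 3, 3)
  for (code in 0:511) {
    cmat <- matrix(as.integer(intToBits(code)[1:9]), 3, 3)
    f <- initial_fuse(a, b, cmat)$f
    got <- consistency_filter(cmat, a, b, f)
    want <- oracle_consistency(cmat, a, b, f)
    expect_identical(got$f, want$f)
    expect_identical(got$c, matrix(as.integer(want$c), 3, 3))
  }
})

test_that("consistency filter is a single pass over the original ownership", {
  # isolated 1 in a field of 0: neighbor sum 0 -> flips to B
  a <- matrix(1, 5, 5)
  b <- matrix(0, 5, 5)
  cmat <- matrix(0L, 5, 5)
  cmat[3, 3] <- 1L
  f <- initial_fuse(a, b, cmat)$f
  res <- consistency_filter(cmat, a, b, f)
  expect_equal(res$f[3, 3], 0)
  expect_equal(res$c[3, 3], 0L)
  # constant ownership is a fixed point (sums 8 or 0 everywhere)
  ones <- matrix(1L, 5, 5)
  expect_identical(consistency_filter(ones, a, b, a)$f, a)
  expect_identical(consistency_filter(0L * ones, a, b, b)$f, b)
  # random fields match the oracle too
  set.seed(33)
  for (case in 1:20) {
    cm <- matrix(rbinom(100, 1, runif(1)), 10, 10)
    aa <- matrix(runif(100), 10, 10)
    bb <- matrix(runif(100), 10, 10)
    ff <- initial_fuse(aa, bb, cm)$f
    got <- consistency_filter(cm, aa, bb, ff)
    want <- oracle_consistency(cm, aa, bb, ff)
    expect_identical(got$f, want$f)
    expect_equal(got$c, want$c)
  }
})

test_that("score maps have source dimensions, symmetry on equal inputs, and grid consistency", {
  m <- small_model()
  a <- make_texture(44, seed = 20)
  b <- make_texture(44, seed = 21)
  sm <- score_map(a, b, m, stride = 4)
  expect_equal(dim(sm$scores), c(44L, 44L))
  expect_true(all(sm$scores >= 0 & sm$scores <= 1))
  expect_identical(score_map(a, a, m, stride = 4)$scores,
                   score_map(a, a, m, stride = 4)$scores)

  s1 <- score_map(a, b, m, exact = TRUE)
  gi <- seq(1, 44, by = 4)
  expect_identical(sm$scores[gi, gi], s1$scores[gi, gi])
  expect_equal(s1$stride_used, 1L)
  expect_error(score_map(a, make_texture(32, 1), m), "size")
})

test_that("dense scoring equals independent per-patch evaluation", {
  m <- small_model()
  cfg <- m$config
  a <- make_texture(36, seed = 22)
  b <- make_texture(36, seed = 23)
  sm <- score_map(a, b, m, stride = 4)
  half <- cfg$patch_size %/% 2
  apad <- celmfuse:::pad_reflect(a, half)
  bpad <- celmfuse:::pad_reflect(b, half)
  gr <- seq(1, 36, by = 4)
  for (i in sample(seq_along(gr), 4)) {
    for (j in sample(seq_along(gr), 4)) {
      pa <- apad[gr[i]:(gr[i] + cfg$patch_size - 1), gr[j]:(gr[j] + cfg$patch_size - 1)]
      pb <- bpad[gr[i]:(gr[i] + cfg$patch_size - 1), gr[j]:(gr[j] + cfg$patch_size - 1)]
      expect_equal(sm$scores[gr[i], gr[j]],
                   elm_predict(pair_features(pa, pb, m$bank), m$elm),
                   tolerance = 1e-10)
    }
  }
})

test_that("stage-1 selection closure holds on a fused phantom", {
  m <- small_model()
  ph <- make_phantom_pair(64, seed = 4)
  sm <- score_map(ph$image_a, ph$image_b, m)
  lab <- label_map(sm, 0.5)
  st <- initial_fuse(ph$image_a, ph$image_b, lab)
  st2 <- consistency_filter(st$c, ph$image_a, ph$image_b, st$f)
  expect_true(all(st$f == ph$image_a | st$f == ph$image_b))
  expect_true(all(st2$f == ph$image_a | st2$f == ph$image_b))
})
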