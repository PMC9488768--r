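test_that("box smoothing preserves constants and k = 1 is the identity", {
  const <- matrix(7, 9, 11)
  expect_equal(box_smooth(const, 5), const)
  img <- matrix(rnorm(30), 5, 6)
  expect_identical(box_smooth(img, 1), img)
  expect_error(box_smooth(img, 4), "odd")
  expect_error(box_smooth(img, -3), "odd")
})

test_that("box smoothing matches the nested-loop oracle exactly", {
  center9 <- matrix(0, 3, 3); center9[2, 2] <- 9
  expect_equal(box_smooth(center9, 3), oracle_box_mean(center9, 3))
  set.seed(101)
  for (i in 1:100) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    img <- random_int_image(h, w)
    k <- sample(c(3, 5, 7), 1)
    expect_identical(box_smooth(img, k), oracle_box_mean(img, k))
  }
})

test_that("window extrema match the exhaustive window scan and sandwich the image", {
  const <- matrix(4, 6, 6)
  env <- window_extrema(const, 5)
  expect_equal(env$upper, const)
  expect_equal(env$lower, const)

  # single bright pixel spreads to the full window block
  z <- matrix(0, 9, 9); z[5, 5] <- 1
  env <- window_extrema(z, 5)
  expect_equal(env$upper, outer(1:9, 1:9, function(i, j) (abs(i - 5) <= 2 & abs(j - 5) <= 2) + 0))
  expect_equal(env$lower, matrix(0, 9, 9))

  set.seed(202)
  for (i in 1:100) {
    img <- random_int_image(10, 10)
    env <- window_extrema(img, 5)
    oracle <- oracle_extrema(img, 5)
    expect_identical(env$upper, oracle$upper)
    expect_identical(env$lower, oracle$lower)
    expect_true(all(env$upper >= img & img >= env$lower))
  }
  expect_error(window_extrema(const, 4), "odd")
})

test_that("envelope clamping is the pointwise max/min against the reference", {
  set.seed(33)
  for (i in 1:20) {
    u <- matrix(rnorm(36), 6); l <- matrix(rnorm(36), 6); r <- matrix(rnorm(36), 6)
    cl <- clamp_envelopes(u, l, r)
    expect_equal(cl$upper, pmax(u, r))
    expect_equal(cl$lower, pmin(l, r))
    expect_true(all(cl$upper >= r & r >= cl$lower))
  }
  u <- matrix(5, 3, 3)
  expect_equal(clamp_envelopes(u, u - 2, u - 1)$upper, u)  # already >= ref
  expect_error(clamp_envelopes(u, u, matrix(0, 2, 2)), "shape")
})

test_that("dyadic resampling does exact stride/replication index arithmetic", {
  ramp <- matrix(0:15, 4, 4, byrow = TRUE)
  expect_equal(dyadic_downsample(ramp, 2), matrix(c(0, 2, 8, 10), 2, 2, byrow = TRUE))
  expect_identical(dyadic_downsample(ramp, 1), ramp)
  m5 <- matrix(1:25, 5, 5)
  expect_equal(dim(dyadic_downsample(m5, 2)), c(3L, 3L))
  expect_equal(dyadic_downsample(m5, 2), m5[c(1, 3, 5), c(1, 3, 5)])
  expect_error(dyadic_downsample(m5, 3), "power of two")

  src <- matrix(1:4, 2, 2, byrow = TRUE)
  expect_equal(upsample_replicate(src, 2, 4, 4),
               matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 3, 3, 4, 4, 3, 3, 4, 4), 4, 4, byrow = TRUE))
  src3 <- matrix(1:9, 3, 3)
  up <- upsample_replicate(src3, 2, 5, 5)
  expect_equal(dim(up), c(5L, 5L))
  expect_equal(up, src3[c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)])
  expect_identical(upsample_replicate(src3, 1, 3, 3), src3)
  expect_error(upsample_replicate(src3, 2, 8, 8), "incompatible")

  # round trip: downsample of the replicated image recovers the source
  expect_equal(dyadic_downsample(upsample_replicate(src3, 2, 6, 6), 2), src3)
})

test_that("one sifting pass is exact on constants and telescopes", {
  const <- matrix(42, 16, 16)
  res <- sift_level(const, 1)
  expect_equal(res$bimf, matrix(0, 16, 16))
  expect_equal(res$next_mean, const)

  set.seed(7)
  img <- matrix(runif(20 * 24, 0, 255), 20, 24)
  res <- sift_level(img, 1)
  expect_lt(max(abs(img - res$bimf - res$next_mean)), 1e-9)
})

test_that("level-1 sifting equals a straight-line scalar oracle", {
  cb <- 100 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  res <- sift_level(cb, 1)
  oracle <- oracle_sift_level1(cb)
  expect_equal(res$bimf, oracle$bimf, tolerance = 1e-12)
  expect_equal(res$next_mean, oracle$next_mean, tolerance = 1e-12)
})

test_that("sifting refuses levels whose downsampled side is too small", {
  img <- matrix(runif(16 * 16), 16, 16)
  expect_error(sift_level(img, 3, mremd_params()), class = "mremd_depth_exceeded")
})

test_that("decomposition reconstructs exactly and is deterministic", {
  const <- matrix(9, 32, 32)
  st <- mremd_decompose(const, mremd_params(n_levels = 3))
  for (b in st$bimfs) expect_equal(b, matrix(0, 32, 32))
  expect_equal(st$residual_mean, const)

  set.seed(12)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  st <- mremd_decompose(img, mremd_params(n_levels = 3))
  expect_length(st$bimfs, 3)
  expect_lt(max(abs(mremd_reconstruct(st) - img)), 1e-9)

  st2 <- mremd_decompose(img, mremd_params(n_levels = 3))
  expect_identical(st, st2)

  # early stop: a 32x32 image cannot go past level 3 (side 8 at level 3,
  # side 4 < min_side at level 4)
  st3 <- mremd_decompose(img[1:32, 1:32], mremd_params(n_levels = 6))
  expect_length(st3$bimfs, 3)
  expect_lt(max(abs(mremd_reconstruct(st3) - img[1:32, 1:32])), 1e-9)
})

test_that("decomposition commutes with global intensity shifts", {
  set.seed(5)
  img <- matrix(runif(40 * 40, 0, 255), 40, 40)
  a <- mremd_decompose(img, mremd_params(n_levels = 2))
  b <- mremd_decompose(img + 37, mremd_params(n_levels = 2))
  expect_equal(a$bimfs[[1]], b$bimfs[[1]], tolerance = 1e-9)
  expect_equal(a$bimfs[[2]], b$bimfs[[2]], tolerance = 1e-9)
  expect_equal(a$residual_mean + 37, b$residual_mean, tolerance = 1e-9)
})

test_that("successive BIMFs carry decreasing spatial frequency", {
  s <- generate_sample(1, 31, synth_params())
  st <- mremd_decompose(s$image, mremd_params(n_levels = 4))
  lap <- function(m) {
    abs(4 * m -
          m[c(1, 1:(nrow(m) - 1)), ] - m[c(2:nrow(m), nrow(m)), ] -
          m[, c(1, 1:(ncol(m) - 1))] - m[, c(2:ncol(m), ncol(m))])
  }
  expect_gt(mean(lap(st$bimfs[[1]])), mean(lap(st$bimfs[[4]])))
})
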