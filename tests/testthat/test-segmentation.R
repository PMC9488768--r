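test_that("region means split the image by the mask", {
  d <- disk_image(16, 5, inside = 200, outside = 50)
  st <- region_means(d$image, d$truth)
  expect_equal(st$c1, 200)
  expect_equal(st$c2, 50)

  const <- matrix(5, 8, 8)
  mask <- matrix(0, 8, 8); mask[3:5, 3:5] <- 1
  expect_equal(region_means(const, mask), list(c1 = 5, c2 = 5))

  expect_error(region_means(const, matrix(0, 8, 8)), class = "empty_region")

  set.seed(9)
  img <- matrix(rnorm(64), 8, 8)
  m <- matrix(rbinom(64, 1, 0.4), 8, 8); m[1, 1] <- 1; m[8, 8] <- 0
  st <- region_means(img, m)
  expect_equal(st$c1, sum(img[m == 1]) / sum(m == 1))
  expect_equal(st$c2, sum(img[m == 0]) / sum(m == 0))
})

test_that("the discrete energy vanishes at an aligned two-tone partition", {
  d <- disk_image(16, 5, inside = 200, outside = 50)
  p0 <- chanvese_params(mu = 0, nu = 0)
  expect_equal(fitting_energy(d$image, d$truth, params = p0), 0)
})

test_that("the discrete energy matches a scalar double-loop oracle", {
  d <- disk_image(8, 3, inside = 200, outside = 50)
  mask <- d$truth
  flip <- which(mask == 1)[1]
  mask[flip] <- 0  # one inside pixel moved outside
  st <- region_means(d$image, mask)
  e <- fitting_energy(d$image, mask, st, chanvese_params(mu = 0, nu = 0))
  e_oracle <- 0
  for (i in 1:8) for (j in 1:8) {
    dev <- if (mask[i, j] == 1) d$image[i, j] - st$c1 else d$image[i, j] - st$c2
    e_oracle <- e_oracle + dev^2
  }
  expect_equal(e, e_oracle)
})

test_that("the length term counts 4-connected boundary pairs", {
  img <- matrix(5, 10, 10)  # constant: data terms are zero for any mask
  mask <- matrix(0, 10, 10); mask[4:5, 4:5] <- 1
  e <- fitting_energy(img, mask, params = chanvese_params(mu = 1, nu = 0))
  expect_equal(e, 8)  # 2x2 square: 8 boundary pairs
})

test_that("the contour recovers a clean disk and survives noise", {
  d <- disk_image(64, 16, noise_sd = 0)
  m <- evolve_contour(d$image)
  expect_gte(dice_coefficient(m, d$truth), 0.98)

  d <- disk_image(64, 16, noise_sd = 10, seed = 4)
  m <- evolve_contour(d$image)
  expect_gte(dice_coefficient(m, d$truth), 0.95)
  e <- attr(m, "energies")
  expect_true(all(diff(e) <= 1e-9))
  expect_lte(e[length(e)], e[1])
})

test_that("a constant image leaves the initial contour unmoved", {
  const <- matrix(100, 32, 32)
  m <- evolve_contour(const)
  expect_true(sum(m) > 0 && sum(m) < length(m))
  # auto-mu is 0 on a zero-range image: no force anywhere, initializer kept
  rr <- matrix(1:32, 32, 32)
  init <- (16 * 0.35 * 2 - sqrt((rr - 16.5)^2 + (t(rr) - 16.5)^2) >= 0) + 0
  expect_equal(sum(m != init), 0)
})

test_that("segmentation achieves Dice >= 0.95 on noisy disks across 20 seeds", {
  d0 <- disk_image(64, 16)
  for (s in 1:20) {
    set.seed(s)
    img <- d0$image + matrix(rnorm(64^2, 0, 10), 64, 64)
    m <- lesion_mask(img)
    expect_gte(dice_coefficient(m, d0$truth), 0.95)
    expect_true(all(diff(attr(evolve_contour(img), "energies")) <= 1e-9))
  }
})

test_that("lesion polarity is chosen against the border ring", {
  dark <- disk_image(64, 16, inside = 60, outside = 190, noise_sd = 3, seed = 2)
  m_dark <- lesion_mask(dark$image)
  expect_gte(dice_coefficient(m_dark, dark$truth), 0.95)
  expect_equal(attr(m_dark, "polarity"), "dark")

  bright <- disk_image(64, 16, inside = 190, outside = 60, noise_sd = 3, seed = 2)
  m_bright <- lesion_mask(bright$image)
  expect_gte(dice_coefficient(m_bright, bright$truth), 0.95)
  expect_equal(attr(m_bright, "polarity"), "bright")
})

test_that("segmentation is invariant to intensity shifts and inversion", {
  d <- disk_image(64, 16, noise_sd = 5, seed = 6)
  m0 <- lesion_mask(d$image)
  m_shift <- lesion_mask(d$image + 40)
  m_inv <- lesion_mask(255 - d$image)
  expect_equal(sum(m0 != m_shift), 0)
  expect_equal(sum(m0 != m_inv), 0)
})

test_that("returned lesion masks have no holes", {
  d <- disk_image(64, 18, noise_sd = 0)
  img <- d$image
  img[30:34, 30:34] <- 50  # background-coloured pocket inside the disk
  m <- lesion_mask(img)
  expect_true(all(m[30:34, 30:34] == 1))
  # complement inside the bounding box of the mask is a single component
  comp <- as.matrix(EBImage::bwlabel(1 - m))
  expect_equal(length(setdiff(unique(comp[m == 0]), 0L)), 1L)
})

test_that("updating the means never increases the fit term for a fixed mask", {
  set.seed(77)
  img <- matrix(runif(400, 0, 255), 20, 20)
  mask <- matrix(rbinom(400, 1, 0.5), 20, 20); mask[1] <- 1; mask[400] <- 0
  p0 <- chanvese_params(mu = 0, nu = 0)
  e_opt <- fitting_energy(img, mask, region_means(img, mask), p0)
  for (i in 1:20) {
    st <- list(c1 = runif(1, 0, 255), c2 = runif(1, 0, 255))
    expect_gte(fitting_energy(img, mask, st, p0), e_opt)
  }
})
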