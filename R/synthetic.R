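#' Parameters of the synthetic lesion-image generator
#'
#' The generator emulates the working material of the classification
#' pipeline: square grayscale crops containing one contrasting, irregularly
#' shaped lesion on a noisy, unevenly lit skin-like background, with
#' ground-truth masks and class labels. Class identity is carried purely by
#' the *interior texture* (an oriented sinusoid plus class-graded speckle),
#' not by mean intensity, so a classifier can only succeed through the
#' texture statistics the LBP features measure.
#'
#' @param side Image side length in pixels, default 200.
#' @param n_classes Number of lesion classes, default 7.
#' @param train_per_class,test_per_class Samples per class in each split,
#'   defaults 70 and 45.
#' @param noise_sd Gaussian background noise, default 8 intensity units.
#' @param illum_gradient Edge-to-edge linear illumination drift, default 15
#'   units.
#' @param lesion_darker If `TRUE` (default) the lesion is darker than the
#'   background, the usual dermoscopy polarity; `FALSE` inverts the image to
#'   exercise polarity selection in segmentation.
#' @param seed Master seed for [generate_dataset()].
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(side = 200L, n_classes = 7L, train_per_class = 70L,
                         test_per_class = 45L, noise_sd = 8,
                         illum_gradient = 15, lesion_darker = TRUE, seed = 1L) {
  if (side < 16) stop("`side` must be at least 16", call. = FALSE)
  if (n_classes < 1) stop("`n_classes` must be >= 1", call. = FALSE)
  if (train_per_class < 1 || test_per_class < 1) {
    stop("per-class sample counts must be >= 1", call. = FALSE)
  }
  if (noise_sd < 0 || illum_gradient < 0) {
    stop("`noise_sd` and `illum_gradient` must be >= 0", call. = FALSE)
  }
  structure(list(side = as.integer(side), n_classes = as.integer(n_classes),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 noise_sd = noise_sd, illum_gradient = illum_gradient,
                 lesion_darker = isTRUE(lesion_darker), seed = as.integer(seed)),
            class = "synth_params")
}

# Star-convex blob mask: periodic cubic spline through jittered control
# radii around a near-central point. Redrawn (deterministically, continuing
# the RNG stream) if the area leaves the 10-60% frame-fraction band.
synth_blob_mask <- function(side, mean_radius, jitter = 0.3) {
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  for (try in 1:20) {
    cy <- stats::runif(1, 0.42, 0.58) * side
    cx <- stats::runif(1, 0.42, 0.58) * side
    n_ctrl <- 12L
    ang <- seq(0, 2 * pi, length.out = n_ctrl + 1L)
    rad <- mean_radius * stats::runif(n_ctrl, 1 - jitter, 1 + jitter)
    rfun <- stats::splinefun(ang, c(rad, rad[1]), method = "periodic")
    theta <- atan2(cc - cx, -(rr - cy)) %% (2 * pi)
    dist <- sqrt((rr - cy)^2 + (cc - cx)^2)
    mask <- (dist <= rfun(theta)) + 0
    frac <- mean(mask)
    if (frac >= 0.10 && frac <= 0.60) return(mask)
  }
  mask
}

#' Generate one synthetic lesion sample
#'
#' The background is base intensity 180 plus a linear illumination gradient
#' and Gaussian noise. The lesion support is a random star-convex blob of
#' mean radius `0.25 * side` with +/-30% radial jitter. Inside, the texture
#' of class `k = label - 1` is base intensity 90 plus an oriented sinusoid of
#' frequency `(2 + k) / 64` cycles/pixel at orientation `k * 180 / 7` degrees
#' and amplitude 25, plus zero-mean speckle of standard deviation `3 k`
#' (variance grows with class). Intensities are clipped to `[0, 255]`. The
#' same `(label, seed, params)` always yields the identical sample.
#'
#' @param label Class label in `1..n_classes`.
#' @param seed Per-sample seed.
#' @param params A [synth_params()] object.
#' @return A list of class `synth_sample` with `image`, `true_mask`, `label`.
#' @export
generate_sample <- function(label, seed, params = synth_params()) {
  if (label < 1 || label > params$n_classes || label != as.integer(label)) {
    stop(sprintf("`label` must be an integer in 1..%d", params$n_classes),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  side <- params$side
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)

  # Background: base 180, linear drift along a random direction, noise.
  dir <- stats::runif(1, 0, 2 * pi)
  proj <- ((rr - 1) / (side - 1) - 0.5) * cos(dir) +
    ((cc - 1) / (side - 1) - 0.5) * sin(dir)
  img <- 180 + params$illum_gradient * proj
  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(side * side, 0, params$noise_sd), side, side)
  }

  mask <- synth_blob_mask(side, 0.25 * side)

  # Interior texture: class-specific oriented sinusoid plus graded speckle.
  k <- label - 1L
  freq <- (2 + k) / 64
  theta <- k * pi / 7
  phase <- stats::runif(1, 0, 2 * pi)
  tex <- 90 + 25 * sin(2 * pi * freq * (cc * cos(theta) + rr * sin(theta)) + phase)
  if (k > 0) {
    tex <- tex + matrix(stats::rnorm(side * side, 0, 3 * k), side, side)
  }
  inside <- mask == 1
  img[inside] <- tex[inside]
  img <- pmin(pmax(img, 0), 255)
  if (!params$lesion_darker) img <- 255 - img
  structure(list(image = img, true_mask = mask, label = as.integer(label)),
            class = "synth_sample")
}

#' Manifest of per-sample seeds for a full dataset
#'
#' Derives one independent sub-seed per sample from the master seed, so
#' datasets are reproducible and samples can be regenerated individually
#' (or streamed) without materializing the whole collection.
#'
#' @param params A [synth_params()] object.
#' @return A tibble with columns `split` ("train"/"test"), `label`, `seed`.
#' @export
dataset_manifest <- function(params = synth_params()) {
  n <- params$n_classes * (params$train_per_class + params$test_per_class)
  set.seed(params$seed)
  seeds <- sample.int(.Machine$integer.max, n)
  split <- c(rep("train", params$n_classes * params$train_per_class),
             rep("test", params$n_classes * params$test_per_class))
  label <- c(rep(seq_len(params$n_classes), each = params$train_per_class),
             rep(seq_len(params$n_classes), each = params$test_per_class))
  tibble::tibble(split = split, label = label, seed = seeds)
}

#' Generate a balanced train/test dataset
#'
#' @param params A [synth_params()] object.
#' @return A list with `train` and `test`, each a list of
#'   [generate_sample()] results, plus the `manifest` tibble.
#' @export
#' @examples
#' p <- synth_params(side = 32, n_classes = 2, train_per_class = 2,
#'                   test_per_class = 1, seed = 7)
#' d <- generate_dataset(p)
#' lengths(d[c("train", "test")])
generate_dataset <- function(params = synth_params()) {
  man <- dataset_manifest(params)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    generate_sample(man$label[i], man$seed[i], params)
  })
  list(train = samples[man$split == "train"],
       test = samples[man$split == "test"],
       manifest = man)
}
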