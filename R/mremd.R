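#' Parameters for multi-resolution empirical mode decomposition
#'
#' MREMD replaces the adaptive, extrema-driven envelope estimation of
#' classical bidimensional EMD with order-statistic filtering over a fixed
#' window, and captures coarser structure at each level by dyadic
#' downsampling rather than by growing the window. The fixed window makes the
#' decomposition insensitive to the number of extrema in the image and
#' removes the per-level window-size search.
#'
#' @param envelope_window Odd window side (pixels) for the max/min envelope
#'   filters; default 5.
#' @param smooth_window Odd window side (pixels) for the moving-average
#'   smoothing applied to the working copy, the envelopes, and the upsampled
#'   mean envelope; default 5, tied to the envelope window.
#' @param n_levels Number of intrinsic mode functions to extract; default 4.
#' @param min_side Decomposition stops before a level whose downsampled side
#'   would fall below this (or below the envelope window); default 8.
#' @return A list of class `mremd_params`.
#' @export
mremd_params <- function(envelope_window = 5L, smooth_window = 5L,
                         n_levels = 4L, min_side = 8L) {
  envelope_window <- assert_odd_window(envelope_window)
  smooth_window <- assert_odd_window(smooth_window)
  if (envelope_window < 3L) stop("`envelope_window` must be >= 3", call. = FALSE)
  if (n_levels < 1L) stop("`n_levels` must be >= 1", call. = FALSE)
  if (min_side < 1L) stop("`min_side` must be >= 1", call. = FALSE)
  structure(list(envelope_window = envelope_window,
                 smooth_window = smooth_window,
                 n_levels = as.integer(n_levels),
                 min_side = as.integer(min_side)),
            class = "mremd_params")
}

#' Moving-average (box) smoothing with replicate padding
#'
#' Each output pixel is the mean of the `k x k` neighbourhood; windows
#' hanging over the border reuse the clamped edge pixel, so no intensities
#' are invented and constants are preserved exactly.
#'
#' @param img Numeric intensity matrix.
#' @param k Odd positive window side; `k = 1` is the identity.
#' @return A matrix of the same shape.
#' @export
box_smooth <- function(img, k) {
  assert_image(img)
  k <- assert_odd_window(k)
  if (k == 1L) return(img)
  h <- (k - 1L) %/% 2L
  # Separable clamped-window sums: rows first, then columns. With replicate
  # padding this equals the full 2-D padded window sum.
  acc <- matrix(0, nrow(img), ncol(img))
  for (d in -h:h) acc <- acc + img[, clamp_seq(ncol(img), d), drop = FALSE]
  out <- matrix(0, nrow(img), ncol(img))
  for (d in -h:h) out <- out + acc[clamp_seq(nrow(img), d), , drop = FALSE]
  out / (k * k)
}

#' Windowed max/min envelopes
#'
#' The upper (lower) envelope value at each pixel is the maximum (minimum)
#' intensity in the `k x k` window centred there, with replicate padding.
#' This is the fixed-window order-statistic estimate MREMD uses in place of
#' surface interpolation over detected extrema.
#'
#' @param img Numeric intensity matrix.
#' @param k Odd window side, at least 3.
#' @return A list with matrices `upper` and `lower`; `upper >= img >= lower`
#'   pointwise.
#' @export
window_extrema <- function(img, k) {
  assert_image(img)
  k <- assert_odd_window(k)
  if (k < 3L) stop("`k` must be >= 3 for envelope formation", call. = FALSE)
  h <- (k - 1L) %/% 2L
  up <- img; lo <- img
  for (d in setdiff(-h:h, 0L)) {
    up <- pmax(up, img[, clamp_seq(ncol(img), d), drop = FALSE])
    lo <- pmin(lo, img[, clamp_seq(ncol(img), d), drop = FALSE])
  }
  up2 <- up; lo2 <- lo
  for (d in setdiff(-h:h, 0L)) {
    up2 <- pmax(up2, up[clamp_seq(nrow(img), d), , drop = FALSE])
    lo2 <- pmin(lo2, lo[clamp_seq(nrow(img), d), , drop = FALSE])
  }
  list(upper = up2, lower = lo2)
}

#' Clamp envelopes against a reference image
#'
#' After smoothing, the envelopes can cut through local extrema of the
#' working copy; clamping restores the defining property that the upper
#' envelope passes at or above every pixel and the lower envelope at or
#' below: `upper' = max(upper, ref)`, `lower' = min(lower, ref)`.
#'
#' @param upper,lower,ref Matrices of one shape.
#' @return A list with clamped `upper` and `lower`.
#' @export
clamp_envelopes <- function(upper, lower, ref) {
  assert_same_shape(upper, lower, "envelopes")
  assert_same_shape(upper, ref, "envelope and reference")
  list(upper = pmax(upper, ref), lower = pmin(lower, ref))
}

#' Dyadic downsampling by stride decimation
#'
#' Keeps every `factor`-th pixel along both axes starting at the first, so a
#' `H x W` image becomes `ceiling(H/factor) x ceiling(W/factor)`. The working
#' copy is smoothed immediately after downsampling, which is why plain
#' decimation (rather than block averaging) suffices here.
#'
#' @param img Numeric matrix.
#' @param factor Power-of-two stride (1, 2, 4, ...); 1 is the identity.
#' @return The decimated matrix.
#' @export
dyadic_downsample <- function(img, factor) {
  assert_image(img)
  if (!is_power_of_two(factor)) {
    stop("`factor` must be a power of two (1, 2, 4, ...)", call. = FALSE)
  }
  if (factor == 1) return(img)
  img[seq(1L, nrow(img), by = factor), seq(1L, ncol(img), by = factor), drop = FALSE]
}

#' Upsampling by pixel replication
#'
#' Expands each source pixel to a `factor x factor` block and crops to the
#' requested target size, the exact inverse bookkeeping of
#' [dyadic_downsample()]'s ceiling dimensions for non-divisible sides.
#'
#' @param img Numeric matrix.
#' @param factor Power-of-two replication factor.
#' @param target_h,target_w Target dimensions; must satisfy
#'   `ceiling(target/factor) == dim(img)`.
#' @return A `target_h x target_w` matrix.
#' @export
upsample_replicate <- function(img, factor, target_h, target_w) {
  assert_image(img)
  if (!is_power_of_two(factor)) {
    stop("`factor` must be a power of two (1, 2, 4, ...)", call. = FALSE)
  }
  if (ceiling(target_h / factor) != nrow(img) ||
      ceiling(target_w / factor) != ncol(img)) {
    stop(sprintf(
      "target %dx%d is incompatible with a %dx%d source at factor %d",
      target_h, target_w, nrow(img), ncol(img), factor), call. = FALSE)
  }
  if (factor == 1) return(img)
  ri <- rep(seq_len(nrow(img)), each = factor)[seq_len(target_h)]
  ci <- rep(seq_len(ncol(img)), each = factor)[seq_len(target_w)]
  img[ri, ci, drop = FALSE]
}

#' One sifting pass: extract a single BIMF and the next mean envelope
#'
#' For level `n` the input is the previous mean envelope (the original image
#' at level 1). The working copy is downsampled by `2^(n-1)`, box-smoothed,
#' its windowed max/min envelopes are formed, smoothed, and clamped against
#' the smoothed working copy; their average is the mean envelope, which for
#' levels above 1 is replicated back to full resolution and smoothed once
#' more to remove blockiness. The BIMF is the input minus the mean envelope,
#' computed against the *unsmoothed* input so that the decomposition
#' telescopes exactly. One pass per level is performed (no inner sifting
#' iterations).
#'
#' @param input_mean Full-resolution input (the image or the previous mean
#'   envelope).
#' @param level Sifting level, 1-based.
#' @param params An [mremd_params()] object.
#' @return A list with `bimf` and `next_mean`, both at full resolution;
#'   `bimf + next_mean` reproduces `input_mean` exactly.
#' @export
sift_level <- function(input_mean, level, params = mremd_params()) {
  assert_image(input_mean)
  if (level < 1L || level != as.integer(level)) {
    stop("`level` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(2^(level - 1L))
  h <- nrow(input_mean); w <- ncol(input_mean)
  work <- dyadic_downsample(input_mean, factor)
  if (min(dim(work)) < max(params$envelope_window, params$min_side)) {
    stop(lesiontex_error(
      "mremd_depth_exceeded",
      sprintf("level %d: downsampled side %d is below the working minimum %d",
              level, min(dim(work)), max(params$envelope_window, params$min_side)),
      level = level))
  }
  y <- box_smooth(work, params$smooth_window)
  env <- window_extrema(y, params$envelope_window)
  upper <- box_smooth(env$upper, params$smooth_window)
  lower <- box_smooth(env$lower, params$smooth_window)
  env <- clamp_envelopes(upper, lower, y)
  m <- (env$upper + env$lower) / 2
  if (factor > 1L) {
    m <- upsample_replicate(m, factor, h, w)
    m <- box_smooth(m, params$smooth_window)
  }
  list(bimf = input_mean - m, next_mean = m)
}

#' Decompose an image into bidimensional intrinsic mode functions
#'
#' Chains [sift_level()] for levels `1..n_levels`, feeding each mean envelope
#' into the next level, and returns the ordered BIMFs together with the final
#' full-resolution mean envelope (the residual). Decomposition stops early if
#' a level's downsampled image would be smaller than the envelope window or
#' `min_side`. By construction the element-wise sum of all BIMFs plus the
#' residual reproduces the input exactly.
#'
#' @param img Numeric intensity matrix.
#' @param params An [mremd_params()] object.
#' @return An object of class `bimf_stack`: a list with `bimfs` (list of
#'   matrices, finest first), `residual_mean`, and `source_shape`.
#' @export
#' @examples
#' img <- matrix(runif(32 * 32, 0, 255), 32, 32)
#' stack <- mremd_decompose(img, mremd_params(n_levels = 2))
#' max(abs(mremd_reconstruct(stack) - img)) < 1e-9
mremd_decompose <- function(img, params = mremd_params()) {
  assert_image(img)
  bimfs <- vector("list", 0L)
  current <- img
  for (lev in seq_len(params$n_levels)) {
    res <- tryCatch(sift_level(current, lev, params),
                    mremd_depth_exceeded = function(e) e)
    if (inherits(res, "mremd_depth_exceeded")) {
      if (length(bimfs) == 0L) stop(res)
      break
    }
    bimfs[[lev]] <- res$bimf
    current <- res$next_mean
  }
  structure(list(bimfs = bimfs, residual_mean = current,
                 source_shape = dim(img)),
            class = "bimf_stack")
}

#' Reconstruct the source image from a BIMF stack
#'
#' Element-wise sum of all BIMFs and the residual mean envelope. Because each
#' BIMF was defined as the difference between consecutive mean envelopes the
#' sum telescopes back to the input.
#'
#' @param stack A `bimf_stack` from [mremd_decompose()].
#' @return The reconstructed intensity matrix.
#' @export
mremd_reconstruct <- function(stack) {
  if (!inherits(stack, "bimf_stack")) stop("`stack` must be a bimf_stack", call. = FALSE)
  out <- stack$residual_mean
  for (b in stack$bimfs) {
    assert_same_shape(out, b, "stack components")
    out <- out + b
  }
  out
}

#' @export
print.bimf_stack <- function(x, ...) {
  cat(sprintf("<bimf_stack> %d BIMF(s) + residual, source %dx%d\n",
              length(x$bimfs), x$source_shape[1], x$source_shape[2]))
  invisible(x)
}
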