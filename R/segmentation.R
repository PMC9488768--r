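#' Parameters for Chan-Vese active contour segmentation
#'
#' The contour minimizes
#' `mu * length(C) + nu * area(inside C) +
#'  lambda1 * sum_inside (u0 - c1)^2 + lambda2 * sum_outside (u0 - c2)^2`,
#' where `c1`/`c2` are the mean intensities inside/outside the curve. With
#' the default simplification `lambda1 = lambda2 = 1`, `nu = 0` only the
#' region-fit terms and the length penalty act.
#'
#' `mu` carries units of squared intensity per unit contour length; when left
#' `NULL` it defaults to `0.1 * range(img)^2 / sqrt(H^2 + W^2)` at
#' segmentation time, so the length penalty scales with the image's intensity
#' contrast while staying well below the per-pixel data terms.
#'
#' @param mu Length-term weight (`NULL` = data-dependent default above).
#' @param nu Area-term weight, default 0.
#' @param lambda1,lambda2 Inside/outside fit weights, default 1.
#' @param max_iter Iteration cap, default 300.
#' @param tol Relative energy-change stopping tolerance, default 1e-4.
#' @param init_radius_frac Initial contour: centred circle with radius
#'   `init_radius_frac * min(H, W)`, default 0.35.
#' @param epsilon Width (pixels) of the smoothed Heaviside/delta used in the
#'   level-set evolution, default 1.
#' @return A list of class `chanvese_params`.
#' @export
chanvese_params <- function(mu = NULL, nu = 0, lambda1 = 1, lambda2 = 1,
                            max_iter = 300L, tol = 1e-4,
                            init_radius_frac = 0.35, epsilon = 1) {
  if (!is.null(mu) && mu < 0) stop("`mu` must be >= 0", call. = FALSE)
  if (nu < 0) stop("`nu` must be >= 0", call. = FALSE)
  if (lambda1 <= 0 || lambda2 <= 0) stop("`lambda1`, `lambda2` must be > 0", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  structure(list(mu = mu, nu = nu, lambda1 = lambda1, lambda2 = lambda2,
                 max_iter = as.integer(max_iter), tol = tol,
                 init_radius_frac = init_radius_frac, epsilon = epsilon),
            class = "chanvese_params")
}

#' Mean intensities inside and outside a mask
#'
#' @param img Numeric intensity matrix.
#' @param mask Binary matrix of the same shape (1 = inside).
#' @return A list with `c1` (inside mean) and `c2` (outside mean).
#' @export
region_means <- function(img, mask) {
  assert_image(img)
  assert_mask(mask)
  assert_same_shape(img, mask, "image and mask")
  inside <- mask == 1
  n_in <- sum(inside)
  if (n_in == 0L || n_in == length(mask)) {
    stop(lesiontex_error("empty_region",
                         "one of the two regions is empty; cannot form region means"))
  }
  list(c1 = mean(img[inside]), c2 = mean(img[!inside]))
}

#' Discrete Chan-Vese energy of a mask
#'
#' Data terms are summed squared deviations from the region means; the length
#' term counts 4-connected neighbour pairs whose mask values differ (a
#' discrete perimeter); the area term counts inside pixels.
#'
#' @param img Numeric intensity matrix.
#' @param mask Binary matrix.
#' @param stats Optional precomputed [region_means()]; recomputed if `NULL`.
#' @param params A [chanvese_params()] object (a `NULL` `mu` counts the
#'   length term with the data-dependent default weight).
#' @return The scalar energy.
#' @export
fitting_energy <- function(img, mask, stats = NULL, params = chanvese_params()) {
  assert_image(img)
  assert_mask(mask)
  assert_same_shape(img, mask, "image and mask")
  if (is.null(stats)) stats <- region_means(img, mask)
  mu <- resolve_mu(params$mu, img)
  inside <- mask == 1
  data_term <- params$lambda1 * sum((img[inside] - stats$c1)^2) +
    params$lambda2 * sum((img[!inside] - stats$c2)^2)
  perim <- sum(mask[-1, ] != mask[-nrow(mask), ]) +
    sum(mask[, -1] != mask[, -ncol(mask)])
  data_term + mu * perim + params$nu * sum(inside)
}

resolve_mu <- function(mu, img) {
  if (!is.null(mu)) return(mu)
  rng <- diff(range(img))
  0.1 * rng^2 / sqrt(nrow(img)^2 + ncol(img)^2)
}

#' Evolve a Chan-Vese contour on an image
#'
#' Level-set gradient descent on the regularized two-phase energy with a
#' smoothed Heaviside of width `epsilon`. Each iteration updates the region
#' means to their Heaviside-weighted optima (the exact minimizers of the
#' smoothed functional for a fixed contour) and then steps the bounded level-set
#' function along the energy gradient preconditioned by the smoothed delta (a
#' pointwise positive rescaling that preserves the descent property while
#' letting the front move away from the current zero level). The step size is
#' bounded by backtracking: it is halved until the smoothed energy does not
#' increase, so the recorded energy trace is non-increasing. Evolution stops
#' when the relative energy change falls below `tol`, when no decreasing step
#' exists, or at `max_iter`.
#'
#' @param img Numeric intensity matrix, larger than 8x8.
#' @param params A [chanvese_params()] object.
#' @return A binary mask (1 = inside the contour) with attributes
#'   `energies` (energy per recorded iteration, starting at the
#'   initializer's), `iterations`, and `region_means`.
#' @export
evolve_contour <- function(img, params = chanvese_params()) {
  assert_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h <= 8L || w <= 8L) stop("image must be larger than 8x8", call. = FALSE)
  mu <- resolve_mu(params$mu, img)

  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- params$init_radius_frac * min(h, w)
  # Bounded level-set profile: the signed distance to the initial circle,
  # capped at +/- 5 units so sign flips need few unit steps anywhere.
  phi_cap <- 5
  phi <- pmin(pmax(r0 - sqrt((rr - (h + 1) / 2)^2 + (cc - (w + 1) / 2)^2),
                   -phi_cap), phi_cap)

  res <- .chanvese_evolve(img, phi, mu, params$nu, params$lambda1,
                          params$lambda2, params$epsilon, params$tol,
                          params$max_iter, phi_cap)
  if (isTRUE(res$collapsed)) {
    stop(lesiontex_error("contour_collapse",
                         sprintf("contour collapsed to a single region at iteration %d",
                                 res$iterations),
                         iteration = res$iterations))
  }
  mask <- (res$phi >= 0) + 0
  n_in <- sum(mask)
  if (n_in == 0L || n_in == length(mask)) {
    stop(lesiontex_error("contour_collapse",
                         sprintf("contour collapsed after %d iterations", res$iterations),
                         iteration = res$iterations))
  }
  attr(mask, "energies") <- res$energies
  attr(mask, "iterations") <- res$iterations
  attr(mask, "region_means") <- region_means(img, mask)
  mask
}

#' Segment the lesion region of an image
#'
#' Runs [evolve_contour()] and post-processes its two-phase partition into a
#' lesion mask: the lesion side is the region whose mean intensity differs
#' most from the mean of the 5-pixel image border ring (lesions sit centrally
#' in dermoscopy crops, so the border ring samples background regardless of
#' polarity), then the largest 8-connected component is kept and its holes
#' filled.
#'
#' @param img Numeric intensity matrix.
#' @param params A [chanvese_params()] object.
#' @return A binary lesion mask with attribute `polarity` (`"dark"` or
#'   `"bright"` lesion relative to the border ring).
#' @export
lesion_mask <- function(img, params = chanvese_params()) {
  assert_image(img)
  raw <- evolve_contour(img, params)
  h <- nrow(img); w <- ncol(img)
  ring <- matrix(FALSE, h, w)
  b <- min(5L, h %/% 2L, w %/% 2L)
  ring[c(seq_len(b), h - seq_len(b) + 1L), ] <- TRUE
  ring[, c(seq_len(b), w - seq_len(b) + 1L)] <- TRUE
  ring_mean <- mean(img[ring])
  st <- region_means(img, raw)
  mask <- if (abs(st$c1 - ring_mean) >= abs(st$c2 - ring_mean)) raw else 1 - raw
  mask <- largest_component_8(mask)
  mask <- as.matrix(EBImage::fillHull(mask))
  lesion_mean <- mean(img[mask == 1])
  if (sum(mask) < 25) {
    stop(lesiontex_error("segmentation_too_small",
                         sprintf("segmented lesion has only %d pixels", sum(mask))))
  }
  attr(mask, "polarity") <- if (lesion_mean < ring_mean) "dark" else "bright"
  mask
}

# Largest 8-connected foreground component. EBImage::bwlabel is 4-connected;
# labels that touch diagonally are merged with a union-find pass.
largest_component_8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n <= 1L) return((lab > 0) + 0)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  h <- nrow(lab); w <- ncol(lab)
  diag_pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))
  )
  diag_pairs <- diag_pairs[diag_pairs[, 1] > 0 & diag_pairs[, 2] > 0 &
                             diag_pairs[, 1] != diag_pairs[, 2], , drop = FALSE]
  if (nrow(diag_pairs) > 0) {
    diag_pairs <- unique(diag_pairs)
    for (i in seq_len(nrow(diag_pairs))) union_(diag_pairs[i, 1], diag_pairs[i, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  merged <- matrix(0L, h, w)
  nz <- lab > 0
  merged[nz] <- roots[lab[nz]]
  sizes <- tabulate(merged[nz], nbins = n)
  best <- which.max(sizes)
  (merged == best) + 0
}

#' Dice overlap between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b Binary matrices of one shape.
#' @return Scalar in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  assert_mask(a); assert_mask(b)
  assert_same_shape(a, b, "masks")
  2 * sum(a == 1 & b == 1) / (sum(a) + sum(b))
}
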