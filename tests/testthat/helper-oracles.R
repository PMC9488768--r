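# Independent brute-force oracles: plain nested loops with no shared code
# paths with the package implementations they check.

oracle_box_mean <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  r <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      s <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          s <- s + img[ii, jj]
        }
      }
      out[i, j] <- s / (k * k)
    }
  }
  out
}

oracle_extrema <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  r <- (k - 1) / 2
  up <- matrix(-Inf, h, w); lo <- matrix(Inf, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          up[i, j] <- max(up[i, j], img[ii, jj])
          lo[i, j] <- min(lo[i, j], img[ii, jj])
        }
      }
    }
  }
  list(upper = up, lower = lo)
}

# LBP by explicit rotation enumeration on the label string.
oracle_lbp_code <- function(center, neighbors) {
  bits <- as.integer(neighbors > center)
  best <- 0L
  for (r in 0:7) {
    rot <- if (r == 0) bits else c(bits[(r + 1):8], bits[1:r])  # rotate left by r
    val <- sum(rot * 2^(7:0))
    if (val > best) best <- val
  }
  as.integer(best)
}

oracle_lbp_map <- function(img) {
  h <- nrow(img); w <- ncol(img)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      nb <- vapply(offs, function(o) {
        img[min(max(i + o[1], 1), h), min(max(j + o[2], 1), w)]
      }, numeric(1))
      out[i, j] <- oracle_lbp_code(img[i, j], nb)
    }
  }
  out
}

oracle_masked_hist <- function(codes, mask) {
  counts <- numeric(256)
  n <- 0
  for (i in seq_len(nrow(codes))) {
    for (j in seq_len(ncol(codes))) {
      if (mask[i, j] == 1) {
        counts[codes[i, j] + 1] <- counts[codes[i, j] + 1] + 1
        n <- n + 1
      }
    }
  }
  counts / n
}

# Bilinear resampling at the align-centers grid, scalar loops.
oracle_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      sr <- min(max((i - 0.5) * h / out_h - 0.5, 0), h - 1)
      sc <- min(max((j - 0.5) * w / out_w - 0.5, 0), w - 1)
      r0 <- min(floor(sr), h - 1); r1 <- min(r0 + 1, h - 1)
      c0 <- min(floor(sc), w - 1); c1 <- min(c0 + 1, w - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- (1 - fr) * ((1 - fc) * img[r0 + 1, c0 + 1] + fc * img[r0 + 1, c1 + 1]) +
        fr * ((1 - fc) * img[r1 + 1, c0 + 1] + fc * img[r1 + 1, c1 + 1])
    }
  }
  out
}

# Straight-line scalar re-statement of one sifting pass (level 1 only:
# no resampling), built exclusively on the loop oracles above.
oracle_sift_level1 <- function(img, env_k = 5, smooth_k = 5) {
  y <- oracle_box_mean(img, smooth_k)
  ext <- oracle_extrema(y, env_k)
  up <- oracle_box_mean(ext$upper, smooth_k)
  lo <- oracle_box_mean(ext$lower, smooth_k)
  up <- pmax(up, y)
  lo <- pmin(lo, y)
  m <- (up + lo) / 2
  list(bimf = img - m, next_mean = m)
}

# Test image builders -------------------------------------------------------

disk_image <- function(side = 64, radius = 16, inside = 200, outside = 50,
                       noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  ctr <- (side + 1) / 2
  truth <- ((rr - ctr)^2 + (cc - ctr)^2 <= radius^2) + 0
  img <- ifelse(truth == 1, inside, outside)
  if (noise_sd > 0) img <- img + matrix(rnorm(side^2, 0, noise_sd), side, side)
  list(image = img, truth = truth)
}

random_int_image <- function(h, w, lo = 0, hi = 255) {
  # integer-valued but double-typed, the storage mode images load as
  matrix(as.numeric(sample(lo:hi, h * w, replace = TRUE)), h, w)
}

# Central finite-difference gradient of the training loss for a subset of
# parameters, addressed as (field, index) pairs.
numeric_grad <- function(model, x, labels, field, idx, h = 1e-5) {
  vapply(idx, function(i) {
    mp <- model; mm <- model
    mp[[field]][i] <- mp[[field]][i] + h
    mm[[field]][i] <- mm[[field]][i] - h
    lp <- lesiontex:::ann_loss_grad(mp, x, labels, want_grad = FALSE)$loss
    lm <- lesiontex:::ann_loss_grad(mm, x, labels, want_grad = FALSE)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}
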