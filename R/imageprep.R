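#' Load a grayscale image
#'
#' Reads a PNG or JPEG file and returns its pixel values as a numeric matrix
#' on the `[0, 255]` intensity scale, the working representation used by every
#' stage of the pipeline. Colour images are converted to luminance with the
#' Rec. 601 weights `0.299 R + 0.587 G + 0.114 B`.
#'
#' Dermoscopic collections ship as 8-bit RGB files; whether a single channel
#' or a luminance mix is used upstream is a modelling choice, so the
#' conversion rule is documented here and applied uniformly.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A numeric matrix (rows = image rows) with values in `[0, 255]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' save_image(matrix(100, 4, 4), f)
#' img <- load_image(f)
#' img[1, 1]
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image: file not found at '%s'", path), call. = FALSE)
  }
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) {
                    stop(sprintf("cannot decode image '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  dat <- EBImage::imageData(img)
  if (length(dat) == 0L) {
    stop(sprintf("image '%s' has zero size", path), call. = FALSE)
  }
  # EBImage stores intensities in [0,1] with x = columns; transpose to the
  # row-major matrix convention used throughout.
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    if (nch >= 3L) {
      g <- 0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      g <- dat[, , 1]
    }
    g <- matrix(g, dim(dat)[1], dim(dat)[2])
  } else {
    g <- dat
  }
  out <- t(g) * 255
  # Source files are 8-bit; snap quantization residue so that integer gray
  # levels round-trip exactly through save/load.
  round(out, 6)
}

#' Save a grayscale image as 8-bit PNG
#'
#' Values are clipped to `[0, 255]` and rounded to the nearest 8-bit level.
#'
#' @param img Numeric matrix of intensities in `[0, 255]`.
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  assert_image(img)
  v <- round(pmin(pmax(img, 0), 255)) / 255
  EBImage::writeImage(EBImage::Image(t(v)), path)
  invisible(path)
}

#' Convert an RGB array to grayscale
#'
#' Applies the Rec. 601 luminance weights `0.299 R + 0.587 G + 0.114 B`.
#' An already-gray triple `(v, v, v)` maps to `v` exactly because the
#' weights sum to 1.
#'
#' @param rgb A numeric array `H x W x 3` (any consistent intensity scale).
#' @return A numeric `H x W` matrix on the same scale.
#' @export
rgb_to_gray <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] < 3L) {
    stop("`rgb` must be an H x W x 3 array", call. = FALSE)
  }
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(g, dim(rgb)[1], dim(rgb)[2])
}

#' Resize an image to the square working resolution
#'
#' Bilinear interpolation with pixel-center alignment: output pixel `(i, j)`
#' samples the input at `((i - 0.5) * H / side - 0.5)` (and likewise for
#' columns), clamped to the frame. Constant images stay constant and an input
#' already at the target size is returned unchanged.
#'
#' @param img Numeric intensity matrix.
#' @param side Target side length in pixels (default 200, the working
#'   resolution of the classification pipeline).
#' @return A `side x side` numeric matrix.
#' @export
resize_to_working <- function(img, side = 200L) {
  assert_image(img)
  if (length(side) != 1L || !is.numeric(side) || side < 1 || side != as.integer(side)) {
    stop("`side` must be a positive integer", call. = FALSE)
  }
  side <- as.integer(side)
  if (nrow(img) == side && ncol(img) == side) {
    return(img)
  }
  bilinear_resize(img, side, side)
}

# Bilinear resampling on the align-centers grid; used by resize_to_working.
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  src_r <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  src_c <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  r0 <- pmin(floor(src_r), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(floor(src_c), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- src_r - r0
  fc <- src_c - c0
  # Outer-product weighting of the four corner grids (1-based indexing).
  a <- img[r0 + 1, c0 + 1, drop = FALSE]
  b <- img[r0 + 1, c1 + 1, drop = FALSE]
  d <- img[r1 + 1, c0 + 1, drop = FALSE]
  e <- img[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}
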