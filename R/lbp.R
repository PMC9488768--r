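## Max-rotation local binary patterns.
##
## Each pixel is compared with its eight 3x3 neighbours; neighbours that
## strictly exceed the centre get label 1. Reading the eight labels clockwise
## gives an 8-bit code, and among its eight cyclic rotations the numerically
## largest byte is kept, which makes the code independent of the starting
## neighbour and (approximately) of in-plane rotation of the texture.

# Clockwise 3x3 neighbour offsets starting at top-left; the first neighbour
# holds the most significant bit before canonicalization.
lbp_offsets <- matrix(c(-1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L,
                        1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L),
                      ncol = 2L, byrow = TRUE)

# Lookup table: byte -> maximum over its 8 cyclic rotations.
lbp_rotation_lut <- local({
  rotl8 <- function(v, r) {
    bitwAnd(bitwOr(bitwShiftL(v, r), bitwShiftR(v, 8L - r)), 255L)
  }
  vapply(0:255, function(v) max(vapply(0:7, rotl8, integer(1), v = v)), integer(1))
})

#' LBP code of one 3x3 neighbourhood
#'
#' Labels each of the 8 neighbours 1 if it strictly exceeds the centre (ties
#' label 0), forms the clockwise 8-bit code, and returns the largest of its
#' eight cyclic rotations as an unsigned byte.
#'
#' @param center Centre pixel intensity.
#' @param neighbors Numeric vector of exactly 8 neighbour intensities,
#'   clockwise from the top-left.
#' @return Integer in `[0, 255]`.
#' @export
#' @examples
#' lbp_code(5, rep(6, 8))      # 255: every neighbour exceeds the centre
#' lbp_code(5, c(6, rep(4, 7)))  # 128: one set bit, rotated to the MSB
lbp_code <- function(center, neighbors) {
  if (length(neighbors) != 8L || !is.numeric(neighbors)) {
    stop("`neighbors` must be exactly 8 numeric values", call. = FALSE)
  }
  bits <- as.integer(neighbors > center)
  raw <- sum(bits * 2L^(7:0))
  lbp_rotation_lut[raw + 1L]
}

#' LBP code map of an image
#'
#' Applies [lbp_code()] at every pixel. Border pixels use replicate padding
#' so lesions touching the frame lose no area.
#'
#' @param img Numeric intensity matrix, at least 3x3.
#' @return Integer matrix of codes in `[0, 255]`, same shape as `img`.
#' @export
lbp_map <- function(img) {
  assert_image(img)
  if (nrow(img) < 3L || ncol(img) < 3L) {
    stop("image must be at least 3x3 for LBP", call. = FALSE)
  }
  raw <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(8L)) {
    nb <- shift_clamped(img, lbp_offsets[i, 1], lbp_offsets[i, 2])
    raw <- raw + as.integer(2L^(8L - i)) * (nb > img)
  }
  codes <- lbp_rotation_lut[raw + 1L]
  dim(codes) <- dim(img)
  codes
}

#' Area-normalized histogram of LBP codes inside a mask
#'
#' Counts each of the 256 codes over pixels with `mask == 1` and divides by
#' the masked area, so the 256 bins sum to 1 for any non-empty mask.
#'
#' @param codes Integer code matrix from [lbp_map()].
#' @param mask Binary matrix of the same shape.
#' @return Numeric vector of length 256 (bin `b + 1` holds code `b`).
#' @export
masked_histogram <- function(codes, mask) {
  assert_mask(mask)
  assert_same_shape(codes, mask, "codes and mask")
  sel <- codes[mask == 1]
  if (length(sel) == 0L) {
    stop(lesiontex_error("empty_mask", "mask selects no pixels"))
  }
  tabulate(sel + 1L, nbins = 256L) / length(sel)
}

#' Extract the 512-entry texture feature vector
#'
#' Concatenates the masked LBP histogram of the image (entries 1-256) with
#' that of its first BIMF (entries 257-512), both taken over the same lesion
#' mask. Entries therefore sum to 2 and each lies in `[0, 1]`.
#'
#' @param img Numeric intensity matrix.
#' @param bimf1 First BIMF of `img`, same shape.
#' @param mask Binary lesion mask, same shape, non-empty.
#' @return Numeric vector of length 512 with attribute `source_area` (the
#'   lesion pixel count).
#' @export
extract_features <- function(img, bimf1, mask) {
  assert_image(img)
  assert_image(bimf1)
  assert_same_shape(img, bimf1, "image and BIMF")
  assert_same_shape(img, mask, "image and mask")
  v <- c(masked_histogram(lbp_map(img), mask),
         masked_histogram(lbp_map(bimf1), mask))
  attr(v, "source_area") <- sum(mask == 1)
  v
}
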