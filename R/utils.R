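#' @keywords internal
"_PACKAGE"

## Internal validation and indexing helpers shared across modules.

assert_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(img)
}

assert_odd_window <- function(k, arg = deparse(substitute(k))) {
  if (length(k) != 1L || !is.numeric(k) || k < 1 || k != as.integer(k) || k %% 2L == 0L) {
    stop(sprintf("`%s` must be an odd positive integer, got %s", arg,
                 paste(k, collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(k))
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share one shape (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(NULL)
}

is_power_of_two <- function(x) {
  length(x) == 1L && is.numeric(x) && x >= 1 && x == as.integer(x) &&
    bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

assert_mask <- function(mask, arg = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary (0/1) matrix", arg), call. = FALSE)
  }
  invisible(mask)
}

# Clamped row/col index sequences used by replicate-padded window filters.
clamp_seq <- function(n, offset) {
  pmin.int(pmax.int(seq_len(n) + offset, 1L), n)
}

# Shift a matrix by (dr, dc) with replicate (edge-clamp) padding.
shift_clamped <- function(img, dr, dc) {
  img[clamp_seq(nrow(img), dr), clamp_seq(ncol(img), dc), drop = FALSE]
}

# Condition constructors so callers can test on class rather than message.
lesiontex_error <- function(class, message, ...) {
  structure(
    class = c(class, "lesiontex_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

#' @useDynLib lesiontex, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
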