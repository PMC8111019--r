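#' Bilinear resize to the network input size
#'
#' Resamples a grayscale intensity matrix to `side` x `side` pixels by
#' bilinear interpolation with centre-aligned sampling: output pixel centre
#' `i` maps to input coordinate `(i - 0.5) * H/side + 0.5` (1-based pixel
#' centres), clamped at the borders. Values are clipped to `[0, 1]`
#' afterwards. An input already at the target size is returned unchanged, so
#' the identity case is exact.
#'
#' @param image numeric matrix of intensities in `[0, 1]`, at least 2 x 2.
#' @param side target side length in pixels (default 224, the standard
#'   input size of the feature-extraction backbones).
#' @return a `side` x `side` numeric matrix with values in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(runif(64), 8, 8)
#' dim(resize_to_input(x, side = 4))
resize_to_input <- function(image, side = 224L) {
  .check_image(image)
  side <- as.integer(side)
  if (side < 1L) stop("'side' must be >= 1", call. = FALSE)
  if (nrow(image) == side && ncol(image) == side) return(image)
  out <- .bilinear_resize(image, side, side)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Centre-aligned separable bilinear resampling (rows then columns).
.bilinear_resize <- function(image, out_h, out_w) {
  interp_axis <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1L)
    list(lo = as.integer(lo), w = src - lo)
  }
  ry <- interp_axis(nrow(image), out_h)
  rx <- interp_axis(ncol(image), out_w)
  rows <- image[ry$lo, , drop = FALSE] * (1 - ry$w) +
    image[ry$lo + 1L, , drop = FALSE] * ry$w
  rows[, rx$lo, drop = FALSE] * rep(1 - rx$w, each = out_h) +
    rows[, rx$lo + 1L, drop = FALSE] * rep(rx$w, each = out_h)
}

.check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (anyNA(image) || !all(is.finite(image)))
    stop("image contains non-finite values", call. = FALSE)
  invisible(image)
}

#' Split an image into left and right halves
#'
#' The left half takes columns `1..floor(W/2)`, the right half the remaining
#' `ceiling(W/2)` columns, so `cbind(left, right)` reproduces the input
#' exactly. "Left" is meant in image coordinates (the viewer's left), not
#' anatomical laterality.
#'
#' @param image numeric matrix with at least 2 columns.
#' @return list with components `left` and `right`.
#' @export
split_halves <- function(image) {
  if (!is.matrix(image) || ncol(image) < 2L)
    stop("image must be a matrix with at least 2 columns", call. = FALSE)
  w <- ncol(image)
  half <- w %/% 2L
  list(left = image[, seq_len(half), drop = FALSE],
       right = image[, (half + 1L):w, drop = FALSE])
}

#' Flip an image horizontally
#'
#' Reverses column order; applying it twice returns the original image.
#'
#' @param image numeric matrix.
#' @return matrix of the same dimensions with columns reversed.
#' @export
hflip <- function(image) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}

#' Build the three aligned views of a radiograph
#'
#' Produces the view triplet the descriptor configurations are built from:
#' the whole image, the left half, and the horizontally flipped right half,
#' each independently resized to `side` x `side`. Flipping the right half is
#' a coarse registration step: on a bilaterally symmetric thorax the flipped
#' right half aligns with the left half, so asymmetric findings (such as a
#' one-sided pleural line) stand out in the comparison.
#'
#' @param image numeric intensity matrix in `[0, 1]`, or an image record
#'   list with a `pixels` element.
#' @param side view side length in pixels (default 224).
#' @return an object of class `view_set`: list with 224 x 224 matrices
#'   `whole`, `left` and `right_flipped`.
#' @export
#' @examples
#' v <- make_views(matrix(runif(32 * 32), 32, 32))
#' sapply(v, dim)
make_views <- function(image, side = 224L) {
  if (is.list(image) && !is.null(image$pixels)) image <- image$pixels
  .check_image(image)
  halves <- split_halves(image)
  out <- list(whole = resize_to_input(image, side),
              left = resize_to_input(halves$left, side),
              right_flipped = resize_to_input(hflip(halves$right), side))
  class(out) <- "view_set"
  out
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("<view_set> whole/left/right_flipped, %d x %d\n",
              nrow(x$whole), ncol(x$whole)))
  invisible(x)
}
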