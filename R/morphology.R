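#' Flat structuring elements
#'
#' @param shape `"square"` or `"disc"`.
#' @param size side length (square) or diameter (disc), in pixels.
#' @return a logical footprint matrix of class `struct_element` whose anchor
#'   is its center; the anchor is always contained in the footprint.
#' @export
struct_element <- function(shape = c("square", "disc"), size = 3) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1) stop_invalid("structuring element size must be >= 1")
  if (shape == "square") {
    fp <- matrix(TRUE, size, size)
  } else {
    r <- (size - 1) / 2
    ix <- seq_len(size) - 1 - r
    fp <- outer(ix^2, ix^2, `+`) <= r^2 + 1e-9
  }
  if (!any(fp)) stop_invalid("empty structuring element footprint")
  structure(fp, class = c("struct_element", "matrix"))
}

#' @noRd
as_kernel <- function(se) {
  if (inherits(se, "struct_element") || is.logical(se)) {
    fp <- unclass(se); storage.mode(fp) <- "double"
  } else fp <- as.matrix(se)
  if (!any(fp > 0)) stop_invalid("empty structuring element footprint")
  fp
}

#' White top-hat transform
#'
#' `f - (f opened by A)`: the residue of grayscale opening, isolating
#' bright features smaller than the structuring element. Nonnegative
#' everywhere, and identically zero on constant images.
#'
#' @param image real image matrix.
#' @param se a [struct_element] (or logical footprint matrix).
#' @return image matrix of the same shape.
#' @export
white_top_hat <- function(image, se) {
  assert_image(image)
  k <- as_kernel(se)
  out <- image - EBImage::opening(image, k)
  pmax(out, 0) # clamp tiny negative rounding residue
}

#' Black top-hat transform
#'
#' `(f closed by A) - f`: the residue of grayscale closing, isolating dark
#' features (pits) smaller than the structuring element. Nonnegative
#' everywhere.
#'
#' @inheritParams white_top_hat
#' @export
black_top_hat <- function(image, se) {
  assert_image(image)
  k <- as_kernel(se)
  out <- EBImage::closing(image, k) - image
  pmax(out, 0)
}

#' Grayscale opening / closing
#'
#' Exposed mainly for the morphological sandwich identity
#' `opening <= f <= closing` used in validation.
#'
#' @inheritParams white_top_hat
#' @export
gray_opening <- function(image, se) {
  assert_image(image)
  EBImage::opening(image, as_kernel(se))
}

#' @rdname gray_opening
#' @export
gray_closing <- function(image, se) {
  assert_image(image)
  EBImage::closing(image, as_kernel(se))
}
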