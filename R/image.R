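#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of nonnegative, finite intensities with
#' pixel-size metadata. Rows index y (top to bottom), columns index x; pixel
#' coordinates are 0-based, origin at the top-left. All spectral metrics in
#' the package consume this type.
#'
#' @param pixels numeric matrix of intensities (arbitrary units), all finite
#'   and >= 0, at least 2 x 2.
#' @param pixel_size physical size of one pixel in nanometres. The default
#'   32.27 nm makes a 128-pixel ROI span 4.13 um, the acquisition scale the
#'   default analysis parameters were chosen for. Metadata only: no metric
#'   depends on it.
#' @return a `gray_image`: the matrix with class and `pixel_size` attributes.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels, pixel_size = 32.27) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("all intensities must be nonnegative", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(pixels,
            pixel_size = as.numeric(pixel_size),
            class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param x object to coerce or test.
#' @param ... passed on to [gray_image()].
#' @export
as_gray_image <- function(x, ...) {
  if (is_gray_image(x)) return(x)
  gray_image(x, ...)
}

#' @rdname gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @export
as.matrix.gray_image <- function(x, ...) {
  m <- unclass(x)
  attr(m, "pixel_size") <- NULL
  m
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g nm/px, intensity range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' @export
plot.gray_image <- function(x, main = "", ...) {
  # transpose + row flip so the top-left pixel plots at the top-left
  m <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  graphics::image(m, col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, main = main, ...)
  invisible(x)
}

# internal: strip class, keep plain matrix
img_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_size") <- NULL
  m
}

# internal: the FFT pipeline is defined on even-sided squares only
assert_square_even <- function(img, what = "image") {
  h <- nrow(img); w <- ncol(img)
  if (h != w) {
    stop(sprintf("%s must be square, got %d x %d", what, h, w), call. = FALSE)
  }
  if (h %% 2L != 0L) {
    stop(sprintf("%s side must be even, got %d", what, h), call. = FALSE)
  }
  invisible(img)
}
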