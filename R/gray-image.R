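#' Grayscale image container
#'
#' A `gray_image` wraps a numeric matrix of 8-bit intensities in `[0, 255]`
#' together with optional physical pixel spacing. Coordinates throughout the
#' package are 0-based `(row, col)` with row 0 at the top of the image, and
#' windows are half-open.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`, at least 2 x 2.
#' @param spacing length-2 numeric `(spacing_y, spacing_x)`: physical size of
#'   one pixel along rows and columns (mm). Defaults to `c(1, 1)` so lengths
#'   are reported in pixel units.
#' @param provenance free-text source tag carried through the pipeline.
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing = c(1, 1), provenance = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two positive numbers (spacing_y, spacing_x)")
  structure(
    list(pixels = pixels, spacing = spacing,
         provenance = as.character(provenance)[1]),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing (%g, %g), range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

#' Binary mask container
#'
#' A logical raster with the same geometry as its source image. Used both for
#' the binarized iris segmentation and for the extracted border (the geodesic
#' domain).
#'
#' @param pixels logical matrix.
#' @param spacing length-2 numeric pixel spacing, inherited from the source
#'   image.
#' @param provenance free-text source tag.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing = c(1, 1), provenance = "") {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("mask pixels must be a logical matrix")
  if (anyNA(pixels)) stop("mask must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("spacing must be two positive numbers")
  structure(
    list(pixels = pixels, spacing = spacing,
         provenance = as.character(provenance)[1]),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)
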