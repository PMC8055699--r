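#' Preprocessing configuration
#'
#' Bundles the crop window, the histogram-matching reference and the
#' complement switch used by [measure_si()].
#'
#' @param crop_window `NULL` (use the full image) or an integer vector
#'   `(row_start, row_stop, col_start, col_stop)`, 0-based and half-open,
#'   from the top-left of the raster.
#' @param reference `NULL` (use [default_reference_histogram()]), a
#'   [gray_image], or a 256-bin histogram of counts.
#' @param apply_complement logical; invert intensities after matching
#'   (default `TRUE`: the iris band becomes the dark class).
#' @return an object of class `preprocess_config`.
#' @seealso [casia2_crop_window()] for the native CASIA2 export window.
#' @export
preprocess_config <- function(crop_window = NULL, reference = NULL,
                              apply_complement = TRUE) {
  if (!is.null(crop_window)) {
    crop_window <- as.integer(crop_window)
    if (length(crop_window) != 4L || anyNA(crop_window))
      stop("crop_window must be (row_start, row_stop, col_start, col_stop)")
    if (crop_window[1] >= crop_window[2] || crop_window[3] >= crop_window[4])
      stop("crop_window is empty")
  }
  if (!is.null(reference) && !is_gray_image(reference))
    reference <- validate_histogram(reference)
  structure(list(crop_window = crop_window, reference = reference,
                 apply_complement = isTRUE(apply_complement)),
            class = "preprocess_config")
}

#' Default crop window for native CASIA2 exports
#'
#' The scanner exports 1000 x 1414 rasters; the analysis region is a
#' 629 x 1102 window. Only the output size is fixed by convention; the
#' default offset is the top-left corner and can be overridden.
#'
#' @param row_start,col_start top-left corner of the window (0-based).
#' @return integer vector `(row_start, row_stop, col_start, col_stop)`.
#' @export
casia2_crop_window <- function(row_start = 0L, col_start = 0L) {
  c(row_start, row_start + 629L, col_start, col_start + 1102L)
}

validate_histogram <- function(h) {
  h <- as.numeric(h)
  if (length(h) != 256L || anyNA(h) || any(h < 0) || sum(h) <= 0)
    stop("reference histogram must have 256 non-negative bins with positive total")
  h
}

#' Crop an image to a region of interest
#'
#' @param image a [gray_image].
#' @param window integer `(row_start, row_stop, col_start, col_stop)`,
#'   0-based, half-open; must lie inside the image.
#' @return the cropped [gray_image]; spacing preserved.
#' @export
crop_to_roi <- function(image, window) {
  stopifnot(is_gray_image(image))
  w <- as.integer(window)
  if (length(w) != 4L) stop("window must have four entries")
  d <- dim(image$pixels)
  if (w[1] < 0L) stop("window row_start ", w[1], " below 0")
  if (w[3] < 0L) stop("window col_start ", w[3], " below 0")
  if (w[2] > d[1]) stop("window row_stop ", w[2], " exceeds image height ", d[1])
  if (w[4] > d[2]) stop("window col_stop ", w[4], " exceeds image width ", d[2])
  if (w[1] >= w[2] || w[3] >= w[4]) stop("window is empty")
  px <- image$pixels[(w[1] + 1L):w[2], (w[3] + 1L):w[4], drop = FALSE]
  gray_image(px, spacing = image$spacing, provenance = image$provenance)
}

#' Intensity histogram of an image
#'
#' @param image a [gray_image].
#' @return integer vector of 256 counts (bins 0..255).
#' @export
image_histogram <- function(image) {
  stopifnot(is_gray_image(image))
  tabulate(as.integer(round(image$pixels)) + 1L, nbins = 256L)
}

#' Match an image's histogram to a reference
#'
#' Classic 256-bin CDF-inversion histogram matching: each gray level `g` is
#' remapped to the smallest reference level whose cumulative frequency
#' reaches the source's cumulative frequency at `g` (ties broken toward the
#' lower output level). The mapping is monotone non-decreasing by
#' construction.
#'
#' @param image a [gray_image].
#' @param reference a [gray_image] or a 256-bin histogram of counts.
#' @return the remapped [gray_image]. A constant input cannot be matched
#'   meaningfully; it is mapped to the reference's median gray level with a
#'   warning.
#' @export
match_histogram <- function(image, reference) {
  stopifnot(is_gray_image(image))
  ref <- if (is_gray_image(reference)) image_histogram(reference)
         else validate_histogram(reference)
  src <- image_histogram(image)
  ref_cdf <- cumsum(ref) / sum(ref)
  lut <- histogram_match_lut(src, ref_cdf)
  if (sum(src > 0) == 1L) {
    med <- which(ref_cdf >= 0.5)[1] - 1L
    warning("constant input image: mapped to the reference's median gray level")
    lut[] <- med
  }
  px <- matrix(lut[as.integer(round(image$pixels)) + 1L],
               nrow = nrow(image$pixels))
  gray_image(px, spacing = image$spacing, provenance = image$provenance)
}

# LUT for CDF inversion: for each source level, smallest reference level whose
# CDF >= source CDF at that level.
histogram_match_lut <- function(src_hist, ref_cdf) {
  src_cdf <- cumsum(src_hist) / sum(src_hist)
  # findInterval on a non-decreasing ref_cdf: smallest j with ref_cdf[j] >= p
  vapply(src_cdf, function(p) which(ref_cdf >= p - 1e-12)[1] - 1L, integer(1))
}

#' Complement (negative) of a grayscale image
#'
#' Every pixel `v` becomes `255 - v`; an involution that reverses intensity
#' order so that bright iris tissue becomes the dark class.
#'
#' @param image a [gray_image].
#' @return the complemented [gray_image].
#' @export
complement_image <- function(image) {
  stopifnot(is_gray_image(image))
  gray_image(255 - image$pixels, spacing = image$spacing,
             provenance = image$provenance)
}

#' Histogram-matching reference for a given scene geometry
#'
#' Histogram matching followed by clustering is, in effect, a quantile
#' threshold at the reference's tissue fraction: the matched image inherits
#' the reference's histogram, so the reference must share the image's
#' approximate iris/background proportions. The study protocol picks a
#' good-quality scan from the same imaging setup as reference; the package
#' equivalent is the canonical synthetic phantom (crypt amplitude 6 px,
#' speckle 0.10, blur 1) rendered at the requested geometry.
#'
#' @param image_params named list of [synthetic_iris_spec()] geometry fields
#'   (`width`, `height`, `side_span`, `baseline_row`, `iris_thickness`,
#'   `pupil_gap`, ...). Defaults give the native 629 x 1102 analysis frame.
#' @return numeric vector of 256 bin counts.
#' @export
reference_histogram_for <- function(image_params = list()) {
  pars <- utils::modifyList(
    list(crypt_amplitude = 6, crypt_frequency = 8, speckle_sigma = 0.10,
         blur_sigma = 1, seed = 20210419L),
    image_params)
  image_histogram(render_iris(do.call(synthetic_iris_spec, pars))$image)
}

#' Default histogram-matching reference
#'
#' [reference_histogram_for()] at the native 629 x 1102 geometry, computed
#' once per session and cached. Images with a substantially different iris
#' fraction (other scanners, cropped phantoms) should supply their own
#' reference via [preprocess_config()].
#'
#' @return numeric vector of 256 bin counts.
#' @export
default_reference_histogram <- function() {
  if (is.null(.irissmooth_env$ref_hist))
    .irissmooth_env$ref_hist <- reference_histogram_for()
  .irissmooth_env$ref_hist
}

.irissmooth_env <- new.env(parent = emptyenv())

#' Run the full preprocessing chain
#'
#' Crop (if configured), histogram-match to the reference, complement.
#'
#' @param image a [gray_image].
#' @param config a [preprocess_config].
#' @return the preprocessed [gray_image].
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- image
  if (!is.null(config$crop_window)) out <- crop_to_roi(out, config$crop_window)
  ref <- config$reference
  if (is.null(ref)) ref <- default_reference_histogram()
  out <- match_histogram(out, ref)
  if (config$apply_complement) out <- complement_image(out)
  out
}
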