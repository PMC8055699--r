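#' Segmentation configuration
#'
#' @param k number of gray-level classes; the iris/background split needs
#'   exactly 2 and other values are rejected.
#' @param max_iter iteration cap for the histogram-domain K-means.
#' @param tol centroid-convergence tolerance in gray levels.
#' @param min_area smallest connected component kept (pixels); also the hole
#'   size filled.
#' @param closing_radius disk radius for morphological closing (pixels).
#' @param polarity which cluster is iris tissue: `"dark"` (default; correct
#'   after the intensity complement) or `"bright"`.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(k = 2L, max_iter = 100L, tol = 0.5,
                                min_area = 50L, closing_radius = 2L,
                                polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (k != 2L) stop("k must be 2: iris border vs background")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (min_area < 0L) stop("min_area must be >= 0")
  if (closing_radius < 0L) stop("closing_radius must be >= 0")
  structure(list(k = 2L, max_iter = as.integer(max_iter), tol = tol,
                 min_area = as.integer(min_area),
                 closing_radius = as.integer(closing_radius),
                 polarity = polarity),
            class = "segmentation_config")
}

#' Binarize an image by two-class K-means on the intensity histogram
#'
#' Deterministic Lloyd's algorithm in the 256-bin histogram domain with K=2:
#' centroids start at the image's 10th and 90th percentile intensities and
#' iterate until both move less than `tol` gray levels. Pixels are assigned
#' to the nearest final centroid; the foreground is the cluster matching
#' `config$polarity` (the darker cluster by default, i.e. iris tissue in the
#' complemented image).
#'
#' @param image a [gray_image] with at least two distinct gray levels.
#' @param config a [segmentation_config].
#' @return a [binary_mask]; attribute `threshold` records the induced cut
#'   (foreground is `<= threshold` for dark polarity, `> threshold`
#'   otherwise).
#' @export
adaptive_kmeans_binarize <- function(image, config = segmentation_config()) {
  stopifnot(is_gray_image(image), inherits(config, "segmentation_config"))
  h <- image_histogram(image)
  levels_present <- which(h > 0) - 1L
  if (length(levels_present) < 2L)
    stop("segmentation error: single gray level, cannot form 2 classes")

  thr <- kmeans2_histogram_threshold(h, config$max_iter, config$tol)
  fg <- if (config$polarity == "dark") image$pixels <= thr else image$pixels > thr
  m <- binary_mask(fg, spacing = image$spacing, provenance = image$provenance)
  attr(m, "threshold") <- thr
  m
}

# 1-D 2-means on a 256-bin histogram; returns the cut threshold (a boundary
# value: levels <= thr belong to the lower centroid).
kmeans2_histogram_threshold <- function(h, max_iter = 100L, tol = 0.5) {
  lv <- 0:255
  cdf <- cumsum(h) / sum(h)
  q <- function(p) lv[which(cdf >= p)[1]]
  c1 <- as.numeric(q(0.10)); c2 <- as.numeric(q(0.90))
  if (c1 == c2) { # degenerate percentiles; fall back to extreme occupied levels
    occ <- lv[h > 0]
    c1 <- min(occ); c2 <- max(occ)
  }
  for (i in seq_len(max_iter)) {
    cut <- (c1 + c2) / 2
    lower <- lv <= cut
    w1 <- sum(h[lower]); w2 <- sum(h[!lower])
    n1 <- if (w1 > 0) sum(h[lower] * lv[lower]) / w1 else c1
    n2 <- if (w2 > 0) sum(h[!lower] * lv[!lower]) / w2 else c2
    moved <- max(abs(n1 - c1), abs(n2 - c2))
    c1 <- n1; c2 <- n2
    if (moved < tol) break
  }
  (c1 + c2) / 2
}

#' Morphological cleanup of a binary segmentation
#'
#' Closing with a disk of `closing_radius`, removal of foreground components
#' (8-connected) smaller than `min_area`, then filling of background holes
#' (4-connected, not touching the image edge) smaller than `min_area`.
#' Idempotent. Every surviving foreground component has area `>= min_area`.
#'
#' @param mask a [binary_mask].
#' @param config a [segmentation_config].
#' @return the cleaned [binary_mask].
#' @export
morphological_clean <- function(mask, config = segmentation_config()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(config, "segmentation_config"))
  px <- mask$pixels
  if (config$closing_radius > 0L) px <- binary_close(px, config$closing_radius)
  if (config$min_area > 0L) {
    lab <- cpp_label_components(px, 8L)
    area <- tabulate(lab[lab > 0L])
    keepm <- lab > 0L
    keepm[keepm] <- area[lab[keepm]] >= config$min_area
    px <- keepm
    # fill small interior holes
    bg <- cpp_label_components(!px, 4L)
    edge_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    barea <- tabulate(bg[bg > 0L])
    hole <- bg > 0L & !(bg %in% edge_labels) &
      array(barea[pmax(bg, 1L)] < config$min_area, dim = dim(bg))
    px[hole] <- TRUE
  }
  if (!any(px))
    stop("segmentation error: no iris component survives cleaning")
  out <- binary_mask(px, spacing = mask$spacing, provenance = mask$provenance)
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}

# digital disc structuring element (d^2 <= r^2 + 1, the slightly dilated
# rasterization, so closing with radius 2 re-bridges 1-px gaps in thin
# borders)
disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2 + 1, , drop = FALSE]
}

# shift a logical matrix, padding with `fill`
shift_logical <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

binary_dilate <- function(m, r) {
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_logical(m, off$dr[i], off$dc[i], FALSE)
  out
}

binary_erode <- function(m, r, pad = TRUE) {
  off <- disk_offsets(r)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_logical(m, off$dr[i], off$dc[i], pad)
  out
}

# closing: dilate then erode; erosion pads with TRUE so the image frame does
# not clip structures touching the edge
binary_close <- function(m, r) binary_erode(binary_dilate(m, r), r, pad = TRUE)

#' Extract the outer boundary of the segmented iris
#'
#' Keeps the `keep` largest 8-connected foreground components (ties broken by
#' the topmost-then-leftmost first pixel) and marks every retained pixel that
#' has at least one 4-neighbour in the background (pixels on the image edge
#' count as touching background). A horizontal B-scan through the pupil shows
#' the nasal and temporal iris as two separate regions, so [measure_si()]
#' uses `keep = 2`.
#'
#' @param mask a cleaned [binary_mask] with at least one foreground pixel.
#' @param keep number of largest components to retain (default 1).
#' @return a [binary_mask] of border pixels (class also `border_mask`).
#' @export
extract_border <- function(mask, keep = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (!any(px)) stop("mask has no foreground component")
  lab <- cpp_label_components(px, 8L)
  area <- tabulate(lab[lab > 0L])
  ord <- order(area, decreasing = TRUE)  # stable: ties keep label order,
  # and labels are assigned in topmost-then-leftmost scan order
  keep_labels <- ord[seq_len(min(keep, length(ord)))]
  sel <- array(lab %in% keep_labels, dim = dim(px))
  # outer boundary: foreground with a 4-neighbour in background
  bg <- !sel
  nbg <- shift_logical(bg, 1, 0, TRUE) | shift_logical(bg, -1, 0, TRUE) |
         shift_logical(bg, 0, 1, TRUE) | shift_logical(bg, 0, -1, TRUE)
  border <- sel & nbg
  out <- binary_mask(border, spacing = mask$spacing, provenance = mask$provenance)
  class(out) <- c("border_mask", class(out))
  out
}
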