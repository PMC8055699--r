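#' Read an image file as an 8-bit grayscale image
#'
#' Supports PNG, JPEG and (plain or binary) PGM. Colour images are converted
#' to luminance with ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B);
#' intensities are rescaled linearly to `[0, 255]`. Sixteen-bit sources are
#' rescaled the same way.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, or `.pgm` file.
#' @param spacing physical pixel spacing `(sy, sx)`, default `c(1, 1)`.
#' @return a [gray_image].
#' @export
read_image <- function(path, spacing = c(1, 1)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    pgm = return(read_pgm(path, spacing)),
    stop("unsupported image format: .", ext,
         " (supported: png, jpg/jpeg, pgm)")
  )
  px <- as_gray_matrix(arr)
  gray_image(px, spacing = spacing, provenance = path)
}

# Collapse a readPNG/readJPEG array (values in [0,1]) to an 8-bit gray matrix.
as_gray_matrix <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      g <- arr[, , 1]
    }
  } else {
    g <- arr
  }
  round(pmin(pmax(g, 0), 1) * 255)
}

#' Write a grayscale image or mask to disk
#'
#' `gray_image` objects are written with intensities mapped to `[0, 1]`;
#' `binary_mask` objects are written as 0/255. Format follows the file
#' extension (`.png` or `.pgm`).
#'
#' @param x a [gray_image] or [binary_mask].
#' @param path output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  px <- if (inherits(x, "binary_mask")) x$pixels * 255 else x$pixels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / 255, path)
  } else if (ext == "pgm") {
    write_pgm(px, path)
  } else {
    stop("unsupported output format: .", ext, " (supported: png, pgm)")
  }
  invisible(path)
}

# Plain-text (P2) and binary (P5) PGM support; 8-bit only for P5.
read_pgm <- function(path, spacing = c(1, 1)) {
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  if (magic == "P2") {
    txt <- strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]]
    txt <- sub("#.*$", "", txt)
    toks <- as.integer(unlist(strsplit(paste(txt[-1], collapse = " "),
                                       "[[:space:]]+")))
    toks <- toks[!is.na(toks)]
    w <- toks[1]; h <- toks[2]; maxv <- toks[3]
    vals <- toks[4:(3 + w * h)]
  } else {
    # parse header tokens byte-wise, then the pixel block follows the single
    # whitespace byte after maxval
    pos <- 3L
    toks <- integer(0)
    buf <- ""
    in_comment <- FALSE
    while (length(toks) < 3L) {
      ch <- rawToChar(raw[pos]); pos <- pos + 1L
      if (in_comment) {
        if (ch == "\n") in_comment <- FALSE
      } else if (ch == "#") {
        in_comment <- TRUE
      } else if (grepl("[[:space:]]", ch)) {
        if (nzchar(buf)) { toks <- c(toks, as.integer(buf)); buf <- "" }
      } else buf <- paste0(buf, ch)
    }
    w <- toks[1]; h <- toks[2]; maxv <- toks[3]
    if (maxv > 255) stop("16-bit binary PGM not supported")
    vals <- as.integer(raw[pos:(pos + w * h - 1L)])
  }
  px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxv != 255) px <- round(px * (255 / maxv))
  gray_image(px, spacing = spacing, provenance = path)
}

write_pgm <- function(px, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
  apply(round(px), 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
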