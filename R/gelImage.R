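#' Load a TRF gel scan from a TIFF file
#'
#' Reads an 8- or 16-bit grayscale or RGB TIFF scan into a [GelImage]. RGB
#' input is reduced to a single channel with the fixed Rec. 601 luminance
#' weighting 0.299 R + 0.587 G + 0.114 B, so channel-equal images map to
#' the common channel value exactly. Values are kept as raw detector counts;
#' no rescaling or display transform is applied.
#'
#' @param path path to a single-page TIFF file with 8- or 16-bit samples and
#'   1 or 3 channels.
#' @return a [GelImage].
#' @examples
#' gel <- generateSyntheticGel(syntheticGelSpec(), seed = 1)
#' tf <- tempfile(fileext = ".tif")
#' writeGelImage(gel$image, tf)
#' img <- loadGelImage(tf)
#' @seealso [writeGelImage()], [rotateGel()], [invertGel()], [cropGel()]
#' @export
loadGelImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) stop("cannot read TIFF: ", conditionMessage(e)))
  bits <- attr(arr, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(arr) > 255) 16L else 8L
  if (!(bits %in% c(8L, 16L))) {
    stop("unsupported bit depth: ", bits, " (8- or 16-bit TIFF required)")
  }
  if (is.double(arr)) {
    # multi-channel images come back rescaled to [0, 1]; restore raw counts
    arr <- arr * (2^bits - 1)
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 3) {
      stop("unsupported channel count: ", dim(arr)[3], " (1 or 3 required)")
    }
    w <- c(0.299, 0.587, 0.114)   # Rec. 601 luma; sums to exactly 1
    raw <- arr[, , 1] * w[1] + arr[, , 2] * w[2] + arr[, , 3] * w[3]
  } else if (length(dim(arr)) == 2) {
    raw <- arr
  } else {
    stop("unsupported TIFF layout")
  }
  raw <- matrix(as.numeric(raw), nrow = nrow(raw))
  new("GelImage", raw = raw, bitDepth = as.integer(bits))
}

#' Write a gel image to a TIFF file
#'
#' Writes the raw counts of a [GelImage] to a single-page grayscale TIFF at
#' the image's bit depth. Integer-valued counts round-trip exactly through
#' [loadGelImage()].
#'
#' @param image a [GelImage].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGelImage <- function(image, path) {
  stopifnot(is(image, "GelImage"))
  vmax <- 2^image@bitDepth - 1
  tiff::writeTIFF(image@raw / vmax, path, bits.per.sample = image@bitDepth,
                  compression = "none")
  invisible(path)
}

newGelLike <- function(image, raw, inverted = image@inverted,
                       cropWindow = image@cropWindow) {
  new("GelImage", raw = raw, bitDepth = image@bitDepth,
      inverted = inverted, cropWindow = cropWindow)
}

#' Right-angle rotation of a gel image
#'
#' Rotates the raw array by 90, 180 or 270 degrees clockwise. Only
#' right-angle rotations are offered: they permute pixels without
#' interpolation, so the raw-data guarantee is preserved.
#'
#' @param image a [GelImage].
#' @param degrees 90, 180 or 270 (clockwise).
#' @return the rotated [GelImage].
#' @export
rotateGel <- function(image, degrees) {
  stopifnot(is(image, "GelImage"))
  if (!degrees %in% c(90, 180, 270)) stop("degrees must be 90, 180 or 270")
  m <- image@raw
  r <- switch(as.character(degrees),
    "90"  = t(m[nrow(m):1, , drop = FALSE]),
    "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
    "270" = t(m)[ncol(m):1, , drop = FALSE]
  )
  newGelLike(image, r)
}

#' Invert gel signal polarity
#'
#' Maps every count v to `(2^bitDepth - 1) - v` and toggles the `inverted`
#' flag. All downstream analysis assumes signal = high counts, so scans with
#' dark bands on a light background must be inverted once before analysis.
#'
#' @param image a [GelImage].
#' @return the inverted [GelImage].
#' @export
invertGel <- function(image) {
  stopifnot(is(image, "GelImage"))
  vmax <- 2^image@bitDepth - 1
  newGelLike(image, vmax - image@raw, inverted = !image@inverted)
}

#' Crop a gel image
#'
#' Extracts the half-open rectangle `[r0, r1) x [c0, c1)` (0-based pixel
#' coordinates), yielding an image of `r1 - r0` rows and `c1 - c0` columns.
#'
#' @param image a [GelImage].
#' @param r0,c0 top-left corner (0-based, inclusive).
#' @param r1,c1 bottom-right corner (exclusive).
#' @return the cropped [GelImage]; `cropWindow` records the rectangle.
#' @export
cropGel <- function(image, r0, c0, r1, c1) {
  stopifnot(is(image, "GelImage"))
  h <- nrow(image@raw); w <- ncol(image@raw)
  if (r0 < 0 || c0 < 0 || r1 > h || c1 > w || r0 >= r1 || c0 >= c1) {
    stop(sprintf("crop rectangle (%d,%d,%d,%d) outside image bounds %dx%d",
                 r0, c0, r1, c1, h, w))
  }
  newGelLike(image, image@raw[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE],
             cropWindow = c(r0, c0, r1, c1))
}
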