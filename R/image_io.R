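#' Read a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale PNG/TIFF into the canonical
#' \linkS4class{GrayImage} representation: intensities on the integer code
#' scale [0, L] with L = 2^bitdepth - 1 carried as metadata. Multi-channel
#' (RGB) inputs are converted to luminance (Rec. 601 weights) when
#' `forceGray = TRUE` and rejected otherwise; an alpha channel is dropped.
#'
#' @param path path to a .png/.tif/.tiff file.
#' @param forceGray convert RGB input to luminance instead of failing.
#' @return A \linkS4class{GrayImage}.
#' @seealso [writeGrayImage()]
#' @export
readGrayImage <- function(path, forceGray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    bits <- attr(raw, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)")
  }
  raw <- array(as.numeric(raw), dim(raw))   # drop reader metadata attributes
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      if (!forceGray)
        stop("multi-channel image; pass forceGray = TRUE to convert to luminance")
      raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw <- raw[, , 1]   # gray + alpha: keep the gray plane
    }
  }
  L <- 2^bits - 1
  GrayImage(raw * L, grayRange = L, origin = path)
}

#' Write a GrayImage to PNG or TIFF
#'
#' Intensities are clipped to [0, L], linearly mapped to the output code
#' range [0, 2^bitDepth - 1], rounded half-away-from-zero and written
#' losslessly. PNG output is 8-bit only; request TIFF for 16-bit.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param path output path (.png/.tif/.tiff).
#' @param bitDepth 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path, bitDepth = 8L) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 16L)) stop("'bitDepth' must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  maxCode <- 2^bitDepth - 1
  p <- pmin(pmax(img@pixels, 0), img@grayRange)
  codes <- round_half_away(p / img@grayRange * maxCode)
  frac <- codes / maxCode
  if (ext == "png") {
    if (bitDepth == 16L)
      stop("16-bit output requires TIFF (PNG writing is 8-bit only)")
    png::writePNG(frac, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(frac, path, bits.per.sample = bitDepth, compression = "none")
  } else {
    stop("unsupported output format '.", ext, "' (PNG and TIFF are supported)")
  }
  invisible(path)
}

#' Linearly rescale an image to a new gray range
#'
#' Maps the old range [0, L] onto [0, newL] and updates the stored gray
#' range; pixel values scale by newL / L.
#'
#' @param img a \linkS4class{GrayImage}.
#' @param newL new gray range, > 0.
#' @return A rescaled \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(c(0, 51, 204, 255), 2, 2))
#' pixels(normalizeImage(img, 1))
#' @export
normalizeImage <- function(img, newL) {
  stopifnot(is(img, "GrayImage"))
  if (length(newL) != 1L || !is.finite(newL) || newL <= 0)
    stop("'newL' must be a single positive number")
  GrayImage(img@pixels * (newL / img@grayRange), grayRange = newL,
            origin = img@origin)
}
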