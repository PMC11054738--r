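#' Construct an RGBImage from a pixel array
#'
#' @param pixels numeric array `c(H, W, 3)` with values in `[0, 255]`,
#'   or in `[0, 1]` (detected and rescaled when the maximum is <= 1).
#' @param source optional source path recorded in the object.
#' @param tag optional capture tag.
#' @return An [RGBImage-class].
#' @export
RGBImage <- function(pixels, source = "", tag = "") {
  pixels <- unname(pixels)
  if (length(dim(pixels)) == 3L && max(pixels) <= 1 && min(pixels) >= 0)
    pixels <- round(pixels * 255)
  new("RGBImage", pixels = pixels, source = source, tag = tag)
}

#' Read a PNG or JPEG image as an RGBImage
#'
#' PNG is read with the \pkg{png} package; JPEG with \pkg{jpeg} when that
#' package is installed. Alpha channels are dropped, grayscale rasters
#' replicated to three channels, and values rescaled to 0--255.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`
#'   (case-insensitive).
#' @param tag optional capture tag stored in the object.
#' @return An [RGBImage-class].
#' @export
readRGBImage <- function(path, tag = "") {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '", ext, "' (PNG or JPEG expected)"))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  RGBImage(round(raw * 255), source = path, tag = tag)
}

#' Write an RGBImage to a PNG file
#'
#' @param image an [RGBImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRGBImage <- function(image, path) {
  stopifnot(is(image, "RGBImage"))
  png::writePNG(pixels(image) / 255, target = path)
  invisible(path)
}
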