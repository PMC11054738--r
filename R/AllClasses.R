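#' @import methods
NULL

#' RGBImage: an 8-bit color raster
#'
#' Container for a height x width x 3 pixel raster with channel values on
#' the 0--255 scale, as delivered by an ordinary color camera. The raster
#' is stored as a numeric array; after white balancing values remain on
#' the same scale, rounded back to whole counts.
#'
#' @slot pixels numeric array, dim `c(H, W, 3)`, all values in `[0, 255]`.
#' @slot source character, path the image was read from (may be `""`).
#' @slot tag character, free-form capture tag.
#'
#' @seealso [readRGBImage()], [whiteBalance()], [toHSV()]
#' @export
setClass("RGBImage",
  representation(pixels = "array", source = "character", tag = "character"),
  prototype(source = "", tag = ""))

setValidity("RGBImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("'pixels' must be an H x W x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    return("image must be at least 16 x 16 pixels")
  if (anyNA(object@pixels) || min(object@pixels) < 0 || max(object@pixels) > 255)
    return("channel values must lie in [0, 255]")
  TRUE
})

#' ROIMask: a region-of-interest mask
#'
#' Logical raster marking the pixels retained for analysis (the fruit
#' surface), together with its pixel count.
#'
#' @slot mask logical matrix with the same H, W as the source image.
#' @slot pixelCount integer, number of `TRUE` cells.
#'
#' @seealso [segmentROI()]
#' @export
setClass("ROIMask",
  representation(mask = "matrix", pixelCount = "integer"))

setValidity("ROIMask", function(object) {
  if (!is.logical(object@mask)) return("'mask' must be a logical matrix")
  if (object@pixelCount != sum(object@mask))
    return("'pixelCount' must equal the number of TRUE cells")
  TRUE
})

#' HueSpectrum: saturation mass per hue degree
#'
#' A circular 360-bin vector in which bin `b` (covering hue degrees
#' `[b, b+1)`, `b = 0..359`) holds the summed -- or, for the
#' `"per_pixel"` normalization, the mean -- saturation (in percent) of
#' the ROI pixels whose hue falls in that bin. Colors are thereby
#' weighted by their vividness rather than merely counted, so gray
#' background and specular reflections contribute nothing.
#'
#' @slot values numeric length-360 vector, all values `>= 0`.
#' @slot normalization character, `"raw_sum"` or `"per_pixel"`.
#' @slot roiPixels integer, number of ROI pixels the spectrum summarizes.
#'
#' @seealso [hueSpectrum()], [gravityPoint()]
#' @export
setClass("HueSpectrum",
  representation(values = "numeric", normalization = "character",
                 roiPixels = "integer"))

setValidity("HueSpectrum", function(object) {
  if (length(object@values) != 360L)
    return("'values' must have length 360 (1-degree bins)")
  if (anyNA(object@values) || min(object@values) < 0)
    return("spectrum values must be finite and non-negative")
  if (!object@normalization %in% c("raw_sum", "per_pixel"))
    return("'normalization' must be 'raw_sum' or 'per_pixel'")
  if (object@roiPixels < 0L) return("'roiPixels' must be non-negative")
  if (object@normalization == "raw_sum" &&
      sum(object@values) > object@roiPixels * 100 + 1e-6)
    return("raw_sum spectrum mass cannot exceed roiPixels * 100")
  TRUE
})

#' ColorSummary: mean and normalized RGB over a ROI
#'
#' Mean channel intensities over the ROI on the 0--255 scale and the
#' intensity-free fractions R/(R+G+B), G/(R+G+B), B/(R+G+B), which sum
#' to one by construction.
#'
#' @slot meanRGB named numeric length 3 (`R`, `G`, `B`), 0--255 scale.
#' @slot normalizedRGB named numeric length 3 (`R_N`, `G_N`, `B_N`),
#'   fractions in `[0, 1]` summing to 1.
#'
#' @seealso [colorSummary()]
#' @export
setClass("ColorSummary",
  representation(meanRGB = "numeric", normalizedRGB = "numeric"))

setValidity("ColorSummary", function(object) {
  if (length(object@meanRGB) != 3L || length(object@normalizedRGB) != 3L)
    return("'meanRGB' and 'normalizedRGB' must have length 3")
  nv <- object@normalizedRGB
  if (abs(sum(nv) - 1) > 1e-12)
    return("normalized fractions must sum to 1 (within 1e-12)")
  if (min(nv) < 0 || max(nv) > 1)
    return("normalized fractions must lie in [0, 1]")
  TRUE
})

#' PQSPoint: the gravity point of a polar hue spectrum
#'
#' The area centroid of the region enclosed by the spectrum drawn as a
#' polar curve r(theta). Carries the same (dimensionless) scale as the
#' spectrum values it was computed from. A fully circular-symmetric
#' spectrum maps to the origin.
#'
#' @slot x numeric, finite.
#' @slot y numeric, finite.
#'
#' @seealso [gravityPoint()], [gravityPointMC()]
#' @export
setClass("PQSPoint", representation(x = "numeric", y = "numeric"))

setValidity("PQSPoint", function(object) {
  if (length(object@x) != 1L || length(object@y) != 1L ||
      !is.finite(object@x) || !is.finite(object@y))
    return("'x' and 'y' must be finite scalars")
  TRUE
})
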