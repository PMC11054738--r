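#' Accessors for huePQS S4 classes
#'
#' Small read-only accessors: `pixels()` returns the raster array of an
#' [RGBImage-class]; `maskMatrix()` and `pixelCount()` the raster and size
#' of a [ROIMask-class]; `spectrumValues()`, `spectrumNormalization()` and
#' `roiPixels()` the contents of a [HueSpectrum-class]; `meanRGB()` and
#' `normalizedRGB()` the two parts of a [ColorSummary-class]; `pqsX()` and
#' `pqsY()` the coordinates of a [PQSPoint-class].
#'
#' @param object an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "RGBImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ROIMask", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("pixelCount", function(object) standardGeneric("pixelCount"))
#' @rdname accessors
#' @export
setMethod("pixelCount", "ROIMask", function(object) object@pixelCount)

#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(object) standardGeneric("spectrumValues"))
#' @rdname accessors
#' @export
setMethod("spectrumValues", "HueSpectrum", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("spectrumNormalization",
           function(object) standardGeneric("spectrumNormalization"))
#' @rdname accessors
#' @export
setMethod("spectrumNormalization", "HueSpectrum",
          function(object) object@normalization)

#' @rdname accessors
#' @export
setGeneric("roiPixels", function(object) standardGeneric("roiPixels"))
#' @rdname accessors
#' @export
setMethod("roiPixels", "HueSpectrum", function(object) object@roiPixels)

#' @rdname accessors
#' @export
setGeneric("meanRGB", function(object) standardGeneric("meanRGB"))
#' @rdname accessors
#' @export
setMethod("meanRGB", "ColorSummary", function(object) object@meanRGB)

#' @rdname accessors
#' @export
setGeneric("normalizedRGB", function(object) standardGeneric("normalizedRGB"))
#' @rdname accessors
#' @export
setMethod("normalizedRGB", "ColorSummary", function(object) object@normalizedRGB)

#' @rdname accessors
#' @export
setGeneric("pqsX", function(object) standardGeneric("pqsX"))
#' @rdname accessors
#' @export
setMethod("pqsX", "PQSPoint", function(object) object@x)

#' @rdname accessors
#' @export
setGeneric("pqsY", function(object) standardGeneric("pqsY"))
#' @rdname accessors
#' @export
setMethod("pqsY", "PQSPoint", function(object) object@y)

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage: %d x %d pixels, 3 x 8-bit channels\n", d[1], d[2]))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
  if (nzchar(object@tag)) cat("  tag:   ", object@tag, "\n")
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("ROIMask: %d x %d, %d pixels in ROI (%.1f%%)\n",
              d[1], d[2], object@pixelCount,
              100 * object@pixelCount / length(object@mask)))
})

setMethod("show", "HueSpectrum", function(object) {
  v <- object@values
  cat(sprintf(
    "HueSpectrum: 360 x 1-degree bins (%s), %d ROI pixels\n",
    object@normalization, object@roiPixels))
  if (any(v > 0))
    cat(sprintf("  total mass %.4g, peak %.4g at %d degrees\n",
                sum(v), max(v), which.max(v) - 1L))
})

setMethod("show", "ColorSummary", function(object) {
  cat(sprintf("ColorSummary: mean RGB (%.1f, %.1f, %.1f)\n",
              object@meanRGB[1], object@meanRGB[2], object@meanRGB[3]))
  cat(sprintf("  normalized  (%.4f, %.4f, %.4f)\n",
              object@normalizedRGB[1], object@normalizedRGB[2],
              object@normalizedRGB[3]))
})

setMethod("show", "PQSPoint", function(object) {
  cat(sprintf("PQSPoint: (X = %.6g, Y = %.6g)\n", object@x, object@y))
})
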