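#' White-balance an image against its white background
#'
#' Produce photographed on a white background carries the background as a
#' built-in color reference: any illumination cast shifts the background
#' channel medians away from neutral. `whiteBalance` estimates one gain
#' per channel so that the white-region medians all equal a common
#' reference level, applies the gains to the whole frame, and clips back
#' to the 8-bit range. With `whiteRegion = NULL` the white region is
#' derived automatically as the low-saturation, high-value pixels.
#'
#' @param image an [RGBImage-class].
#' @param whiteRegion an [ROIMask-class] marking known-white pixels, or
#'   `NULL` for automatic detection (saturation <= 10%, value >= 60%).
#' @param referenceLevel target median for each channel in the white
#'   region (default 240, safely below the 255 ceiling to limit clipping).
#' @param minPixels minimum number of white pixels required (default 100).
#' @return A white-balanced [RGBImage-class] on the same 0--255 scale.
#' @examples
#' img <- renderTomatoImage(110, 55, seed = 1,
#'                          background = c(230, 235, 225))
#' wb <- whiteBalance(img$image)
#' @export
whiteBalance <- function(image, whiteRegion = NULL, referenceLevel = 240,
                         minPixels = 100) {
  stopifnot(is(image, "RGBImage"))
  px <- pixels(image)
  if (is.null(whiteRegion)) {
    hsv <- toHSV(image)
    m <- hsv$saturation <= 10 & hsv$value >= 60
    whiteRegion <- new("ROIMask", mask = m, pixelCount = as.integer(sum(m)))
  }
  stopifnot(is(whiteRegion, "ROIMask"))
  m <- maskMatrix(whiteRegion)
  if (sum(m) < minPixels)
    stop("degenerate white region: only ", sum(m), " pixels (need >= ",
         minPixels, ")")
  med <- vapply(1:3, function(ch) stats::median(px[, , ch][m]), 0)
  names(med) <- c("R", "G", "B")
  if (any(med == 0))
    stop("degenerate white region: zero median in channel ",
         paste(names(med)[med == 0], collapse = ", "))
  gains <- referenceLevel / med
  out <- px
  for (ch in 1:3) out[, , ch] <- px[, , ch] * gains[ch]
  out[] <- round(pmin(255, pmax(0, out)))
  new("RGBImage", pixels = out, source = image@source,
      tag = image@tag)
}

#' Convert an RGBImage to hue, saturation and value rasters
#'
#' Standard hexcone RGB to HSV conversion. Hue is returned in degrees on
#' `[0, 360)`, saturation and value in percent on `[0, 100]`. Achromatic
#' pixels (max = min) get hue 0 and saturation 0; as they can never pass
#' a positive saturation threshold, this assignment is inert downstream.
#'
#' @param image an [RGBImage-class].
#' @return A list with matrices `hue`, `saturation`, `value`.
#' @export
toHSV <- function(image) {
  stopifnot(is(image, "RGBImage"))
  px <- pixels(image)
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- matrix(hsv[1, ] * 360, d[1], d[2])
  hue[hue >= 360] <- 0
  list(hue = hue,
       saturation = matrix(hsv[2, ] * 100, d[1], d[2]),
       value = matrix(hsv[3, ] * 100, d[1], d[2]))
}

#' Saturation threshold from the histogram (Otsu's criterion)
#'
#' Computes a global threshold separating the dull (background, glare)
#' and vivid (fruit) pixels from the saturation histogram, using Otsu's
#' criterion: the threshold maximizing the between-class variance of the
#' two classes, equivalently minimizing the pooled intra-class variance.
#' Saturation is binned at whole percent (101 bins, 0--100); when several
#' thresholds tie, their mean is returned.
#'
#' @param saturation saturation raster (matrix or vector), percent scale.
#' @return Threshold in `(0, 100)`; pixels with saturation strictly above
#'   it form the region of interest.
#' @seealso [segmentROI()]
#' @export
otsuThreshold <- function(saturation) {
  s <- as.vector(saturation)
  if (length(s) == 0L) stop("empty saturation raster")
  bin <- pmin(100L, pmax(0L, as.integer(floor(s))))
  if (min(bin) == max(bin))
    stop("constant saturation raster: Otsu threshold undefined, ",
         "use a fixed threshold instead")
  counts <- tabulate(bin + 1L, nbins = 101L)
  lev <- 0:100
  n <- sum(counts)
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * lev)
  mu <- m1[101]
  # between-class variance for threshold t = lev (class 1: <= t)
  t <- 1:100
  w <- w1[t]
  valid <- w > 0 & w < n
  bcv <- rep(-Inf, 100)
  bcv[valid] <- (mu * w[valid] / n - m1[t][valid])^2 /
    (w[valid] / n * (1 - w[valid] / n))
  best <- which(bcv >= max(bcv) - 1e-9 * abs(max(bcv)))
  mean(lev[best])
}

#' Segment the region of interest by saturation thresholding
#'
#' Marks as ROI every pixel whose saturation strictly exceeds the
#' threshold. The gray-scaled, low-saturation background and specular
#' reflections are excluded by construction.
#'
#' @param saturation saturation raster (matrix), percent scale.
#' @param threshold threshold in `(0, 100)`, typically from
#'   [otsuThreshold()].
#' @return An [ROIMask-class].
#' @export
segmentROI <- function(saturation, threshold) {
  stopifnot(is.matrix(saturation), threshold > 0, threshold < 100)
  m <- saturation > threshold
  if (!any(m)) stop("no fruit found: empty ROI at threshold ", threshold)
  new("ROIMask", mask = m, pixelCount = as.integer(sum(m)))
}

## Sum saturation per 1-degree hue bin; used by hueSpectrum and the
## synthetic generator's pixel-cloud sampler.
binSaturation <- function(hue, saturation) {
  bin <- (as.integer(floor(hue)) %% 360L) + 1L
  out <- numeric(360)
  agg <- rowsum(as.numeric(saturation), bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Compute the saturation-weighted hue spectrum of a ROI
#'
#' Each ROI pixel contributes its saturation (percent) to the 1-degree
#' bin holding its hue, so the spectrum is a vividness-weighted circular
#' color distribution, not a plain histogram. `"raw_sum"` keeps the raw
#' bin masses (their total equals the total ROI saturation exactly);
#' `"per_pixel"` divides by the ROI pixel count so frames with different
#' fruit sizes are comparable, which is the scaling used for PQS
#' compression.
#'
#' @param hue hue raster, degrees `[0, 360)`.
#' @param saturation saturation raster, percent.
#' @param mask an [ROIMask-class]; must be nonempty.
#' @param normalization `"per_pixel"` (default) or `"raw_sum"`.
#' @return A [HueSpectrum-class].
#' @export
hueSpectrum <- function(hue, saturation, mask,
                        normalization = c("per_pixel", "raw_sum")) {
  normalization <- match.arg(normalization)
  stopifnot(is(mask, "ROIMask"))
  m <- maskMatrix(mask)
  npx <- pixelCount(mask)
  if (npx == 0L) stop("empty ROI: hue spectrum undefined")
  vals <- binSaturation(hue[m], saturation[m])
  if (normalization == "per_pixel") vals <- vals / npx
  new("HueSpectrum", values = vals, normalization = normalization,
      roiPixels = npx)
}

#' Write / read a hue spectrum as CSV
#'
#' Two columns: `bin_deg` (0--359, the lower edge of each 1-degree bin)
#' and `value`.
#'
#' @param spectrum a [HueSpectrum-class].
#' @param path CSV path.
#' @return `writeHueSpectrum`: `path` invisibly. `readHueSpectrum`: a
#'   [HueSpectrum-class] (ROI pixel count is not stored in the CSV and is
#'   set to 0 for `per_pixel` spectra).
#' @export
writeHueSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "HueSpectrum"))
  df <- data.frame(bin_deg = 0:359,
                   value = sprintf("%.17g", spectrumValues(spectrum)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHueSpectrum
#' @param normalization normalization tag to record when reading.
#' @param roiPixels ROI pixel count to record when reading.
#' @export
readHueSpectrum <- function(path, normalization = "per_pixel",
                            roiPixels = 0L) {
  df <- utils::read.csv(path)
  stopifnot(all(c("bin_deg", "value") %in% names(df)))
  vals <- numeric(360)
  vals[df$bin_deg + 1L] <- as.numeric(df$value)
  new("HueSpectrum", values = vals, normalization = normalization,
      roiPixels = as.integer(roiPixels))
}

#' Mean and normalized RGB over a ROI
#'
#' Channel means over the ROI followed by intensity normalization
#' `R_N = R/(R+G+B)` (and similarly for G, B). Normalization removes
#' intensity differences, so the fractions reflect color only.
#'
#' @param image an [RGBImage-class].
#' @param mask an [ROIMask-class]; must be nonempty.
#' @return A [ColorSummary-class].
#' @export
colorSummary <- function(image, mask) {
  stopifnot(is(image, "RGBImage"), is(mask, "ROIMask"))
  if (pixelCount(mask) == 0L) stop("empty ROI: color summary undefined")
  px <- pixels(image)
  m <- maskMatrix(mask)
  means <- vapply(1:3, function(ch) mean(px[, , ch][m]), 0)
  names(means) <- c("R", "G", "B")
  tot <- sum(means)
  if (tot == 0) stop("black ROI: R + G + B = 0, normalization undefined")
  nv <- means / tot
  names(nv) <- c("R_N", "G_N", "B_N")
  new("ColorSummary", meanRGB = means, normalizedRGB = nv)
}
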