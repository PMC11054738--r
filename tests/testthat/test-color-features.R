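test_that("white balance is the identity when the white region already sits at the reference", {
  img <- uniformImage(240, 240, 240)
  out <- whiteBalance(img, maskAll(img))
  expect_identical(pixels(out), pixels(img))
})

test_that("white balance equalizes channel medians at the reference level", {
  img <- uniformImage(200, 220, 240)
  out <- whiteBalance(img, maskAll(img))
  expect_equal(unique(as.vector(pixels(out))), 240)

  # rendered frame with an illumination cast: background medians must agree
  res <- renderTomatoImage(110, 55, seed = 11, background = c(230, 235, 225))
  wb <- whiteBalance(res$image)   # automatic white region
  bg <- !(res$fruitMask | res$glareMask)
  med <- vapply(1:3, function(ch) median(pixels(wb)[, , ch][bg]), 0)
  expect_lt(max(med) - min(med), 1 + 1e-9)
})

test_that("white balance fails loudly on degenerate white regions", {
  img <- uniformImage(200, 220, 240)
  small <- matrix(FALSE, 16, 16); small[1:3, 1:3] <- TRUE
  expect_error(
    whiteBalance(img, new("ROIMask", mask = small, pixelCount = 9L)),
    "degenerate white region")
  dark <- uniformImage(120, 100, 0)
  expect_error(whiteBalance(dark, maskAll(dark)), "channel B")
})

test_that("HSV conversion follows the hexcone definition", {
  hsv <- toHSV(uniformImage(255, 0, 0))
  expect_equal(unique(as.vector(hsv$hue)), 0)
  expect_equal(unique(as.vector(hsv$saturation)), 100)

  hsv <- toHSV(uniformImage(128, 128, 128))
  expect_equal(unique(as.vector(hsv$saturation)), 0)
  expect_equal(unique(as.vector(hsv$hue)), 0)   # achromatic convention

  hsv <- toHSV(uniformImage(0, 255, 0))
  expect_equal(unique(as.vector(hsv$hue)), 120)
  expect_equal(unique(as.vector(hsv$saturation)), 100)
})

test_that("Otsu threshold separates a bimodal saturation histogram", {
  s <- matrix(c(rep(5, 128), rep(80, 128)), 16, 16)
  thr <- otsuThreshold(s)
  expect_gt(thr, 5); expect_lt(thr, 80)
  expect_error(otsuThreshold(matrix(42, 16, 16)), "constant")
})

test_that("Otsu threshold minimizes intra-class variance (brute-force oracle)", {
  bruteIntraVar <- function(s, t) {
    lo <- s[floor(s) <= t]; hi <- s[floor(s) > t]
    if (!length(lo) || !length(hi)) return(Inf)
    v <- function(x) if (length(x) > 1) var(x) * (length(x) - 1) else 0
    # population-style pooled within-class variance on binned levels
    (v(floor(lo)) + v(floor(hi))) / length(s)
  }
  # equal-parts two-level raster
  s <- c(rep(10, 200), rep(90, 200))
  thr <- otsuThreshold(s)
  objs <- vapply(0:99, function(t) bruteIntraVar(s, t), 0)
  expect_equal(bruteIntraVar(s, floor(thr)), min(objs))
  # random integer-valued rasters
  for (seed in 1:5) {
    set.seed(seed)
    s <- c(round(rnorm(300, 8, 3)), round(rnorm(300, 65, 12)))
    s <- pmin(100, pmax(0, s))
    thr <- otsuThreshold(s)
    objs <- vapply(0:99, function(t) bruteIntraVar(s, t), 0)
    expect_equal(bruteIntraVar(s, floor(thr)), min(objs))
  }
})

test_that("ROI segmentation is exactly the strict-threshold set", {
  set.seed(4)
  s <- matrix(runif(400, 0, 100), 20, 20)
  roi <- segmentROI(s, 37)
  expect_identical(maskMatrix(roi), s > 37)
  expect_identical(pixelCount(roi), sum(s > 37))
  expect_error(segmentROI(matrix(0, 16, 16), 50), "no fruit found")
  full <- segmentROI(matrix(100, 16, 16), 50)
  expect_true(all(maskMatrix(full)))
})

test_that("segmentation excludes rendered glare spots", {
  res <- renderTomatoImage(15, 70, seed = 5, glareFraction = 0.06)
  hsv <- toHSV(res$image)
  roi <- segmentROI(hsv$saturation, otsuThreshold(hsv$saturation))
  expect_false(any(maskMatrix(roi) & res$glareMask))
})

test_that("hue spectrum handles single-color and zero-saturation ROIs", {
  h <- matrix(60.4, 16, 16); s <- matrix(80, 16, 16)
  img <- uniformImage(0, 0, 0)  # only for mask dimensions
  roi <- maskAll(img)
  raw <- hueSpectrum(h, s, roi, "raw_sum")
  expect_equal(sum(spectrumValues(raw) > 0), 1)
  expect_equal(spectrumValues(raw)[61], 80 * 256)   # bin 60
  per <- hueSpectrum(h, s, roi, "per_pixel")
  expect_equal(spectrumValues(per)[61], 80)

  zero <- hueSpectrum(h, matrix(0, 16, 16), roi, "raw_sum")
  expect_true(all(spectrumValues(zero) == 0))
})

test_that("hue spectrum conserves saturation mass and ignores pixel order", {
  set.seed(9)
  h <- matrix(runif(400, 0, 360), 20, 20)
  s <- matrix(runif(400, 0, 100), 20, 20)
  m <- matrix(runif(400) < 0.6, 20, 20)
  roi <- new("ROIMask", mask = m, pixelCount = as.integer(sum(m)))
  raw <- hueSpectrum(h, s, roi, "raw_sum")
  expect_equal(sum(spectrumValues(raw)), sum(s[m]), tolerance = 1e-12)
  per <- hueSpectrum(h, s, roi, "per_pixel")
  expect_equal(spectrumValues(per), spectrumValues(raw) / sum(m))

  # permute the pixel layout (mask permuted identically)
  perm <- sample(400)
  h2 <- matrix(as.vector(h)[perm], 20, 20)
  s2 <- matrix(as.vector(s)[perm], 20, 20)
  m2 <- matrix(as.vector(m)[perm], 20, 20)
  roi2 <- new("ROIMask", mask = m2, pixelCount = as.integer(sum(m2)))
  expect_identical(spectrumValues(hueSpectrum(h2, s2, roi2, "raw_sum")),
                   spectrumValues(raw))
})

test_that("color summary matches hand arithmetic and conserves fractions", {
  cs <- colorSummary(uniformImage(100, 100, 100), maskAll(uniformImage(1, 1, 1)))
  expect_equal(unname(normalizedRGB(cs)), rep(1 / 3, 3))

  cs <- colorSummary(uniformImage(255, 0, 0), maskAll(uniformImage(1, 1, 1)))
  expect_equal(unname(normalizedRGB(cs)), c(1, 0, 0))

  # two-pixel ROI: (200,0,0) and (0,100,0)
  px <- array(0, c(16, 16, 3))
  px[1, 1, ] <- c(200, 0, 0); px[1, 2, ] <- c(0, 100, 0)
  img <- RGBImage(px)
  m <- matrix(FALSE, 16, 16); m[1, 1:2] <- TRUE
  roi <- new("ROIMask", mask = m, pixelCount = 2L)
  cs <- colorSummary(img, roi)
  expect_equal(unname(meanRGB(cs)), c(100, 50, 0))
  expect_equal(unname(normalizedRGB(cs)), c(2 / 3, 1 / 3, 0))

  expect_error(colorSummary(uniformImage(0, 0, 0),
                            maskAll(uniformImage(1, 1, 1))), "black ROI")

  # normalization conserves to machine precision on rendered frames
  for (seed in 1:20) {
    res <- renderTomatoImage(runif(1, 0, 360) %% 360, runif(1, 30, 90),
                             seed = seed)
    hsv <- toHSV(res$image)
    roi <- segmentROI(hsv$saturation, otsuThreshold(hsv$saturation))
    expect_equal(sum(normalizedRGB(colorSummary(res$image, roi))), 1,
                 tolerance = 1e-14)
  }
})
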