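smallConfig <- function(...) {
  simulationConfig(nFruitPerGroup = 2, days = c(0, 7, 14), nPixels = 200, ...)
}

test_that("trajectory generation is deterministic and has the factorial layout", {
  cfg <- smallConfig(seed = 3)
  s1 <- simulateTrajectories(cfg)
  s2 <- simulateTrajectories(cfg)
  expect_identical(s1, s2)
  # 5 groups x 2 arms + F x 1 arm = 11 arms, 2 fruits, 3 days
  expect_equal(nrow(s1$features), 11 * 2 * 3)
  expect_false("SF" %in% s1$features$treatment[s1$features$group == "F"])
  expect_false(any(duplicated(
    s1$features[c("sample_id", "day")])))
})

test_that("noise-free trajectories are monotone and ordered at day 0", {
  cfg <- simulationConfig(nFruitPerGroup = 1, noise = FALSE, nPixels = 50,
                          seed = 8)
  tr <- simulateTrajectories(cfg)$truth
  for (sid in unique(tr$sample_id)) {
    s <- tr[tr$sample_id == sid, ]
    s <- s[order(s$day), ]
    expect_true(all(diff(s$u) >= 0))
    expect_true(all(diff(s$true_a) >= 0))
    expect_true(all(diff(s$true_da) <= 0))
    expect_true(all(diff(s$true_s) <= 1e-12))
  }
  day0 <- tr[tr$day == 0 & tr$treatment == "control", ]
  day0 <- day0[order(day0$group), ]
  expect_true(all(diff(day0$true_a) > 0))   # A < B < C < D < E < F
})

test_that("the DA floor keeps simulated readings non-negative", {
  cfg <- simulationConfig(nFruitPerGroup = 10, seed = 13, nPixels = 50)
  expect_gte(min(simulateTrajectories(cfg)$features$da_index), 0)
})

test_that("a zero treatment effect makes arms statistically indistinguishable", {
  cfg <- simulationConfig(nFruitPerGroup = 40, days = c(0, 14), rho = 0,
                          nPixels = 50, seed = 17)
  f <- simulateTrajectories(cfg)$features
  d14 <- f[f$day == 14 & f$group == "A", ]
  p <- t.test(a_star ~ treatment, d14)$p.value
  expect_gt(p, 0.001)
})

test_that("noise-free group-A day-14 trajectories mirror the treated/control sign split", {
  cfg <- simulationConfig(nFruitPerGroup = 1, noise = FALSE, nPixels = 50)
  tr <- simulateTrajectories(cfg)$truth
  a14 <- tr[tr$group == "A" & tr$day == 14, ]
  expect_gt(a14$true_a[a14$treatment == "control"], 15)
  expect_lt(a14$true_a[a14$treatment == "SF"], 0)
})

test_that("the injected treatment contrast is recovered from simulated data", {
  target <- injectedTreatmentContrast(simulationConfig(), "A", 14)
  est <- vapply(1:10, function(seed) {
    cfg <- simulationConfig(days = c(0, 14), nPixels = 10, seed = seed)
    f <- simulateTrajectories(cfg)$features
    d14 <- f[f$day == 14 & f$group == "A", ]
    mean(d14$a_star[d14$treatment == "control"]) -
      mean(d14$a_star[d14$treatment == "SF"])
  }, 0)
  expect_lt(abs(mean(est) - target) / target, 0.1)
})

test_that("renderer ground-truth tally matches hueSpectrum exactly", {
  for (seed in 1:5) {
    res <- renderTomatoImage(runif(1, 0, 120), runif(1, 40, 90),
                             seed = seed, glareFraction = 0.04,
                             patchHue = 10, patchSat = 85,
                             patchFraction = runif(1))
    hsv <- toHSV(res$image)
    roi <- new("ROIMask", mask = res$fruitMask,
               pixelCount = as.integer(sum(res$fruitMask)))
    hs <- hueSpectrum(hsv$hue, hsv$saturation, roi, "raw_sum")
    expect_identical(spectrumValues(hs), res$tally)
  }
})

test_that("a noise-free single-hue render produces a one-bin spectrum", {
  res <- renderTomatoImage(60.4, 80, seed = 2, hueSD = 0, satSD = 0,
                           valueSD = 0)
  expect_equal(sum(res$tally > 0), 1)
  hsv <- toHSV(res$image)
  roi <- segmentROI(hsv$saturation, otsuThreshold(hsv$saturation))
  hs <- hueSpectrum(hsv$hue, hsv$saturation, roi, "raw_sum")
  expect_equal(which(spectrumValues(hs) > 0), which(res$tally > 0))
})

test_that("ripe renders sit to the red side of green renders in the PQS plane", {
  gpOf <- function(hue) {
    res <- renderTomatoImage(hue, 70, seed = 23)
    hsv <- toHSV(res$image)
    roi <- segmentROI(hsv$saturation, otsuThreshold(hsv$saturation))
    gravityPoint(hueSpectrum(hsv$hue, hsv$saturation, roi))
  }
  expect_gt(pqsX(gpOf(8)), pqsX(gpOf(110)))
})

test_that("background-only frames fail cleanly at segmentation", {
  img <- uniformImage(247, 249, 243, 64, 64)
  hsv <- toHSV(img)
  expect_error(otsuThreshold(hsv$saturation), "constant")
  expect_error(segmentROI(hsv$saturation, 20), "no fruit found")
  expect_error(renderTomatoImage(10, 50, diameterPx = 80,
                                 frameSize = c(64, 64)), "larger than")
})

test_that("simulation config validation rejects out-of-range parameters", {
  expect_error(simulationConfig(rho = 1.2))
  expect_error(simulationConfig(aNoiseSD = -1))
  expect_error(simulationConfig(efficacy = c(A = 1, B = 1, C = 0.6,
                                             D = 0.3, E = 0.2, F = 0.5)))
})
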