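#' Configuration for the synthetic tomato-ripening study
#'
#' Bundles every parameter of the synthetic study generator. The default
#' design mirrors a two-week postharvest storage trial: six maturity
#' groups (A mature green ... F full red) graded on the CTIFL color
#' scale, a control arm and a 1-MCP-treated arm for groups A--E (F, the
#' fully ripe absolute control, is never treated), 20 fruits per group
#' and arm, sampled on days 0, 2, 5, 7, 9, 12 and 14.
#'
#' Each fruit carries a latent ripeness state `u` in `[0, 1]` following
#' a logistic curve with group-specific start and rate
#' `k * (1 - rho * efficacy_g)` under treatment, so 1-MCP slows ripening
#' most where its receptor-blocking action is reported strongest
#' (mature green and breaker fruit). The measured quantities derive from
#' `u`: the colorimeter a* rises linearly from green to red, the
#' chlorophyll-related DA-index decays exponentially toward (never
#' below) zero, acoustic firmness declines exponentially in storage time
#' at a treatment-slowed rate, and the visible surface is a two-patch
#' mixture -- a dull, hue-broad green patch and a vivid, hue-narrow red
#' patch whose surface fraction equals `u`, which is how the CTIFL
#' stages are defined (percent of surface turned red).
#'
#' @param nFruitPerGroup fruits per group and arm (default 20).
#' @param days sampling days (default `c(0, 2, 5, 7, 9, 12, 14)`).
#' @param u0 named initial latent ripeness per group A--F.
#' @param efficacy named treatment efficacy multiplier per group
#'   (fraction of `rho` realized; 0 for F).
#' @param rho fractional slowing of the ripening rate under 1-MCP, in
#'   `[0, 1]` (default 0.9).
#' @param k baseline logistic ripening rate per day (default 0.35).
#' @param u0LogitSD,kJitterSD between-fruit spread of the initial state
#'   (logit scale) and of the rate (log scale).
#' @param aMin,aMax a* at `u = 0` and `u = 1`; `aNoiseSD` measurement SD.
#' @param daAmp,daRate DA-index `daAmp * exp(-daRate * u)`;
#'   `daNoiseBase`, `daNoiseProp` additive and proportional noise SDs
#'   (readings are floored at 0).
#' @param sInit range of the day-0 firmness coefficient (uniform);
#'   `sFloor` asymptotic floor; `sRate` softening rate per day;
#'   `sRho` fractional slowing of softening under treatment;
#'   `sRateJitterSD` between-fruit rate spread (log scale);
#'   `sNoiseSD` measurement SD.
#' @param greenHue,redHue,greenHueSD,redHueSD,greenSat,redSat,
#'   greenSatSD,redSatSD surface patch hue centers (degrees), hue
#'   spreads, saturation means and spreads (percent).
#' @param valueMean,valueSD HSV value (brightness) of fruit pixels,
#'   percent.
#' @param nPixels pixels drawn per fruit and day for the vision features.
#' @param massMean,massSD fruit mass distribution (g).
#' @param firmnessScale instrument scale for [acousticFirmness()].
#' @param a720Base reference-wavelength absorbance used to decompose the
#'   DA-index into the two stored absorbances.
#' @param imageDiameterPx,imageFrameSize,imageGlareFraction,
#'   imageBackground rendering parameters for [simulateStudy()] images.
#' @param seed integer seed; every draw of the generator flows from it.
#' @param noise set `FALSE` to zero all measurement noise and
#'   between-fruit jitter (deterministic trajectories).
#' @return A list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
    nFruitPerGroup = 20,
    days = c(0, 2, 5, 7, 9, 12, 14),
    u0 = c(A = 0.05, B = 0.2, C = 0.4, D = 0.6, E = 0.75, F = 0.995),
    efficacy = c(A = 1, B = 1, C = 0.6, D = 0.3, E = 0.2, F = 0),
    rho = 0.9, k = 0.35,
    u0LogitSD = 0.2, kJitterSD = 0.08,
    aMin = -15, aMax = 26, aNoiseSD = 1.6,
    daAmp = 1.79, daRate = 6.39, daNoiseBase = 0.04, daNoiseProp = 0.12,
    sInit = c(5.2, 7.8), sFloor = 2.0, sRate = 0.223, sRho = 0.8,
    sRateJitterSD = 0.1, sNoiseSD = 0.45,
    greenHue = 105, redHue = 12, greenHueSD = 18, redHueSD = 4,
    greenSat = 25, redSat = 88, greenSatSD = 8, redSatSD = 6,
    valueMean = 78, valueSD = 4, nPixels = 1200,
    massMean = 110, massSD = 6, firmnessScale = 1e-6, a720Base = 0.05,
    imageDiameterPx = 40, imageFrameSize = c(64, 64),
    imageGlareFraction = 0.04, imageBackground = c(247, 249, 243),
    seed = 1, noise = TRUE) {
  if (!isTRUE(noise)) {
    aNoiseSD <- daNoiseBase <- daNoiseProp <- sNoiseSD <- 0
    u0LogitSD <- kJitterSD <- sRateJitterSD <- 0
  }
  cfg <- list(
    nFruitPerGroup = nFruitPerGroup, days = days, u0 = u0,
    efficacy = efficacy, rho = rho, k = k,
    u0LogitSD = u0LogitSD, kJitterSD = kJitterSD,
    aMin = aMin, aMax = aMax, aNoiseSD = aNoiseSD,
    daAmp = daAmp, daRate = daRate, daNoiseBase = daNoiseBase,
    daNoiseProp = daNoiseProp,
    sInit = sInit, sFloor = sFloor, sRate = sRate, sRho = sRho,
    sRateJitterSD = sRateJitterSD, sNoiseSD = sNoiseSD,
    greenHue = greenHue, redHue = redHue,
    greenHueSD = greenHueSD, redHueSD = redHueSD,
    greenSat = greenSat, redSat = redSat,
    greenSatSD = greenSatSD, redSatSD = redSatSD,
    valueMean = valueMean, valueSD = valueSD, nPixels = nPixels,
    massMean = massMean, massSD = massSD, firmnessScale = firmnessScale,
    a720Base = a720Base,
    imageDiameterPx = imageDiameterPx, imageFrameSize = imageFrameSize,
    imageGlareFraction = imageGlareFraction,
    imageBackground = imageBackground,
    seed = seed, noise = isTRUE(noise))
  validateSimulationConfig(cfg)
  structure(cfg, class = "SimulationConfig")
}

validateSimulationConfig <- function(cfg) {
  stopifnot(cfg$rho >= 0, cfg$rho <= 1,
            all(cfg$efficacy >= 0), all(cfg$efficacy <= 1),
            cfg$efficacy[["F"]] == 0,  # the absolute control is never treated
            all(cfg$u0 > 0), all(cfg$u0 < 1),
            cfg$nFruitPerGroup >= 1, length(cfg$days) >= 1,
            cfg$aNoiseSD >= 0, cfg$daNoiseBase >= 0, cfg$daNoiseProp >= 0,
            cfg$sNoiseSD >= 0, cfg$u0LogitSD >= 0, cfg$kJitterSD >= 0,
            cfg$sRateJitterSD >= 0, cfg$nPixels >= 10)
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  arms <- sum(ifelse(names(x$u0) == "F", 1, 2))
  cat("Synthetic tomato-ripening study configuration\n")
  cat(sprintf("  %d groups (%s), %d arms, %d fruits/group/arm, days %s\n",
              length(x$u0), paste(names(x$u0), collapse = ""), arms,
              x$nFruitPerGroup, paste(x$days, collapse = ",")))
  cat(sprintf("  ripening k = %g/day, 1-MCP slowing rho = %g, seed = %d\n",
              x$k, x$rho, x$seed))
  invisible(x)
}

## Logistic latent ripeness: u(t) from start u0 and rate k.
latentRipeness <- function(u0, k, t) 1 / (1 + (1 - u0) / u0 * exp(-k * t))

#' Deterministic treatment contrast injected by the generator
#'
#' The noise-free difference (control minus treated) in the expected a*
#' value of a group at a given day, evaluated from the configuration's
#' central parameters. This is the ground truth against which a
#' treatment contrast estimated from simulated data can be compared.
#'
#' @param config a [simulationConfig()].
#' @param group group letter (default `"A"`).
#' @param day storage day (default 14).
#' @return Numeric contrast in a* units.
#' @export
injectedTreatmentContrast <- function(config, group = "A", day = 14) {
  stopifnot(inherits(config, "SimulationConfig"), group %in% names(config$u0))
  u0 <- config$u0[[group]]
  kc <- config$k
  kt <- config$k * (1 - config$rho * config$efficacy[[group]])
  aOf <- function(u) config$aMin + (config$aMax - config$aMin) * u
  aOf(latentRipeness(u0, kc, day)) - aOf(latentRipeness(u0, kt, day))
}

## Vectorized hexcone HSV -> RGB. h degrees, s and v in [0, 1].
hsvToRgb <- function(h, s, v) {
  hh <- (h %% 360) / 60
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  tt <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, tt, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, tt, ifelse(i == 3, q, p)))
  b <- ifelse(i == 4 | i == 5, v, ifelse(i == 3, tt, ifelse(i == 2, q, p)))
  cbind(r = r, g = g, b = b)
}

## Hexcone RGB -> (hue deg, sat pct) on quantized 0..255 integers,
## mirroring the arithmetic sequence of grDevices::rgb2hsv so that bin
## assignments agree bitwise with toHSV().
quantizedHS <- function(r, g, b) {
  rr <- r / 255; gg <- g / 255; bb <- b / 255
  mx <- pmax(rr, gg, bb); mn <- pmin(rr, gg, bb)
  delta <- mx - mn
  h <- numeric(length(rr))
  s <- ifelse(mx > 0, delta / mx, 0)
  chrom <- delta > 0
  hr <- chrom & rr == mx
  hg <- chrom & !hr & gg == mx
  hb <- chrom & !hr & !hg
  h[hr] <- (gg[hr] - bb[hr]) / delta[hr]
  h[hg] <- 2 + (bb[hg] - rr[hg]) / delta[hg]
  h[hb] <- 4 + (rr[hb] - gg[hb]) / delta[hb]
  h <- h / 6
  h[h < 0] <- h[h < 0] + 1
  hue <- h * 360
  hue[hue >= 360] <- 0
  list(hue = hue, sat = s * 100)
}

## Draw a cloud of fruit-surface pixels for red-patch fraction `frac`.
## Returns hue (deg), saturation (pct), value (pct).
sampleSurfacePixels <- function(n, frac, cfg) {
  nRed <- stats::rbinom(1, n, frac)
  nGreen <- n - nRed
  hue <- c(stats::rnorm(nGreen, cfg$greenHue, cfg$greenHueSD),
           stats::rnorm(nRed, cfg$redHue, cfg$redHueSD)) %% 360
  sat <- pmin(100, pmax(5, c(stats::rnorm(nGreen, cfg$greenSat, cfg$greenSatSD),
                             stats::rnorm(nRed, cfg$redSat, cfg$redSatSD))))
  val <- pmin(100, pmax(40, stats::rnorm(n, cfg$valueMean, cfg$valueSD)))
  list(hue = hue, sat = sat, val = val)
}

## Vision features (mean/normalized RGB, PQS point) from a pixel cloud.
## Pixels are quantized to 8 bits first, as a camera would deliver them.
cloudVisionFeatures <- function(cloud) {
  rgb <- round(hsvToRgb(cloud$hue, cloud$sat / 100, cloud$val / 100) * 255)
  hs <- quantizedHS(rgb[, 1], rgb[, 2], rgb[, 3])
  n <- length(hs$hue)
  spec <- binSaturation(hs$hue, hs$sat) / n
  gp <- gravityPoint(spec)
  means <- colMeans(rgb)
  tot <- sum(means)
  c(red = means[[1]], green = means[[2]], blue = means[[3]],
    r_n = means[[1]] / tot, g_n = means[[2]] / tot, b_n = means[[3]] / tot,
    pqs_x = pqsX(gp), pqs_y = pqsY(gp))
}

#' Simulate per-fruit ripening trajectories and vision features
#'
#' Generates the full factorial study at the configured size: for every
#' group, arm, fruit and sampling day it draws the latent ripeness
#' state, the reference measurements (a*, DA-index, firmness) with
#' their measurement noise, and the machine-vision features (mean and
#' normalized RGB, PQS coordinates) computed from a quantized pixel
#' cloud of the two-patch surface model through the package's own
#' spectrum and gravity-point code.
#'
#' @param config a [simulationConfig()].
#' @return A list with `features` (one row per fruit and day:
#'   `sample_id`, `group`, `treatment`, `fruit`, `day`, `a_star`,
#'   `da_index`, `firmness_s`, `red`, `green`, `blue`, `r_n`, `g_n`,
#'   `b_n`, `pqs_x`, `pqs_y`, `roi_pixels`) and `truth` (the noise-free
#'   ground truth per row: latent `u`, `red_fraction`, `true_a`,
#'   `true_da`, `true_s`).
#' @export
simulateTrajectories <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  groups <- names(cfg$u0)
  feat <- list(); truth <- list()
  for (g in groups) {
    arms <- if (g == "F") "control" else c("control", "SF")
    for (arm in arms) {
      for (fr in seq_len(cfg$nFruitPerGroup)) {
        sid <- paste(g, arm, fr, sep = "_")
        u0 <- stats::plogis(stats::qlogis(cfg$u0[[g]]) +
                              stats::rnorm(1, 0, cfg$u0LogitSD))
        kEff <- cfg$k * exp(stats::rnorm(1, 0, cfg$kJitterSD)) *
          (1 - cfg$rho * cfg$efficacy[[g]] * (arm == "SF"))
        s0 <- stats::runif(1, cfg$sInit[1], cfg$sInit[2])
        rS <- cfg$sRate * exp(stats::rnorm(1, 0, cfg$sRateJitterSD)) *
          (1 - cfg$sRho * cfg$efficacy[[g]] * (arm == "SF"))
        for (d in cfg$days) {
          u <- latentRipeness(u0, kEff, d)
          trueA <- cfg$aMin + (cfg$aMax - cfg$aMin) * u
          trueDa <- cfg$daAmp * exp(-cfg$daRate * u)
          trueS <- cfg$sFloor + (s0 - cfg$sFloor) * exp(-rS * d)
          aStar <- trueA + stats::rnorm(1, 0, cfg$aNoiseSD)
          da <- max(0, trueDa + stats::rnorm(1, 0, cfg$daNoiseBase +
                                               cfg$daNoiseProp * trueDa))
          S <- max(0, trueS + stats::rnorm(1, 0, cfg$sNoiseSD))
          vis <- cloudVisionFeatures(
            sampleSurfacePixels(cfg$nPixels, u, cfg))
          feat[[length(feat) + 1L]] <- data.frame(
            sample_id = sid, group = g, treatment = arm, fruit = fr,
            day = d, a_star = aStar, da_index = da, firmness_s = S,
            t(vis), roi_pixels = cfg$nPixels)
          truth[[length(truth) + 1L]] <- data.frame(
            sample_id = sid, group = g, treatment = arm, fruit = fr,
            day = d, u = u, red_fraction = u, true_a = trueA,
            true_da = trueDa, true_s = trueS)
        }
      }
    }
  }
  list(features = do.call(rbind, feat), truth = do.call(rbind, truth))
}

#' Render a synthetic tomato frame with ground truth
#'
#' Draws a single fruit as a disk of chromatic pixels on a near-white,
#' low-saturation background, optionally with a background color cast
#' (to exercise white balancing) and specular glare spots whose
#' saturation falls below any sensible threshold. The fruit surface is
#' a wrapped-normal hue cloud around `hueCenter`; an optional second,
#' red patch turns a `patchFraction` of the surface toward
#' `patchHue` -- the generator's model of progressive surface reddening.
#'
#' The returned per-bin saturation tally is computed from the quantized
#' 8-bit pixels at generation time and serves as exact ground truth for
#' [hueSpectrum()].
#'
#' @param hueCenter base patch hue center, degrees `[0, 360)`.
#' @param satMean base patch mean saturation, percent `(0, 100]`.
#' @param diameterPx fruit disk diameter in pixels (default 40).
#' @param frameSize `c(H, W)` of the frame (default 64 x 64).
#' @param background RGB triple of the background (default near white);
#'   pass an unequal triple to impose a color cast.
#' @param glareFraction fraction of fruit pixels turned into a glare
#'   spot (default 0).
#' @param seed optional integer seed.
#' @param hueSD,satSD spread of the base patch (degrees / percent).
#' @param valueMean,valueSD fruit pixel brightness, percent.
#' @param patchHue,patchSat,patchHueSD,patchSatSD,patchFraction optional
#'   red-patch parameters (`patchFraction = 0` disables the patch).
#' @return A list: `image` ([RGBImage-class]), `fruitMask` (logical
#'   matrix, chromatic non-glare fruit pixels), `glareMask`, `tally`
#'   (length-360 per-bin saturation sums over `fruitMask`), and
#'   `nFruitPixels`.
#' @export
renderTomatoImage <- function(hueCenter, satMean, diameterPx = 40,
                              frameSize = c(64, 64),
                              background = c(250, 250, 250),
                              glareFraction = 0, seed = NULL,
                              hueSD = 4, satSD = 6,
                              valueMean = 78, valueSD = 3,
                              patchHue = NULL, patchSat = NULL,
                              patchHueSD = 4, patchSatSD = 6,
                              patchFraction = 0) {
  stopifnot(hueCenter >= 0, hueCenter < 360, satMean > 0, satMean <= 100)
  H <- frameSize[1]; W <- frameSize[2]
  if (diameterPx > min(H, W) - 2)
    stop("fruit disk (", diameterPx, " px) larger than the frame")
  if (!is.null(seed)) set.seed(seed)
  # background with mild channel noise (keeps saturation low but nonzero)
  px <- array(0, c(H, W, 3))
  for (ch in 1:3)
    px[, , ch] <- matrix(stats::rnorm(H * W, background[ch], 1.2), H, W)
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad <- diameterPx / 2
  dist <- sqrt((row - cy)^2 + (col - cx)^2)
  disk <- which(dist <= rad)
  n <- length(disk)
  if (n == 0L) stop("empty fruit disk")
  nRed <- if (patchFraction > 0) stats::rbinom(1, n, patchFraction) else 0L
  isRed <- rep(FALSE, n)
  if (nRed > 0) isRed[sample.int(n, nRed)] <- TRUE
  hue <- numeric(n); sat <- numeric(n)
  hue[!isRed] <- stats::rnorm(n - nRed, hueCenter, hueSD) %% 360
  sat[!isRed] <- pmin(100, pmax(20, stats::rnorm(n - nRed, satMean, satSD)))
  if (nRed > 0) {
    hue[isRed] <- stats::rnorm(nRed, patchHue, patchHueSD) %% 360
    sat[isRed] <- pmin(100, pmax(20, stats::rnorm(nRed, patchSat, patchSatSD)))
  }
  val <- pmin(100, pmax(40, stats::rnorm(n, valueMean, valueSD)))
  # glare: a compact cluster of washed-out pixels near the upper shoulder
  glare <- rep(FALSE, n)
  nGlare <- round(glareFraction * n)
  if (nGlare > 0) {
    gy <- cy - rad * 0.4; gx <- cx - rad * 0.3
    gdist <- sqrt((row[disk] - gy)^2 + (col[disk] - gx)^2)
    glare[order(gdist)[seq_len(nGlare)]] <- TRUE
    sat[glare] <- stats::runif(nGlare, 0, 2)
    val[glare] <- stats::runif(nGlare, 95, 99)
  }
  rgb <- hsvToRgb(hue, sat / 100, val / 100) * 255
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[disk] <- rgb[, ch]
    px[, , ch] <- plane
  }
  px[] <- round(pmin(255, pmax(0, px)))
  fruitIdx <- disk[!glare]
  hs <- quantizedHS(px[, , 1][fruitIdx], px[, , 2][fruitIdx],
                    px[, , 3][fruitIdx])
  tally <- binSaturation(hs$hue, hs$sat)
  fruitMask <- matrix(FALSE, H, W); fruitMask[fruitIdx] <- TRUE
  glareMask <- matrix(FALSE, H, W); glareMask[disk[glare]] <- TRUE
  list(image = new("RGBImage", pixels = px, source = "",
                   tag = sprintf("synthetic hue=%g sat=%g", hueCenter,
                                 satMean)),
       fruitMask = fruitMask, glareMask = glareMask, tally = tally,
       nFruitPixels = length(fruitIdx))
}

#' Simulate a complete on-disk study
#'
#' Runs [simulateTrajectories()] and writes a self-contained dataset:
#' `images/{group}_{arm}_{fruit}_{day}.png` rendered frames (one per
#' fruit and day), `readings.csv` in the instrument readings schema of
#' [readReadings()], `truth.json` with the per-row ground truth, and
#' `config.yaml`, a snapshot of the resolved configuration. Regeneration
#' with the same configuration (including seed) is byte-identical.
#'
#' The stored absorbances decompose the simulated DA-index against a
#' constant reference (`a720Base`); the resonance frequency is solved
#' from the simulated firmness coefficient and the fruit mass so that
#' [acousticFirmness()] recovers it.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created; parent must exist).
#' @param writeImages set `FALSE` to skip frame rendering (records only).
#' @return Invisibly, a list with the dataset paths and the `features`
#'   and `truth` tables.
#' @export
simulateStudy <- function(config, outdir, writeImages = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!dir.exists(dirname(outdir)))
    stop("parent directory does not exist: ", dirname(outdir))
  dir.create(outdir, showWarnings = FALSE)
  sim <- simulateTrajectories(config)
  feat <- sim$features; truth <- sim$truth
  # readings schema
  set.seed(config$seed + 1L)
  fruitKey <- unique(feat[c("sample_id")])
  mass <- stats::setNames(
    round(stats::rnorm(nrow(fruitKey), config$massMean, config$massSD), 1),
    fruitKey$sample_id)
  m <- mass[feat$sample_id]
  fHz <- sqrt(feat$firmness_s / (config$firmnessScale * m^(2 / 3)))
  u <- truth$u
  readings <- data.frame(
    sample_id = feat$sample_id, group = feat$group,
    treatment = feat$treatment, day = feat$day,
    a670 = feat$da_index + config$a720Base, a720 = config$a720Base,
    f_hz = fHz, mass_g = as.numeric(m), a_star = feat$a_star,
    l_star = 58 - 18 * u + stats::rnorm(nrow(feat), 0, 1.5),
    b_star = 32 - 6 * u + stats::rnorm(nrow(feat), 0, 1.5))
  writeReadings(readings, file.path(outdir, "readings.csv"))
  nImages <- 0L
  if (writeImages) {
    imgDir <- file.path(outdir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      res <- renderTomatoImage(
        hueCenter = config$greenHue, satMean = config$greenSat,
        hueSD = config$greenHueSD, satSD = config$greenSatSD,
        valueMean = config$valueMean,
        diameterPx = config$imageDiameterPx,
        frameSize = config$imageFrameSize,
        background = config$imageBackground,
        glareFraction = config$imageGlareFraction,
        patchHue = config$redHue, patchSat = config$redSat,
        patchHueSD = config$redHueSD, patchSatSD = config$redSatSD,
        patchFraction = r$u,
        seed = (config$seed * 97L + i * 7919L) %% 2147483647L)
      writeRGBImage(res$image, file.path(
        imgDir, sprintf("%s_%s_%d_%d.png", r$group, r$treatment,
                        r$fruit, r$day)))
      nImages <- nImages + 1L
    }
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       digits = NA, dataframe = "columns")
  snap <- unclass(config)
  yaml::write_yaml(snap, file.path(outdir, "config.yaml"))
  invisible(list(dir = outdir, readings = file.path(outdir, "readings.csv"),
                 nImages = nImages, features = feat, truth = truth))
}
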