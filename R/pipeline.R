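#' Pipeline configuration
#'
#' Collects the tunable knobs of the image-to-report pipeline in one
#' serializable object: segmentation method, spectrum normalization,
#' optional PQS hue-range trimming, white-balance reference, firmness
#' instrument scale, the ANOVA design and the significance level.
#'
#' @param seed integer seed used by pipeline steps that draw random
#'   numbers.
#' @param thresholdMethod `"otsu"` (default) or `"fixed"`.
#' @param thresholdValue fixed saturation threshold in `(0, 100)`; used
#'   only when `thresholdMethod = "fixed"`.
#' @param spectrumNormalization `"per_pixel"` (default; comparable
#'   across fruit sizes and the scaling used before PQS) or `"raw_sum"`.
#' @param hueRange optional `c(from, to)` arc restricting the PQS
#'   computation, degrees.
#' @param whiteBalance apply automatic white balancing (default `TRUE`).
#' @param whiteBalanceReference target white level (default 240).
#' @param firmnessScale instrument scale for [acousticFirmness()].
#' @param alpha significance level (default 0.05).
#' @param anovaFactors factors of the factorial design (default group,
#'   treatment, day).
#' @param anovaInteractions as in [factorialAnova()] (default all
#'   pairwise).
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1,
                           thresholdMethod = c("otsu", "fixed"),
                           thresholdValue = NULL,
                           spectrumNormalization = c("per_pixel", "raw_sum"),
                           hueRange = NULL,
                           whiteBalance = TRUE,
                           whiteBalanceReference = 240,
                           firmnessScale = 1e-6,
                           alpha = 0.05,
                           anovaFactors = c("group", "treatment", "day"),
                           anovaInteractions = TRUE) {
  thresholdMethod <- match.arg(thresholdMethod)
  spectrumNormalization <- match.arg(spectrumNormalization)
  if (thresholdMethod == "fixed" &&
      (is.null(thresholdValue) || thresholdValue <= 0 ||
       thresholdValue >= 100))
    stop("'fixed' thresholding needs a thresholdValue in (0, 100)")
  structure(list(
    seed = seed, thresholdMethod = thresholdMethod,
    thresholdValue = thresholdValue,
    spectrumNormalization = spectrumNormalization, hueRange = hueRange,
    whiteBalance = whiteBalance,
    whiteBalanceReference = whiteBalanceReference,
    firmnessScale = firmnessScale, alpha = alpha,
    anovaFactors = anovaFactors, anovaInteractions = anovaInteractions),
    class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("huePQS pipeline configuration\n")
  cat(sprintf("  threshold: %s%s, spectrum: %s, white balance: %s (ref %g)\n",
              x$thresholdMethod,
              if (x$thresholdMethod == "fixed")
                sprintf(" (%g%%)", x$thresholdValue) else "",
              x$spectrumNormalization,
              if (x$whiteBalance) "on" else "off",
              x$whiteBalanceReference))
  cat(sprintf("  alpha = %g, ANOVA factors: %s\n", x$alpha,
              paste(x$anovaFactors, collapse = ", ")))
  invisible(x)
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trip stable: loading a saved configuration reproduces it.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `savePipelineConfig`: `path` invisibly; `loadPipelineConfig`:
#'   a `"PipelineConfig"`.
#' @export
savePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname savePipelineConfig
#' @export
loadPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw[!vapply(raw, is.null, TRUE)])
}

## Parse {group}_{treatment}_{fruit}_{day} metadata from a file name.
parseSampleName <- function(fname) {
  bn <- basename(fname)
  m <- regmatches(bn,
                  regexec("^([A-Za-z]+)_([A-Za-z]+)_([0-9]+)_([0-9]+)\\.",
                          bn))[[1]]
  if (length(m) == 5L)
    data.frame(group = m[2], treatment = m[3],
               fruit = as.integer(m[4]), day = as.integer(m[5]))
  else
    data.frame(group = NA_character_, treatment = NA_character_,
               fruit = NA_integer_, day = NA_integer_)
}

#' Extract color features from a directory of images
#'
#' For every readable image: white balance against the background,
#' convert to HSV, pick the saturation threshold (Otsu by default),
#' segment the fruit ROI, and compute the color summary, hue spectrum
#' and PQS gravity point. Images whose processing fails are skipped
#' with a warning. File names of the form
#' `{group}_{treatment}_{fruit}_{day}.png` contribute study metadata
#' columns; optional crop rectangles turn one frame into several
#' per-fruit rows.
#'
#' @param images a directory or a character vector of image paths.
#' @param config a [pipelineConfig()].
#' @param crops optional named list: for an image basename, a list of
#'   integer rectangles `c(row1, row2, col1, col2)` each processed as
#'   its own ROI source.
#' @param outCsv optional path; when given the feature table is also
#'   written as CSV (deterministically formatted).
#' @return A `data.frame` with one row per image (or crop): metadata,
#'   `file`, `crop`, `threshold`, `roi_pixels`, `red`, `green`, `blue`,
#'   `r_n`, `g_n`, `b_n`, `pqs_x`, `pqs_y`.
#' @export
extractFeatures <- function(images, config = pipelineConfig(),
                            crops = NULL, outCsv = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.(png|jpe?g)$",
                         ignore.case = TRUE, full.names = TRUE)
  images <- sort(images)
  if (length(images) == 0L) stop("no images to process")
  rows <- list()
  for (path in images) {
    imgCrops <- crops[[basename(path)]]
    if (is.null(imgCrops)) imgCrops <- list(NULL)
    for (ci in seq_along(imgCrops)) {
      row <- tryCatch({
        img <- readRGBImage(path)
        rect <- imgCrops[[ci]]
        if (!is.null(rect)) {
          px <- pixels(img)[rect[1]:rect[2], rect[3]:rect[4], , drop = FALSE]
          img <- new("RGBImage", pixels = px, source = path, tag = "crop")
        }
        if (config$whiteBalance)
          img <- tryCatch(
            whiteBalance(img,
                         referenceLevel = config$whiteBalanceReference),
            error = function(e) {
              warning("white balance skipped for ", basename(path), ": ",
                      conditionMessage(e))
              img
            })
        hsv <- toHSV(img)
        thr <- if (config$thresholdMethod == "fixed")
          config$thresholdValue else otsuThreshold(hsv$saturation)
        roi <- segmentROI(hsv$saturation, thr)
        cs <- colorSummary(img, roi)
        hs <- hueSpectrum(hsv$hue, hsv$saturation, roi,
                          normalization = config$spectrumNormalization)
        gp <- gravityPoint(hs, hueRange = config$hueRange)
        meta <- parseSampleName(path)
        cbind(meta,
              data.frame(file = basename(path), crop = ci,
                         threshold = thr, roi_pixels = pixelCount(roi),
                         red = meanRGB(cs)[["R"]],
                         green = meanRGB(cs)[["G"]],
                         blue = meanRGB(cs)[["B"]],
                         r_n = normalizedRGB(cs)[["R_N"]],
                         g_n = normalizedRGB(cs)[["G_N"]],
                         b_n = normalizedRGB(cs)[["B_N"]],
                         pqs_x = pqsX(gp), pqs_y = pqsY(gp)))
      }, error = function(e) {
        warning("skipping ", basename(path), ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no image could be processed")
  out <- do.call(rbind, rows)
  if (!is.null(outCsv)) {
    fmt <- out
    for (cn in names(fmt))
      if (is.double(fmt[[cn]])) fmt[[cn]] <- sprintf("%.17g", fmt[[cn]])
    utils::write.csv(fmt, outCsv, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Analyze a study feature table
#'
#' The statistical layer applied to a joined feature table (one row per
#' fruit and day with `group`, `treatment`, `day` plus numeric
#' features): a factorial ANOVA per response (groups observed in both
#' arms only, so the never-treated absolute control group drops out of
#' treatment models), final-day post hoc comparisons routed by Levene's
#' test (Tukey HSD under homogeneous variances, Games-Howell otherwise)
#' with compact letters for the maturity comparison within each arm and
#' capital letters for the control-vs-treated comparison within each
#' group, and Pearson plus Spearman correlation matrices.
#'
#' @param table the feature `data.frame`.
#' @param config a [pipelineConfig()].
#' @param responses numeric feature columns to analyze; defaults to the
#'   intersection of the standard feature set with `names(table)`.
#' @return A list of class `"studyReport"`: `anova` (wide F table, one
#'   row per response), `anovaDetails`, `posthoc`, `finalDaySummary`
#'   (mean, sd, n per group x arm), `pearson`, `spearman`, `alpha`,
#'   `responses`, `finalDay`.
#' @export
analyzeStudy <- function(table, config = pipelineConfig(),
                         responses = NULL) {
  stopifnot(is.data.frame(table))
  need <- c("group", "treatment", "day")
  if (!all(need %in% names(table)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  if (is.null(responses))
    responses <- intersect(
      c("a_star", "da_index", "firmness_s", "red", "green", "blue",
        "r_n", "g_n", "b_n", "pqs_x", "pqs_y"), names(table))
  if (length(responses) == 0L) stop("no numeric responses to analyze")
  if (length(unique(table$group)) < 2L)
    stop("analysis needs at least 2 maturity groups; got ",
         paste(unique(table$group), collapse = ", "))
  bothArms <- names(which(tapply(table$treatment, table$group,
                                 function(x) length(unique(x))) == 2L))
  if (length(bothArms) < 2L)
    stop("treatment analysis needs >= 2 groups observed in both arms")
  sub <- table[table$group %in% bothArms, ]
  anovaDetails <- list()
  for (resp in responses)
    anovaDetails[[resp]] <- factorialAnova(
      sub, resp, config$anovaFactors,
      interactions = config$anovaInteractions)
  terms <- anovaDetails[[1]]$term
  anovaF <- data.frame(response = responses)
  for (tm in terms) {
    anovaF[[paste0("F_", gsub(":", "x", tm))]] <-
      vapply(responses, function(r) {
        d <- anovaDetails[[r]]; d$statistic[d$term == tm]
      }, 0)
    anovaF[[paste0("p_", gsub(":", "x", tm))]] <-
      vapply(responses, function(r) {
        d <- anovaDetails[[r]]; d$p[d$term == tm]
      }, 0)
  }
  finalDay <- max(table$day)
  fd <- table[table$day == finalDay, ]
  posthoc <- list()
  summ <- list()
  for (resp in responses) {
    byArm <- list()
    for (arm in unique(fd$treatment)) {
      sub2 <- fd[fd$treatment == arm & fd$group %in% bothArms, ]
      byArm[[arm]] <- routedPosthoc(sub2[[resp]], sub2$group, config$alpha)
    }
    byGroup <- list()
    for (g in bothArms) {
      sub2 <- fd[fd$group == g, ]
      ph <- routedPosthoc(sub2[[resp]], sub2$treatment, config$alpha)
      ph$letters <- stats::setNames(toupper(ph$result$letters),
                                    names(ph$result$letters))
      byGroup[[g]] <- ph
    }
    posthoc[[resp]] <- list(maturity = byArm, treatment = byGroup)
    agg <- stats::aggregate(fd[[resp]],
                            by = list(group = fd$group,
                                      treatment = fd$treatment),
                            FUN = function(x) c(mean = mean(x),
                                                sd = stats::sd(x),
                                                n = length(x)))
    summ[[resp]] <- data.frame(group = agg$group,
                               treatment = agg$treatment,
                               mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                               n = agg$x[, "n"])
  }
  structure(list(
    anova = anovaF, anovaDetails = anovaDetails, posthoc = posthoc,
    finalDaySummary = summ,
    pearson = correlationMatrix(table, responses, "pearson"),
    spearman = correlationMatrix(table, responses, "spearman"),
    alpha = config$alpha, responses = responses, finalDay = finalDay),
    class = "studyReport")
}

## Levene-routed post hoc: Tukey HSD for homogeneous variances,
## Games-Howell otherwise.
routedPosthoc <- function(values, groups, alpha) {
  lev <- leveneHomogeneity(values, groups)
  homog <- lev$degenerate || is.na(lev$p) || lev$p >= alpha
  res <- if (homog) tukeyHsd(values, groups, alpha = alpha)
         else gamesHowell(values, groups, alpha = alpha)
  list(levene = lev, route = if (homog) "tukey" else "games-howell",
       result = res, letters = res$letters)
}

#' @export
print.studyReport <- function(x, ...) {
  cat(sprintf("huePQS study report: %d responses, final day %d\n",
              length(x$responses), x$finalDay))
  cat("ANOVA F values:\n")
  f <- x$anova[c("response", grep("^F_", names(x$anova), value = TRUE))]
  fmt <- f
  fmt[-1] <- lapply(fmt[-1], signif, 4)
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write a study report as JSON and Markdown
#'
#' `report.json` carries the full report (versioned schema); `report.md`
#' renders the ANOVA F table, the final-day group tables with compact
#' letter superscripts (capital letters compare treatments, lower-case
#' letters maturity groups), and both correlation matrices.
#'
#' @param report a `"studyReport"` from [analyzeStudy()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "studyReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  mdPath <- file.path(dir, "report.md")
  ser <- list(
    schema = "huePQS-report/1.0",
    alpha = report$alpha,
    final_day = report$finalDay,
    responses = report$responses,
    anova = report$anova,
    posthoc = lapply(report$posthoc, function(ph) list(
      maturity = lapply(ph$maturity, function(r)
        list(route = r$route, letters = as.list(r$letters),
             levene_p = r$levene$p, comparisons = r$result$comparisons)),
      treatment = lapply(ph$treatment, function(r)
        list(route = r$route, letters = as.list(r$letters),
             levene_p = r$levene$p, comparisons = r$result$comparisons)))),
    final_day_summary = report$finalDaySummary,
    pearson = list(r = report$pearson$r, p = report$pearson$p),
    spearman = list(r = report$spearman$r, p = report$spearman$p))
  jsonlite::write_json(ser, jsonPath, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  md <- c(sprintf("# huePQS study report (alpha = %g)", report$alpha), "")
  md <- c(md, "## Factorial ANOVA, F values", "",
          mdTable(signifCols(report$anova)), "")
  for (resp in report$responses) {
    md <- c(md, sprintf("## %s at day %d", resp, report$finalDay), "",
            mdLetterTable(report, resp), "")
  }
  md <- c(md, "## Pearson correlations", "",
          mdMatrix(report$pearson$r), "",
          "## Spearman correlations", "", mdMatrix(report$spearman$r))
  writeLines(md, mdPath)
  invisible(c(json = jsonPath, md = mdPath))
}

signifCols <- function(df, digits = 4) {
  df[-1] <- lapply(df[-1], function(x)
    if (is.numeric(x)) signif(x, digits) else x)
  df
}

mdTable <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r)
    paste("|", paste(as.character(r), collapse = " | "), "|"))
  c(hdr, sep, rows)
}

mdMatrix <- function(m) {
  df <- data.frame(feature = rownames(m), round(m, 3),
                   check.names = FALSE)
  mdTable(df)
}

mdLetterTable <- function(report, resp) {
  summ <- report$finalDaySummary[[resp]]
  ph <- report$posthoc[[resp]]
  arms <- names(ph$maturity)
  groups <- sort(unique(summ$group))
  df <- data.frame(group = groups)
  for (arm in arms) {
    cells <- vapply(groups, function(g) {
      row <- summ[summ$group == g & summ$treatment == arm, ]
      if (nrow(row) == 0L) return("-")
      cap <- if (!is.null(ph$treatment[[g]]))
        ph$treatment[[g]]$letters[[arm]] else ""
      low <- if (g %in% names(ph$maturity[[arm]]$letters))
        ph$maturity[[arm]]$letters[[g]] else ""
      sprintf("%.3g +/- %.3g ^%s%s", row$mean, row$sd, cap, low)
    }, "")
    df[[arm]] <- cells
  }
  mdTable(df)
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Simulates an on-disk study, extracts vision features from the
#' rendered frames, joins them with the instrument readings (computing
#' the DA-index and acoustic firmness from the stored raw quantities),
#' analyzes the joined table and writes the report.
#'
#' @param simConfig a [simulationConfig()].
#' @param pipeConfig a [pipelineConfig()].
#' @param outdir output directory for the dataset and report.
#' @return Invisibly, a list with the `report`, the joined `table`, and
#'   the dataset paths.
#' @export
runStudyPipeline <- function(simConfig = simulationConfig(),
                             pipeConfig = pipelineConfig(),
                             outdir) {
  ds <- simulateStudy(simConfig, outdir, writeImages = TRUE)
  feat <- extractFeatures(file.path(outdir, "images"), pipeConfig,
                          outCsv = file.path(outdir, "features.csv"))
  readings <- readReadings(ds$readings)
  readings$da_index <- daIndex(readings$a670, readings$a720)
  readings$firmness_s <- acousticFirmness(readings$f_hz, readings$mass_g,
                                          scale = pipeConfig$firmnessScale)
  feat$sample_id <- paste(feat$group, feat$treatment, feat$fruit, sep = "_")
  joined <- merge(feat,
                  readings[c("sample_id", "day", "a_star", "da_index",
                             "firmness_s")],
                  by = c("sample_id", "day"))
  report <- analyzeStudy(joined, pipeConfig)
  paths <- writeReport(report, file.path(outdir, "report"))
  invisible(list(report = report, table = joined, dataset = ds,
                 reportPaths = paths))
}
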