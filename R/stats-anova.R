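#' Levene's test for homogeneity of variances
#'
#' Classic Levene test: a one-way ANOVA on the absolute deviations of
#' each observation from its group center (mean by default, median for
#' the Brown-Forsythe variant). Used to route post hoc testing: groups
#' with homogeneous variances go to Tukey HSD, inhomogeneous ones to
#' Games-Howell. Backed by [car::leveneTest()].
#'
#' @param values numeric response vector.
#' @param groups grouping vector (coerced to factor), >= 2 levels with
#'   at least 2 observations each.
#' @param center `"mean"` (default) or `"median"`.
#' @return A list with `statistic` (F), `df` (numerator, denominator),
#'   `p`, and `degenerate` (`TRUE` when every group is internally
#'   constant, in which case the statistic is undefined and flagged).
#' @export
leveneHomogeneity <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n <- table(groups)
  if (any(n < 2L))
    stop("every group needs >= 2 observations; offending: ",
         paste(names(n)[n < 2], collapse = ", "))
  centerFun <- if (center == "mean") mean else stats::median
  dev <- abs(values - stats::ave(values, groups, FUN = centerFun))
  if (all(dev < .Machine$double.eps^0.5 * (1 + abs(values)))) {
    warning("all groups internally constant: Levene statistic undefined")
    return(list(statistic = NaN, df = c(nlevels(groups) - 1L,
                                        length(values) - nlevels(groups)),
                p = NA_real_, degenerate = TRUE))
  }
  lt <- car::leveneTest(values, groups, center = centerFun)
  list(statistic = lt[1, "F value"],
       df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"],
       degenerate = FALSE)
}

#' Factorial fixed-effects ANOVA with Type III sums of squares
#'
#' Fits a fixed-effects linear model with the requested main effects and
#' pairwise interactions and returns the Type III ANOVA table computed
#' with sum-to-zero contrasts, the routing SPSS applies by default.
#' Each term's sum of squares is the residual-sum-of-squares increase
#' from dropping that term's columns from the full model
#' (non-sequential), which remains well defined even for perfect
#' noise-free fits. The shipped study design is three crossed factors
#' -- maturity group, treatment, storage time -- with all three pairwise
#' interactions and no three-way term.
#'
#' Terms whose sum of squares is exactly zero (e.g. a constant response)
#' report `F = 0`, `p = 1`; a perfect noise-free fit reports `F = Inf`,
#' `p = 0` for the non-zero terms.
#'
#' @param data a `data.frame`.
#' @param response name of the numeric response column.
#' @param factors character vector of >= 1 factor columns (each must
#'   have >= 2 observed levels).
#' @param interactions `TRUE` for all pairwise interactions (default),
#'   `FALSE` for main effects only, or a character vector of explicit
#'   `"a:b"` terms.
#' @return A `data.frame` of class `"anovaResult"` with columns `term`,
#'   `df`, `sumsq`, `statistic` (F) and `p`, plus attributes
#'   `df_residual` and `ss_residual`.
#' @examples
#' cfg <- simulationConfig(nFruitPerGroup = 4, days = c(0, 7, 14))
#' tab <- simulateTrajectories(cfg)$features
#' tab <- tab[tab$group %in% c("A", "C"), ]
#' factorialAnova(tab, "a_star", c("group", "treatment", "day"))
#' @export
factorialAnova <- function(data, response, factors, interactions = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (!all(factors %in% names(data)))
    stop("missing factor columns: ",
         paste(setdiff(factors, names(data)), collapse = ", "))
  if (!is.numeric(data[[response]])) stop("'", response, "' must be numeric")
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    data[[f]] <- droplevels(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 observed levels")
  }
  pairTerms <- character(0)
  if (isTRUE(interactions) && length(factors) >= 2L) {
    cmb <- utils::combn(factors, 2L)
    pairTerms <- apply(cmb, 2L, paste, collapse = ":")
  } else if (is.character(interactions)) {
    pairTerms <- interactions
  }
  for (term in pairTerms) {
    fs <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(fs %in% factors))
      stop("interaction '", term, "' uses unknown factors")
    tab <- table(data[[fs[1]]], data[[fs[2]]])
    if (any(tab == 0L)) {
      idx <- which(tab == 0L, arr.ind = TRUE)[1, ]
      stop("interaction '", term, "' is inestimable: empty cell ",
           fs[1], "=", rownames(tab)[idx[1]], " x ",
           fs[2], "=", colnames(tab)[idx[2]])
    }
  }
  fml <- stats::reformulate(c(factors, pairTerms), response = response)
  contr <- stats::setNames(
    rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = contr)
  X <- stats::model.matrix(fit)
  y <- data[[response]]
  asgn <- attr(X, "assign")
  termLabels <- attr(stats::terms(fit), "term.labels")
  rssOf <- function(cols) {
    if (length(cols) == 0L) return(sum((y - mean(y))^2))
    sum(stats::lm.fit(X[, cols, drop = FALSE], y)$residuals^2)
  }
  ssr <- sum(stats::residuals(fit)^2)
  dfr <- stats::df.residual(fit)
  # Type III: each term's SS is the RSS increase from dropping its columns
  # from the full sum-contrast model (non-sequential), the SPSS default.
  ss <- df <- numeric(length(termLabels))
  for (i in seq_along(termLabels)) {
    cols <- which(asgn != i)
    ss[i] <- rssOf(cols) - ssr
    df[i] <- sum(asgn == i)
  }
  msr <- if (dfr > 0) ssr / dfr else NA_real_
  tol <- .Machine$double.eps^0.75 * max(1, sum((y - mean(y))^2))
  Fv <- pv <- numeric(length(termLabels))
  for (i in seq_along(termLabels)) {
    if (ss[i] <= tol) {
      Fv[i] <- 0; pv[i] <- 1
    } else if (!is.na(msr) && msr <= tol) {
      Fv[i] <- Inf; pv[i] <- 0
    } else {
      Fv[i] <- (ss[i] / df[i]) / msr
      pv[i] <- stats::pf(Fv[i], df[i], dfr, lower.tail = FALSE)
    }
  }
  out <- data.frame(term = termLabels, df = df, sumsq = pmax(ss, 0),
                    statistic = Fv, p = pv, row.names = NULL)
  attr(out, "df_residual") <- dfr
  attr(out, "ss_residual") <- ssr
  class(out) <- c("anovaResult", "data.frame")
  out
}

#' @export
print.anovaResult <- function(x, ...) {
  cat("Factorial ANOVA (Type III, sum-to-zero contrasts)\n")
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 5)
  df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  cat(sprintf("Residual df: %d\n", attr(x, "df_residual")))
  invisible(x)
}
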