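## Shared constructor for post hoc results.
posthocResult <- function(comparisons, pMatrix, alpha, method) {
  letters <- compactLetters(pMatrix, alpha = alpha)
  structure(list(comparisons = comparisons, p = pMatrix,
                 letters = letters, alpha = alpha, method = method),
            class = "posthocResult")
}

#' @export
print.posthocResult <- function(x, ...) {
  cat(sprintf("%s post hoc comparisons (alpha = %g)\n", x$method, x$alpha))
  df <- x$comparisons
  df$statistic <- signif(df$statistic, 5)
  df$p_adj <- signif(df$p_adj, 4)
  print(df, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons for groups with homogeneous variances, using
#' the studentized-range distribution with the pooled within-group
#' variance (Tukey-Kramer form for unequal group sizes). Adjusted
#' p-values come from `ptukey(q, k, N - k)`; compact letters are
#' attached via [compactLetters()].
#'
#' @param values numeric response vector.
#' @param groups grouping vector (coerced to factor), >= 2 levels with
#'   at least 2 observations each.
#' @param alpha significance level for the letter display (default 0.05).
#' @return A `"posthocResult"` list: `comparisons` (data.frame with
#'   `level_i`, `level_j`, `statistic` = q, `df`, `p_adj`), the symmetric
#'   `p` matrix, `letters`, `alpha`, `method`.
#' @export
tukeyHsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2L))
    stop("every group needs >= 2 observations; offending: ",
         paste(levels(groups)[n < 2], collapse = ", "))
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  N <- length(values)
  dfr <- N - k
  s2p <- sum((n - 1) * v) / dfr
  lev <- levels(groups)
  pMat <- matrix(1, k, k, dimnames = list(lev, lev))
  comp <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(s2p / 2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) {
      q <- if (m[i] == m[j]) 0 else Inf
      p <- if (m[i] == m[j]) 1 else 0
      if (p == 0) warning("zero pooled SE with unequal means")
    } else {
      q <- abs(m[i] - m[j]) / se
      p <- stats::ptukey(q, k, dfr, lower.tail = FALSE)
    }
    pMat[i, j] <- pMat[j, i] <- p
    comp <- rbind(comp, data.frame(level_i = lev[i], level_j = lev[j],
                                   statistic = unname(q), df = dfr,
                                   p_adj = unname(p)))
  }
  posthocResult(comp, pMat, alpha, "Tukey HSD")
}

#' Games-Howell pairwise comparisons
#'
#' All-pairs comparisons robust to unequal variances: Welch-type
#' statistics `t = |m_i - m_j| / sqrt(s_i^2/n_i + s_j^2/n_j)` with
#' Welch-Satterthwaite degrees of freedom, referred to the studentized
#' range distribution as `q = t * sqrt(2)`. Accepts either raw samples
#' or printed summary statistics (mean, SD, n per level), the latter
#' enabling direct checks against published group tables.
#'
#' @param values numeric response vector (ignored when `summaries` is
#'   given).
#' @param groups grouping vector matching `values`.
#' @param summaries alternatively, a `data.frame` with columns `level`,
#'   `mean`, `sd`, `n` (each `n >= 2`, `sd >= 0`).
#' @param alpha significance level for the letter display (default 0.05).
#' @return A `"posthocResult"` list as in [tukeyHsd()] (statistic = t).
#' @examples
#' day14 <- data.frame(level = c("A", "B", "C", "D", "E"),
#'                     mean = c(21.09, 20.73, 23.64, 24.83, 25.46),
#'                     sd = c(3.48, 2.85, 1.8, 1.79, 1.16), n = 40)
#' gamesHowell(summaries = day14)$letters
#' @export
gamesHowell <- function(values = NULL, groups = NULL, summaries = NULL,
                        alpha = 0.05) {
  if (is.null(summaries)) {
    groups <- factor(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    summaries <- data.frame(
      level = levels(groups),
      mean = as.numeric(tapply(values, groups, mean)),
      sd = as.numeric(tapply(values, groups, stats::sd)),
      n = as.integer(table(groups)))
  }
  stopifnot(all(c("level", "mean", "sd", "n") %in% names(summaries)))
  if (any(summaries$n < 2L)) stop("every group needs n >= 2")
  if (any(summaries$sd < 0)) stop("standard deviations must be >= 0")
  k <- nrow(summaries)
  if (k < 2L) stop("need at least 2 groups")
  lev <- as.character(summaries$level)
  m <- summaries$mean; s <- summaries$sd; n <- summaries$n
  pMat <- matrix(1, k, k, dimnames = list(lev, lev))
  comp <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- s[i]^2 / n[i] + s[j]^2 / n[j]
    if (se2 == 0) {
      tstat <- if (m[i] == m[j]) 0 else Inf
      df <- n[i] + n[j] - 2
      p <- if (m[i] == m[j]) 1 else 0
      if (p == 0) warning("zero pooled SE with unequal means: p = 0")
    } else {
      tstat <- abs(m[i] - m[j]) / sqrt(se2)
      df <- se2^2 / ((s[i]^2 / n[i])^2 / (n[i] - 1) +
                     (s[j]^2 / n[j])^2 / (n[j] - 1))
      p <- stats::ptukey(tstat * sqrt(2), k, df, lower.tail = FALSE)
    }
    pMat[i, j] <- pMat[j, i] <- p
    comp <- rbind(comp, data.frame(level_i = lev[i], level_j = lev[j],
                                   statistic = tstat, df = df, p_adj = p))
  }
  posthocResult(comp, pMat, alpha, "Games-Howell")
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb lettering: starting from a single letter covering
#' all levels, every significant pair splits the letters containing both
#' members, and redundant (subset) letters are absorbed. Two levels
#' share a letter iff no chain of the display separates them, i.e.
#' levels connected by `p >= alpha` share a letter; the letter set is
#' minimal for the insert-and-absorb rule.
#'
#' @param p complete symmetric matrix of adjusted p-values with level
#'   names as dimnames (diagonal ignored).
#' @param alpha significance level (default 0.05).
#' @return Named character vector of letter strings, one per level.
#' @examples
#' p <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3, 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' compactLetters(p)  # A="a", B="ab", C="b"
#' @export
compactLetters <- function(p, alpha = 0.05) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  lev <- rownames(p)
  if (is.null(lev)) lev <- paste0("L", seq_len(nrow(p)))
  k <- length(lev)
  cols <- list(stats::setNames(rep(TRUE, k), lev))
  sig <- which(upper.tri(p) & p < alpha, arr.ind = TRUE)
  if (nrow(sig)) for (r in seq_len(nrow(sig))) {
    i <- sig[r, 1]; j <- sig[r, 2]
    nxt <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[j] <- FALSE
        c2 <- col; c2[i] <- FALSE
        nxt <- c(nxt, list(c1, c2))
      } else nxt <- c(nxt, list(col))
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) for (b in seq_along(nxt)) {
      if (a != b && keep[a] && keep[b] && all(nxt[[a]] <= nxt[[b]]) &&
          (any(nxt[[a]] != nxt[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- nxt[keep]
  }
  ord <- order(vapply(cols, function(col) which(col)[1], 0L))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(i)
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = ""), "")
  stats::setNames(out, lev)
}
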