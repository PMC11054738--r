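#' Pearson or Spearman correlation matrix with p-values
#'
#' Pairwise-complete correlation matrix over the requested feature
#' columns with two-sided p-values from [stats::cor.test()]. Spearman's
#' rank correlation is offered alongside Pearson's because several
#' ripening quantities (notably the chlorophyll-related DA-index) relate
#' to color monotonically but not linearly. A constant feature yields
#' `NA` entries with a warning, as its correlation is undefined; pairs
#' with fewer than 3 complete rows likewise.
#'
#' @param data a `data.frame`.
#' @param features character vector of numeric column names.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `"correlationResult"` list with symmetric matrices `r`, `p`
#'   and `n` (pairwise complete sample sizes) and the `method`.
#' @export
correlationMatrix <- function(data, features,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(features %in% names(data)))
  k <- length(features)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(features, features))
  n <- matrix(0L, k, k, dimnames = list(features, features))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- vapply(features, function(f) sum(!is.na(data[[f]])), 0L)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- data[[features[i]]]; y <- data[[features[j]]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L) {
      warning("fewer than 3 complete rows for ", features[i], " vs ",
              features[j])
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("constant feature in pair ", features[i], " vs ",
              features[j], ": correlation undefined")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n, method = method),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("%s correlation matrix (%d features)\n",
              tools::toTitleCase(x$method), nrow(x$r)))
  print(round(x$r, 3))
  invisible(x)
}
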