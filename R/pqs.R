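## Resolve a hue arc [from, to) in degrees to a logical keep-vector over
## n equal bins; wrap-around arcs (from > to) are allowed.
arcMask <- function(n, hueRange) {
  centers <- (seq_len(n) - 0.5) * (360 / n)
  if (is.null(hueRange)) return(rep(TRUE, n))
  stopifnot(length(hueRange) == 2L)
  a <- hueRange[1] %% 360
  b <- hueRange[2]
  if (b != 360) b <- b %% 360
  if (a == b) stop("empty hue range: the arc [", hueRange[1], ", ",
                   hueRange[2], ") covers no bins")
  keep <- if (a < b) centers >= a & centers < b else centers >= a | centers < b
  if (!any(keep)) stop("empty hue range: no bins inside the arc")
  keep
}

#' PQS gravity point (surface method) of a polar spectrum
#'
#' Compresses a hue spectrum to a single 2-D quality point: the spectrum
#' is drawn as a polar curve r(theta), with theta the hue-bin center in
#' radians and r the bin value, and the area centroid (gravity point) of
#' the enclosed figure is returned. Summed per circular sector of width
#' `dtheta`:
#' \deqn{A = \tfrac12 \sum_i r_i^2 \Delta\theta,\quad
#'   X = \frac{1}{3A} \sum_i r_i^3 \cos\theta_i \Delta\theta,\quad
#'   Y = \frac{1}{3A} \sum_i r_i^3 \sin\theta_i \Delta\theta.}
#' This is the exact centroid of the piecewise-constant polar region, so
#' a constant spectrum maps to the origin, a half-disk to
#' `(4r/(3*pi), 0)`, and a single thin sector to approximately
#' `(2r/3)(cos theta, sin theta)`.
#'
#' A `hueRange` arc restricts the sum to the bins inside it, which
#' implements the trimming of indifferent hue segments.
#'
#' @param spectrum a [HueSpectrum-class], or a bare non-negative numeric
#'   vector of bin values covering the full circle (any number of equal
#'   bins -- useful for binning-refinement checks).
#' @param hueRange optional numeric `c(from, to)` arc in degrees,
#'   inclusive of `from`, exclusive of `to`; `from > to` wraps through 0.
#' @return A [PQSPoint-class].
#' @examples
#' half <- c(rep(1, 90), rep(0, 180), rep(1, 90))  # r = 1 on [-90, 90]
#' gravityPoint(half)                              # ~ (4/(3*pi), 0)
#' @export
setGeneric("gravityPoint",
           function(spectrum, hueRange = NULL) standardGeneric("gravityPoint"))

#' @rdname gravityPoint
#' @export
setMethod("gravityPoint", "numeric", function(spectrum, hueRange = NULL) {
  r <- spectrum
  n <- length(r)
  if (n < 1L) stop("empty spectrum")
  if (anyNA(r) || any(r < 0)) stop("spectrum must be non-negative and finite")
  keep <- arcMask(n, hueRange)
  r <- r * keep
  dtheta <- 2 * pi / n
  theta <- (seq_len(n) - 0.5) * dtheta
  A <- 0.5 * sum(r^2) * dtheta
  if (A <= 0)
    stop("gravity point undefined for a zero-area spectrum")
  new("PQSPoint",
      x = sum(r^3 * cos(theta)) * dtheta / (3 * A),
      y = sum(r^3 * sin(theta)) * dtheta / (3 * A))
})

#' @rdname gravityPoint
#' @export
setMethod("gravityPoint", "HueSpectrum", function(spectrum, hueRange = NULL) {
  gravityPoint(spectrumValues(spectrum), hueRange = hueRange)
})

#' Monte Carlo gravity point (independent oracle)
#'
#' Estimates the same area centroid as [gravityPoint()] by rejection
#' sampling: points are drawn uniformly in the bounding disk of the polar
#' curve, those inside the region (`rho <= r(theta)` of their angular
#' bin) are kept, and their mean position is returned together with its
#' standard error. Intended as an implementation-independent check of
#' the closed-form sector sums, not for production use.
#'
#' @param spectrum a [HueSpectrum-class] or non-negative numeric vector.
#' @param nSamples number of proposal points (>= 1e4).
#' @param seed optional integer seed for reproducibility.
#' @param hueRange optional arc as in [gravityPoint()].
#' @return A list with elements `point` ([PQSPoint-class]), `se` (named
#'   numeric, standard errors of x and y), and `nAccepted`.
#' @export
gravityPointMC <- function(spectrum, nSamples = 1e5, seed = NULL,
                           hueRange = NULL) {
  if (is(spectrum, "HueSpectrum")) spectrum <- spectrumValues(spectrum)
  stopifnot(is.numeric(spectrum), nSamples >= 1e4)
  n <- length(spectrum)
  r <- spectrum * arcMask(n, hueRange)
  if (anyNA(r) || any(r < 0)) stop("spectrum must be non-negative and finite")
  rmax <- max(r)
  if (rmax <= 0) stop("gravity point undefined for a zero-area spectrum")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  theta <- stats::runif(nSamples, 0, 2 * pi)
  rho <- rmax * sqrt(stats::runif(nSamples))
  bin <- pmin(n, floor(theta / (2 * pi / n)) + 1L)
  acc <- rho <= r[bin]
  nacc <- sum(acc)
  if (nacc == 0L) stop("Monte Carlo acceptance rate is zero")
  x <- rho[acc] * cos(theta[acc])
  y <- rho[acc] * sin(theta[acc])
  list(point = new("PQSPoint", x = mean(x), y = mean(y)),
       se = c(x = stats::sd(x) / sqrt(nacc), y = stats::sd(y) / sqrt(nacc)),
       nAccepted = nacc)
}
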