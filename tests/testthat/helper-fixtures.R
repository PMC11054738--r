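# Shared fixture builders: all synthetic, generated at test time.

# Smooth, strictly positive random polar spectrum (Fourier-type bumps).
randomSpectrum <- function(seed, n = 360) {
  set.seed(seed)
  th <- (seq_len(n) - 0.5) * 2 * pi / n
  k1 <- sample(1:4, 1); k2 <- sample(1:5, 1)
  r <- exp(runif(1, 0.3, 0.9) * sin(k1 * th + runif(1, 0, 2 * pi)) +
             runif(1, 0.2, 0.6) * cos(k2 * th + runif(1, 0, 2 * pi)))
  r * runif(1, 0.5, 2)
}

# Uniform-color image (default 16 x 16).
uniformImage <- function(r, g, b, h = 16, w = 16) {
  px <- array(0, c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  RGBImage(px)
}

maskAll <- function(image) {
  d <- dim(pixels(image))
  new("ROIMask", mask = matrix(TRUE, d[1], d[2]),
      pixelCount = as.integer(d[1] * d[2]))
}

# Letter partition as a canonical sharing structure (for order-invariance
# checks): for each unordered level pair, whether they share a letter.
letterSharing <- function(letters) {
  lev <- sort(names(letters))
  sets <- lapply(letters, function(s) strsplit(s, "")[[1]])
  out <- outer(lev, lev, Vectorize(function(a, b)
    length(intersect(sets[[a]], sets[[b]])) > 0))
  dimnames(out) <- list(lev, lev)
  out
}

# Half-disk spectrum: r = 1 on [-90, 90], 0 elsewhere, at n bins.
halfDiskSpectrum <- function(n = 360) {
  q <- n / 4
  c(rep(1, q), rep(0, 2 * q), rep(1, q))
}
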