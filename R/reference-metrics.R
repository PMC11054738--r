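#' DA-index: chlorophyll-related absorbance difference
#'
#' The index of absorbance difference `I_AD = A670 - A720`, the
#' difference between the absorbance at the chlorophyll-a peak (670 nm)
#' and at a reference wavelength (720 nm). It proxies photosynthetically
#' active chlorophyll content: higher means greener tissue, and the value
#' decays toward zero as ripening progresses. Instruments report it on a
#' 0--5 range; values outside that range are flagged with a warning but
#' never clamped, since the index is a pure difference.
#'
#' @param a670,a720 absorbances (dimensionless); vectors are recycled to
#'   a common length.
#' @return `a670 - a720`.
#' @examples
#' daIndex(1.3, 0)    # greenest plausible tomato reading
#' daIndex(0.05, 0.047)
#' @export
daIndex <- function(a670, a720) {
  if (!all(is.finite(a670)) || !all(is.finite(a720)))
    stop("absorbances must be finite")
  idx <- a670 - a720
  if (any(idx < 0 | idx > 5))
    warning("DA-index outside the instrument range [0, 5]")
  idx
}

#' Acoustic firmness (stiffness) coefficient
#'
#' From the resonance frequency of a mechanically excited fruit:
#' `S = f^2 * m^(2/3)`, with `f` the resonance frequency and `m` the
#' mass. An instrument scale factor is applied on top of the formula
#' (default `1e-6`, equivalent to expressing `f` in kHz), which brings
#' plausible tomato readings onto the conventional single-digit
#' `g^(2/3) s^-2` reporting band. The coefficient declines monotonically
#' as the fruit softens.
#'
#' @param f resonance frequency in Hz (`>= 0`).
#' @param mass fruit mass in g (`> 0`).
#' @param scale positive instrument scale factor (default `1e-6`).
#' @return Firmness coefficient(s) `scale * f^2 * mass^(2/3)`.
#' @examples
#' acousticFirmness(500, 110)  # ~5.7, a firm just-harvested tomato
#' @export
acousticFirmness <- function(f, mass, scale = 1e-6) {
  if (!all(is.finite(f)) || any(f < 0)) stop("'f' must be finite and >= 0")
  if (!all(is.finite(mass)) || any(mass <= 0))
    stop("'mass' must be finite and > 0")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  scale * f^2 * mass^(2 / 3)
}

readingsColumns <- c("sample_id", "group", "treatment", "day",
                     "a670", "a720", "f_hz", "mass_g",
                     "a_star", "l_star", "b_star")

#' Read / write an instrument readings table
#'
#' CSV schema: `sample_id, group, treatment, day, a670, a720, f_hz,
#' mass_g, a_star, l_star, b_star`. `l_star` and `b_star` are carried
#' for completeness but not analyzed downstream (they carry little
#' ripening information). Numeric columns are serialized with 17
#' significant digits so that a read/write round trip preserves every
#' double bit-exactly.
#'
#' @param path CSV path.
#' @return `readReadings`: a `data.frame` with the schema above.
#' @export
readReadings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(readingsColumns, names(df))
  if (length(missing))
    stop("readings CSV is missing columns: ", paste(missing, collapse = ", "))
  df[readingsColumns]
}

#' @rdname readReadings
#' @param readings a `data.frame` with the schema above.
#' @export
writeReadings <- function(readings, path) {
  missing <- setdiff(readingsColumns, names(readings))
  if (length(missing))
    stop("readings table is missing columns: ",
         paste(missing, collapse = ", "))
  out <- readings[readingsColumns]
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
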