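# Circular dichroism: molar normalization, composite-spectrum prediction,
# quartet-count amplitude scaling and parallel-topology classification.

#' Construct a CDSpectrum
#'
#' @param wavelength numeric, strictly increasing wavelength grid (nm).
#' @param value numeric, ellipticity (mdeg) or molar CD.
#' @param units \code{"raw"} (mdeg) or \code{"molar"}.
#' @param meta list of provenance fields.
#' @return a \linkS4class{CDSpectrum}.
#' @examples
#' cdSpectrum(220:340, rep(0, 121))
#' @export
cdSpectrum <- function(wavelength, value, units = "raw", meta = list()) {
  new("CDSpectrum", wavelength = as.numeric(wavelength),
      value = as.numeric(value), units = units, meta = meta)
}

#' Read a two-column wavelength/value CSV as a CDSpectrum
#'
#' @param file CSV with a header line and columns wavelength, value.
#' @param units units flag for the values read (default \code{"raw"}).
#' @return a \linkS4class{CDSpectrum}.
#' @export
readCDSpectrum <- function(file, units = "raw") {
  d <- utils::read.csv(file)
  if (ncol(d) < 2) stop("expected at least two columns (wavelength, value)")
  o <- order(d[[1]])
  cdSpectrum(d[[1]][o], d[[2]][o], units = units,
             meta = list(source = file))
}

#' Write a CDSpectrum to CSV
#'
#' @param spec a \linkS4class{CDSpectrum}.
#' @param file output path.
#' @export
writeCDSpectrum <- function(spec, file) {
  utils::write.csv(data.frame(wavelength = spec@wavelength,
                              value = spec@value),
                   file, row.names = FALSE)
  invisible(file)
}

#' Normalize raw ellipticity to molar circular dichroism
#'
#' \eqn{\Delta\epsilon(\lambda) = \theta(\lambda) / (32980 \, c \, l)}
#' with \eqn{\theta} in millidegrees, \eqn{c} the DNA strand concentration
#' in mol/L and \eqn{l} the path length in cm.
#'
#' @param raw a \linkS4class{CDSpectrum} with \code{units = "raw"}.
#' @param conc_M strand concentration in mol/L (> 0).
#' @param path_cm path length in cm (> 0).
#' @return a molar \linkS4class{CDSpectrum}; \code{meta} records
#'   \code{conc_M} and \code{path_cm}.
#' @examples
#' s <- cdSpectrum(250:270, rep(32.980, 21))
#' normalizeToMolarCD(s, conc_M = 1e-6, path_cm = 1)  # 1000 everywhere
#' @export
normalizeToMolarCD <- function(raw, conc_M, path_cm = 1) {
  stopifnot(is(raw, "CDSpectrum"))
  if (raw@units != "raw")
    stop("spectrum is already on the molar scale")
  if (conc_M <= 0) stop("concentration must be > 0")
  if (path_cm <= 0) stop("path length must be > 0")
  meta <- raw@meta
  meta$conc_M <- conc_M
  meta$path_cm <- path_cm
  cdSpectrum(raw@wavelength, raw@value / (32980 * conc_M * path_cm),
             units = "molar", meta = meta)
}

#' Resample a spectrum onto a common 1-nm grid by linear interpolation
#'
#' @param spec a \linkS4class{CDSpectrum}.
#' @param grid target wavelength grid (default 220:340 nm).
#' @return a \linkS4class{CDSpectrum} on \code{grid}; wavelengths outside
#'   the original coverage raise an error.
#' @export
resampleSpectrum <- function(spec, grid = 220:340) {
  stopifnot(is(spec, "CDSpectrum"))
  rng <- range(spec@wavelength)
  if (min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 1e-9)
    stop("requested grid extends beyond spectrum coverage (",
         rng[1], "-", rng[2], " nm)")
  v <- stats::approx(spec@wavelength, spec@value, xout = grid)$y
  cdSpectrum(grid, v, units = spec@units, meta = spec@meta)
}

#' Weighted sum of component spectra
#'
#' Predicts the spectrum of a composite structure as a pointwise weighted
#' sum of molar component spectra, after resampling all components to a
#' common grid. Linear in every component and invariant to component
#' order.
#'
#' @param components list of \linkS4class{CDSpectrum} objects
#'   (\code{units = "molar"}).
#' @param weights numeric vector of non-negative weights, recycled to the
#'   number of components (default all 1: one structural unit each).
#' @param grid common wavelength grid; defaults to the intersection of
#'   all component ranges, at 1-nm steps.
#' @return a molar \linkS4class{CDSpectrum}.
#' @export
compositeSpectrum <- function(components, weights = 1, grid = NULL) {
  if (!length(components)) stop("no components supplied")
  if (!all(vapply(components, function(x)
    is(x, "CDSpectrum") && x@units == "molar", logical(1))))
    stop("all components must be molar CDSpectrum objects")
  weights <- rep_len(weights, length(components))
  if (any(weights < 0)) stop("weights must be >= 0")
  if (is.null(grid)) {
    lo <- max(vapply(components, function(x) min(x@wavelength), numeric(1)))
    hi <- min(vapply(components, function(x) max(x@wavelength), numeric(1)))
    if (lo >= hi) stop("component spectra have no common wavelength range")
    grid <- seq(ceiling(lo), floor(hi), by = 1)
  }
  vals <- vapply(components, function(x) resampleSpectrum(x, grid)@value,
                 numeric(length(grid)))
  v <- as.numeric(vals %*% weights)
  cdSpectrum(grid, v, units = "molar",
             meta = list(weights = weights, n_components = length(components)))
}

#' Scale a reference parallel-quadruplex spectrum by quartet count
#'
#' The molar CD amplitude of stacked parallel quadruplexes grows in
#' proportion to the number of stacked G-quartets, so a structure with
#' \code{n_target} quartets is predicted to have
#' \code{n_target / n_ref} times the amplitude of an \code{n_ref}-quartet
#' reference unit at every wavelength.
#'
#' @param reference molar \linkS4class{CDSpectrum} of an
#'   \code{n_ref}-quartet parallel unit.
#' @param n_target number of quartets in the predicted structure (>= 1).
#' @param n_ref number of quartets in the reference (default 3).
#' @return the scaled \linkS4class{CDSpectrum}.
#' @export
quartetScaledPrediction <- function(reference, n_target, n_ref = 3) {
  stopifnot(is(reference, "CDSpectrum"))
  if (n_target < 1 || n_ref < 1) stop("quartet counts must be >= 1")
  meta <- reference@meta
  meta$quartet_scale <- n_target / n_ref
  cdSpectrum(reference@wavelength, reference@value * (n_target / n_ref),
             units = reference@units, meta = meta)
}

#' Classify a molar CD spectrum as parallel-quadruplex-like or other
#'
#' The hallmark of a parallel quadruplex is a positive maximum near
#' 260 nm with a negative minimum near 240 nm. The classifier requires
#' the global maximum over 230-300 nm to fall in a window around 260 nm
#' (default 255-270 nm) with positive sign, and a negative local minimum
#' in a window around 240 nm (default 235-245 nm).
#'
#' @param spec molar \linkS4class{CDSpectrum} covering at least
#'   230-300 nm.
#' @param max_window,min_window numeric length-2 windows (nm) for the
#'   peak and trough tests.
#' @return \code{"parallel"} or \code{"other"}.
#' @export
classifyTopology <- function(spec, max_window = c(255, 270),
                             min_window = c(235, 245)) {
  stopifnot(is(spec, "CDSpectrum"))
  if (spec@units != "molar") stop("classifier expects a molar spectrum")
  if (min(spec@wavelength) > 230 || max(spec@wavelength) < 300)
    stop("spectrum must cover 230-300 nm")
  keep <- spec@wavelength >= 230 & spec@wavelength <= 300
  wl <- spec@wavelength[keep]
  v <- spec@value[keep]
  wmax <- wl[which.max(v)]
  peak_ok <- max(v) > 0 && wmax >= max_window[1] && wmax <= max_window[2]
  inmin <- wl >= min_window[1] & wl <= min_window[2]
  trough_ok <- any(inmin) && min(v[inmin]) < 0 &&
    min(v[inmin]) <= min(v[wl >= 230 & wl < min_window[1]], Inf)
  if (peak_ok && trough_ok) "parallel" else "other"
}

#' Amplitude of a spectrum at (or near) a wavelength
#'
#' @param spec a \linkS4class{CDSpectrum}.
#' @param wavelength wavelength of interest in nm (default 260).
#' @return interpolated signal value.
#' @export
amplitudeAt <- function(spec, wavelength = 260) {
  stopifnot(is(spec, "CDSpectrum"))
  stats::approx(spec@wavelength, spec@value, xout = wavelength)$y
}
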