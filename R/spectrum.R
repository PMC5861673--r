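#' Working spectral grid
#'
#' A regular wavelength grid on which all spectra, coefficient tables and
#' simulations are expressed. The default grid is 400--2200 nm at 1 nm
#' (1801 points), the domain over which the leaf model is calibrated and the
#' measured signal is above the noise floor.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm).
#' @param step Grid step (nm), strictly positive.
#' @return An object of class `working_grid`.
#' @examples
#' g <- working_grid()
#' length(grid_wavelengths(g)) # 1801
#' @export
working_grid <- function(start = 400, stop = 2200, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1,
            is.finite(start), is.finite(stop), is.finite(step))
  if (step <= 0) stop("grid step must be > 0")
  if (stop <= start) stop("grid stop must exceed start")
  structure(list(start = start, stop = stop, step = step),
            class = "working_grid")
}

#' @rdname working_grid
#' @param g A `working_grid`.
#' @export
grid_wavelengths <- function(g) {
  stopifnot(inherits(g, "working_grid"))
  seq(g$start, g$stop, by = g$step)
}

#' @export
print.working_grid <- function(x, ...) {
  cat(sprintf("<working_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, length(grid_wavelengths(x))))
  invisible(x)
}

#' Leaf spectrum
#'
#' A wavelength-indexed vector of reflectance or transmittance values.
#' Calibrated spectra are dimensionless fractions; values marginally above 1
#' (up to 1.05) are tolerated for measurement noise. Raw detector signals can
#' be stored with `calibrated = FALSE`, in which case no range check applies.
#'
#' @param wavelength Wavelengths in nm, strictly increasing, within
#'   350--2500 nm.
#' @param value Spectral values, same length as `wavelength`.
#' @param calibrated Logical; `TRUE` for reflectance/transmittance fractions.
#' @return An object of class `leaf_spectrum`.
#' @export
spectrum <- function(wavelength, value, calibrated = TRUE) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length")
  if (length(wavelength) < 1L) stop("empty spectrum")
  if (anyNA(wavelength) || anyNA(value))
    stop("spectrum contains missing values")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelength) < 350 || max(wavelength) > 2500)
    stop("wavelengths must lie within 350-2500 nm")
  if (calibrated && (min(value) < 0 || max(value) > 1.05))
    stop("calibrated values must lie within [0, 1.05]")
  structure(list(wavelength = wavelength, value = value,
                 calibrated = isTRUE(calibrated)),
            class = "leaf_spectrum")
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> %d points, %g-%g nm, values %.4g-%.4g%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value),
              if (x$calibrated) "" else " (uncalibrated)"))
  invisible(x)
}

#' @export
as.data.frame.leaf_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' Resample a spectrum onto a working grid
#'
#' Linear interpolation between neighbouring samples; the input must cover
#' the full grid (no extrapolation is ever performed). Idempotent for a
#' spectrum already on the grid.
#'
#' @param s A [spectrum()].
#' @param g A [working_grid()].
#' @return A `leaf_spectrum` on exactly the grid wavelengths.
#' @export
resample_to_grid <- function(s, g) {
  stopifnot(inherits(s, "leaf_spectrum"), inherits(g, "working_grid"))
  if (min(s$wavelength) > g$start || max(s$wavelength) < g$stop)
    stop(sprintf(
      "spectrum support %g-%g nm does not cover grid %g-%g nm",
      min(s$wavelength), max(s$wavelength), g$start, g$stop))
  wl <- grid_wavelengths(g)
  v <- stats::approx(s$wavelength, s$value, xout = wl, method = "linear",
                     ties = "ordered")$y
  spectrum(wl, v, calibrated = s$calibrated)
}

#' Mean reflectance over a wavelength band
#'
#' Arithmetic mean of the spectral values at the stored wavelengths falling
#' in `[lo, hi]` inclusive. A degenerate band (`lo == hi`) returns the value
#' at the nearest stored wavelength, which is how single-band terms of
#' vegetation indices are read off the grid.
#'
#' @param s A [spectrum()].
#' @param lo,hi Band limits in nm, `lo <= hi`, within the spectrum support.
#' @return A scalar.
#' @export
band_mean <- function(s, lo, hi = lo) {
  stopifnot(inherits(s, "leaf_spectrum"), is.numeric(lo), is.numeric(hi))
  if (lo > hi) stop("band lower limit exceeds upper limit")
  if (lo < min(s$wavelength) || hi > max(s$wavelength))
    stop(sprintf("band %g-%g nm outside spectrum support %g-%g nm",
                 lo, hi, min(s$wavelength), max(s$wavelength)))
  if (lo == hi) {
    return(s$value[which.min(abs(s$wavelength - lo))])
  }
  sel <- s$wavelength >= lo & s$wavelength <= hi
  if (!any(sel)) { # band narrower than the grid step: fall back to nearest
    return(s$value[which.min(abs(s$wavelength - (lo + hi) / 2))])
  }
  mean(s$value[sel])
}

#' Read or write a two-column spectrum file
#'
#' Plain-text ad-hoc exchange format: a header line then
#' `wavelength_nm,value` rows.
#'
#' @param path File path.
#' @param calibrated Passed to [spectrum()].
#' @return `read_spectrum()` returns a `leaf_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path, calibrated = TRUE) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected a two-column wavelength,value file")
  spectrum(d[[1]], d[[2]], calibrated = calibrated)
}

#' @rdname read_spectrum
#' @param s A `leaf_spectrum`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "leaf_spectrum"))
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}
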