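#' White background spectrum
#'
#' Hemispherical reflectance of the Teflon white background placed under the
#' leaf. When no measured background is available a flat synthetic Teflon
#' curve (default 0.99) is used; a measured spectrum can be supplied and is
#' resampled to the grid.
#'
#' @param grid A [working_grid()].
#' @param reflectance Either a scalar in (0, 1] for a flat background or a
#'   [spectrum()] to resample.
#' @return A `leaf_spectrum` on the grid, values in (0, 1].
#' @export
background_spectrum <- function(grid = working_grid(), reflectance = 0.99) {
  if (inherits(reflectance, "leaf_spectrum")) {
    bg <- resample_to_grid(reflectance, grid)
  } else {
    stopifnot(is.numeric(reflectance), length(reflectance) == 1)
    bg <- spectrum(grid_wavelengths(grid),
                   rep(reflectance, length(grid_wavelengths(grid))))
  }
  if (any(bg$value <= 0) || any(bg$value > 1))
    stop("background reflectance must lie in (0, 1]")
  bg
}

.bg_values <- function(bg, coefs) {
  if (inherits(bg, "leaf_spectrum")) {
    if (length(bg$wavelength) != length(coefs$wavelength) ||
        any(bg$wavelength != coefs$wavelength))
      stop("background spectrum is not on the coefficient grid")
    bg$value
  } else {
    rep_len(as.numeric(bg), length(coefs$wavelength))
  }
}

#' Reflectance of the lower leaf surface over the white background
#'
#' Multiple-bounce coupling of the (wavelength-independent, non-absorbing)
#' lower surface of reflectivity `Rsurf` and transmissivity `1 - Rsurf` with
#' the background:
#' \deqn{R_{surf}^{wb}(\lambda) = R_{surf} +
#'   \frac{R_{wb}(\lambda)(1-R_{surf})^2}{1 - R_{surf} R_{wb}(\lambda)}}
#'
#' @param rsurf Surface reflectivity, scalar in `[0, 1)`.
#' @param r_wb Background reflectance: a `leaf_spectrum` or numeric vector
#'   in `[0, 1]`.
#' @return Same type as `r_wb` (spectrum in, spectrum out).
#' @export
surface_over_background <- function(rsurf, r_wb) {
  stopifnot(is.numeric(rsurf), length(rsurf) == 1, rsurf >= 0, rsurf < 1)
  spec_in <- inherits(r_wb, "leaf_spectrum")
  v <- if (spec_in) r_wb$value else as.numeric(r_wb)
  stopifnot(all(v >= 0), all(v <= 1))
  out <- .surface_over_bg_vec(rsurf, v)
  if (spec_in) spectrum(r_wb$wavelength, out) else out
}

.surface_over_bg_vec <- function(rsurf, rwb) {
  denom <- 1 - rsurf * rwb
  denom[denom <= 0] <- .Machine$double.eps # unreachable for valid inputs
  pmin(rsurf + rwb * (1 - rsurf)^2 / denom, 1)
}

#' Reflectance of the leaf over the white background
#'
#' Two-stage composition of the leaf volume with the backed lower surface
#' and then with the upper surface: first the reflectance at the bottom of
#' the upper epidermis,
#' \deqn{R_{bue}^{wb} = R_{leaf} + \frac{R_{surf}^{wb} T_{leaf}^2}
#'   {1 - R_{leaf} R_{surf}^{wb}},}
#' then the top-of-leaf reflectance
#' \deqn{R_{leaf}^{wb} = R_{surf} + \frac{R_{bue}^{wb}(1-R_{surf})^2}
#'   {1 - R_{surf} R_{bue}^{wb}}.}
#'
#' @param r_leaf,t_leaf Leaf-volume reflectance and transmittance
#'   (`leaf_spectrum` or numeric vectors on a common grid).
#' @param r_surf_wb Output of [surface_over_background()].
#' @param rsurf Surface reflectivity, scalar in `[0, 1)`.
#' @return Same type as `r_leaf`.
#' @export
leaf_on_background <- function(r_leaf, t_leaf, r_surf_wb, rsurf) {
  stopifnot(is.numeric(rsurf), length(rsurf) == 1, rsurf >= 0, rsurf < 1)
  spec_in <- inherits(r_leaf, "leaf_spectrum")
  val <- function(x) if (inherits(x, "leaf_spectrum")) x$value else
    as.numeric(x)
  rl <- val(r_leaf); tl <- val(t_leaf); rs <- val(r_surf_wb)
  if (length(tl) != length(rl) || length(rs) != length(rl))
    stop("inputs are not on a common grid")
  out <- .leaf_on_bg_vec(rl, tl, rs, rsurf)
  if (spec_in) spectrum(r_leaf$wavelength, out) else out
}

.leaf_on_bg_vec <- function(rl, tl, rswb, rsurf) {
  d1 <- 1 - rl * rswb
  d1[d1 <= 0] <- .Machine$double.eps
  rbue <- rl + rswb * tl^2 / d1
  rbue <- pmin(rbue, 1)
  d2 <- 1 - rsurf * rbue
  d2[d2 <= 0] <- .Machine$double.eps
  pmin(rsurf + rbue * (1 - rsurf)^2 / d2, 1)
}

#' Full system reflectance of a leaf over the white background
#'
#' Forward-simulates the measured configuration: leaf-volume radiative
#' transfer, coupling with the surface reflectivity and the background, and
#' linear mixing with the fraction `fwb` of background directly illuminated
#' beside the leaf:
#' \deqn{R(\lambda) = R_{wb}(\lambda) f_{wb} + (1 - f_{wb})
#'   R_{leaf}^{wb}(\lambda).}
#'
#' @inheritParams leaf_volume_rt
#' @param bg A [background_spectrum()] (or scalar reflectance).
#' @return A `leaf_spectrum` of system reflectance in `[0, 1]`.
#' @export
system_reflectance <- function(p, coefs, bg = background_spectrum(coefs$grid),
                               brown = p$Cbp > 0,
                               interfaces = c("internal", "none")) {
  interfaces <- match.arg(interfaces)
  .check_params_version(p, coefs, brown = brown)
  rwb <- .bg_values(bg, coefs)
  contents <- unlist(p[names(coefs$sac)])
  out <- .system_reflectance_vec(coefs, rwb, contents, p$N, p$Rsurf, p$fwb,
                                 interfaces)
  spectrum(coefs$wavelength, out)
}

.system_reflectance_vec <- function(coefs, rwb, contents, N, rsurf, fwb,
                                    interfaces = "internal") {
  k <- .absorption_vec(coefs, contents, N)
  rt <- .leaf_volume_vec(k, N, coefs, interfaces)
  rswb <- .surface_over_bg_vec(rsurf, rwb)
  rlwb <- .leaf_on_bg_vec(rt$R, rt$T, rswb, rsurf)
  fwb * rwb + (1 - fwb) * rlwb
}
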