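#' @title Specific absorption coefficient sets
#' @description A `coefficient_set` bundles, on a common working grid, the
#' refractive index of the leaf material and the per-wavelength specific
#' absorption coefficients (SAC) of the constituents a given model version
#' separates: pooled chlorophyllian pigments (`Cabc`, versions P3/P4),
#' chlorophyll a+b and carotenoids (`Cab`/`Cc`, version P5), additionally
#' anthocyanins (`Canth`, version PD), plus water (`Cw`), dry matter (`Cm`)
#' and brown pigments (`Cbp`) in every version. Pigment SACs are in
#' cm2/ug, water and dry matter in cm2/mg, brown pigments in the
#' dimensionless relative convention of leaf-model distributions.
#'
#' The coefficients shipped by [synthetic_coefficients()] are a *synthetic*
#' library: smooth parametric curves built from the qualitative spectroscopy
#' of each constituent (chlorophyll Soret and red bands, carotenoid blue
#' band, anthocyanin green band, water overtone bands near 970, 1200, 1450
#' and 1940 nm at literature magnitudes, broad dry-matter features in the
#' shortwave infrared, a decaying visible continuum for brown pigments).
#' They are not the published calibrations of any model generation; use
#' [read_coefficients()] to supply calibrated tables.
#' @name coefficient_set
NULL

.PWB_VERSIONS <- c("P3", "P4", "P5", "PD")

# pigment separation per version (Cw, Cm, Cbp are common to all)
.version_pigments <- function(version) {
  switch(version,
         P3 = "Cabc", P4 = "Cabc",
         P5 = c("Cab", "Cc"),
         PD = c("Cab", "Cc", "Canth"),
         stop("unknown model version: ", version))
}

# constituents whose SAC a version's table must provide
.version_constituents <- function(version) {
  c(.version_pigments(version), "Cw", "Cm", "Cbp")
}

.gauss <- function(wl, center, width, amp) amp * exp(-((wl - center) / width)^2)

# version-specific shape factors: the four generations differ slightly in
# band amplitude/width and refractive index, mirroring successive
# recalibrations of the same underlying spectroscopy
.version_tweaks <- list(
  P3 = list(pig = 1.06, pigw = 1.05, n0 = 0.010),
  P4 = list(pig = 1.02, pigw = 1.02, n0 = 0.002),
  P5 = list(pig = 1.00, pigw = 1.00, n0 = 0.000),
  PD = list(pig = 0.97, pigw = 0.97, n0 = -0.010)
)

#' Synthetic coefficient library
#'
#' Build the synthetic [coefficient_set] of a model version on a working
#' grid. See [coefficient_set] for what "synthetic" means here.
#'
#' @param version One of `"P3"`, `"P4"`, `"P5"`, `"PD"`.
#' @param grid A [working_grid()].
#' @return A `coefficient_set`.
#' @export
synthetic_coefficients <- function(version = "PD", grid = working_grid()) {
  version <- match.arg(version, .PWB_VERSIONS)
  wl <- grid_wavelengths(grid)
  tw <- .version_tweaks[[version]]

  n <- 1.33 + 0.16 * exp(-(wl - 400) / 900) + tw$n0

  sac_cab <- tw$pig * (.gauss(wl, 430, 35 * tw$pigw, 0.045) +
                       .gauss(wl, 668, 26 * tw$pigw, 0.070) +
                       .gauss(wl, 600, 60, 0.008))
  sac_cc <- tw$pig * (.gauss(wl, 450, 28 * tw$pigw, 0.100) +
                      .gauss(wl, 480, 26 * tw$pigw, 0.085))
  sac_canth <- .gauss(wl, 548, 30, 0.045)
  # pooled chlorophyllian pigments: chlorophyll-dominated mixture (the
  # chlorophyll-to-carotenoid content ratio in green leaves is about 5)
  sac_cabc <- (5 * sac_cab + sac_cc) / 6
  sac_cbp <- 1.8 * exp(-(wl - 400) / 160)
  sac_cw <- .gauss(wl, 970, 40, 0.00045) + .gauss(wl, 1190, 50, 0.0010) +
    .gauss(wl, 1450, 60, 0.029) + .gauss(wl, 1940, 70, 0.125) +
    .gauss(wl, 2500, 300, 0.045)
  sac_cm <- 0.0012 + .gauss(wl, 1730, 55, 0.0055) +
    .gauss(wl, 2100, 80, 0.0090) + .gauss(wl, 2310, 70, 0.0110)

  sac <- switch(version,
    P3 = ,
    P4 = list(Cabc = sac_cabc, Cw = sac_cw, Cm = sac_cm, Cbp = sac_cbp),
    P5 = list(Cab = sac_cab, Cc = sac_cc, Cw = sac_cw, Cm = sac_cm,
              Cbp = sac_cbp),
    PD = list(Cab = sac_cab, Cc = sac_cc, Canth = sac_canth, Cw = sac_cw,
              Cm = sac_cm, Cbp = sac_cbp))
  .coefficient_set(version, grid, wl, n, sac)
}

.coefficient_set <- function(version, grid, wl, n, sac) {
  if (any(n < 1) || any(n > 1.7))
    stop("refractive index outside [1.0, 1.7]")
  for (nm in names(sac)) {
    if (length(sac[[nm]]) != length(wl))
      stop("SAC table for ", nm, " does not cover the working grid")
    if (any(sac[[nm]] < 0)) stop("negative SAC values for ", nm)
  }
  missing <- setdiff(.version_constituents(version), names(sac))
  if (length(missing))
    stop("version ", version, " requires SAC tables for: ",
         paste(missing, collapse = ", "))
  # diffuse interface quantities between elementary layers, fixed per set
  t12 <- tav(90, n)
  t21 <- t12 / n^2
  jt <- t21 / (2 - t12)  # composite internal (leaf-air-leaf) interface
  structure(list(version = version, grid = grid, wavelength = wl, n = n,
                 sac = sac, t12 = t12, t21 = t21,
                 j_t = jt, j_r = 1 - jt),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> version %s, %d wavelengths (%g-%g nm)\n",
              x$version, length(x$wavelength), min(x$wavelength),
              max(x$wavelength)))
  cat("  constituents:", paste(names(x$sac), collapse = ", "), "\n")
  invisible(x)
}

#' Read a coefficient table from CSV
#'
#' The file must contain a `wavelength_nm` column, an `n` column with the
#' refractive index, and `sac_<constituent>` columns (lower-case constituent
#' names, e.g. `sac_cab`, `sac_cw`). Tables are linearly resampled onto the
#' working grid, which they must fully cover.
#'
#' @param path CSV file path.
#' @param version Model version the table belongs to.
#' @param grid A [working_grid()].
#' @return A `coefficient_set`.
#' @export
read_coefficients <- function(path, version, grid = working_grid()) {
  version <- match.arg(version, .PWB_VERSIONS)
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "n") %in% names(d)))
    stop("coefficient file must have 'wavelength_nm' and 'n' columns")
  wl_in <- d$wavelength_nm
  if (any(diff(wl_in) <= 0)) stop("wavelength column not strictly increasing")
  wl <- grid_wavelengths(grid)
  if (min(wl_in) > grid$start || max(wl_in) < grid$stop)
    stop("coefficient table does not cover the working grid")
  res <- function(v) stats::approx(wl_in, v, xout = wl, ties = "ordered")$y
  n <- res(d$n)
  saccols <- grep("^sac_", names(d), value = TRUE)
  sac <- lapply(saccols, function(cn) res(d[[cn]]))
  # sac_cab -> Cab, sac_cabc -> Cabc, sac_canth -> Canth, sac_cw -> Cw ...
  names(sac) <- sub("^sac_c", "C", saccols)
  .coefficient_set(version, grid, wl, n, sac)
}

#' @rdname read_coefficients
#' @param coefs A `coefficient_set`.
#' @export
write_coefficients <- function(coefs, path) {
  stopifnot(inherits(coefs, "coefficient_set"))
  d <- data.frame(wavelength_nm = coefs$wavelength, n = coefs$n)
  for (nm in names(coefs$sac))
    d[[paste0("sac_", tolower(nm))]] <- coefs$sac[[nm]]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
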