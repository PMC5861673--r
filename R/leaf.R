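#' Leaf model state vector
#'
#' The full parameter vector of the white-background leaf model. Which
#' fields are active depends on the model version and on whether brown
#' pigments are fitted; inactive fields are defined and must be zero.
#'
#' @param Cab Chlorophyll a+b content (ug/cm2), versions P5/PD.
#' @param Cc Carotenoid content (ug/cm2), versions P5/PD.
#' @param Cabc Pooled chlorophyllian pigment content (ug/cm2), versions
#'   P3/P4.
#' @param Canth Anthocyanin content (ug/cm2), version PD.
#' @param Cbp Brown pigment content (dimensionless), "b" variants.
#' @param Cw Water content, equivalent water thickness (mg/cm2).
#' @param Cm Dry matter content (mg/cm2).
#' @param N Mesophyll structure parameter (number of elementary layers,
#'   real-valued, `>= 1`).
#' @param Rsurf Wavelength-independent surface reflectivity, in `[0, 1)`,
#'   identical for both leaf faces.
#' @param fwb Fraction of the white background directly illuminated by the
#'   source, in `[0, 1]`.
#' @return An object of class `leaf_params`.
#' @export
leaf_params <- function(Cab = 0, Cc = 0, Cabc = 0, Canth = 0, Cbp = 0,
                        Cw = 0, Cm = 0, N = 1, Rsurf = 0, fwb = 0) {
  p <- c(Cc = Cc, Cab = Cab, Cabc = Cabc, Canth = Canth, Cm = Cm, Cw = Cw,
         Cbp = Cbp, N = N, Rsurf = Rsurf, fwb = fwb)
  if (anyNA(p) || any(!is.finite(p))) stop("non-finite leaf parameter")
  contents <- p[c("Cc", "Cab", "Cabc", "Canth", "Cm", "Cw", "Cbp")]
  if (any(contents < 0)) stop("constituent contents must be >= 0")
  if (p["N"] < 1) stop("N must be >= 1")
  if (p["Rsurf"] < 0 || p["Rsurf"] >= 1) stop("Rsurf must be in [0, 1)")
  if (p["fwb"] < 0 || p["fwb"] > 1) stop("fwb must be in [0, 1]")
  structure(as.list(p), class = "leaf_params")
}

#' @export
print.leaf_params <- function(x, ...) {
  v <- unlist(x)
  cat("<leaf_params>\n")
  print(round(v[v != 0 | names(v) %in% c("N", "Rsurf", "fwb")], 4))
  invisible(x)
}

# canonical variable order, matching the fitting table of the study design
.PWB_VARS <- c("Cc", "Cab", "Cabc", "Canth", "Cm", "Cw", "Cbp", "N",
               "Rsurf", "fwb")

#' Active (fitted) variables of a model variant
#'
#' @param version `"P3"`, `"P4"`, `"P5"` or `"PD"` (a trailing `"b"`, e.g.
#'   `"P5b"`, is accepted and sets `brown = TRUE`).
#' @param brown Logical; include the brown pigment content as a variable.
#' @return Character vector of variable names in canonical order.
#' @export
active_variables <- function(version, brown = FALSE) {
  pv <- .parse_version(version, brown)
  vars <- c(.version_pigments(pv$version), "Cw", "Cm",
            if (pv$brown) "Cbp", "N", "Rsurf", "fwb")
  .PWB_VARS[.PWB_VARS %in% vars]
}

.parse_version <- function(version, brown = FALSE) {
  version <- as.character(version)
  if (grepl("b$", version)) {
    brown <- TRUE
    version <- sub("b$", "", version)
  }
  if (!version %in% .PWB_VERSIONS)
    stop("unknown model version: ", version,
         " (expected P3, P4, P5, PD, optionally with a 'b' suffix)")
  list(version = version, brown = isTRUE(brown))
}

# check that p carries no content in a constituent the version cannot see
.check_params_version <- function(p, coefs, brown = FALSE) {
  stopifnot(inherits(p, "leaf_params"), inherits(coefs, "coefficient_set"))
  all_pig <- c("Cc", "Cab", "Cabc", "Canth")
  inactive <- setdiff(all_pig, .version_pigments(coefs$version))
  bad <- inactive[vapply(inactive, function(nm) p[[nm]] > 0, logical(1))]
  if (length(bad))
    stop("version ", coefs$version, " has no absorption table for nonzero ",
         paste(bad, collapse = ", "))
  if (!brown && p$Cbp > 0)
    stop("Cbp > 0 requires the brown-pigment variant (brown = TRUE)")
  invisible(TRUE)
}

#' Absorption coefficient of one elementary layer
#'
#' Sum of the specific absorption coefficients of the version's
#' constituents, each weighted by its content and shared equally by the `N`
#' elementary layers:
#' \deqn{k(\lambda) = \sum_i \mathrm{sac}_i(\lambda)\, C_i / N}
#'
#' @param p A [leaf_params()].
#' @param coefs A [coefficient_set].
#' @param brown Logical; allow a nonzero brown pigment content.
#' @return A `leaf_spectrum` (uncalibrated: k is an optical depth, not a
#'   fraction).
#' @export
absorption_spectrum <- function(p, coefs, brown = p$Cbp > 0) {
  .check_params_version(p, coefs, brown = brown)
  k <- .absorption_vec(coefs, unlist(p[names(coefs$sac)]), p$N)
  spectrum(coefs$wavelength, k, calibrated = FALSE)
}

.absorption_vec <- function(coefs, contents, N) {
  k <- numeric(length(coefs$wavelength))
  for (nm in names(contents)) {
    if (contents[[nm]] != 0) k <- k + coefs$sac[[nm]] * contents[[nm]]
  }
  k / N
}

#' Leaf-volume reflectance and transmittance
#'
#' Reflectance and transmittance of the stack of `N` elementary absorbing
#' layers that constitutes the leaf volume, with *no* reflectivity at its
#' external top and bottom boundaries (the measured surface reflectivity is
#' handled separately by the scalar `Rsurf` of the coupling equations). The
#' internal boundaries between consecutive elementary layers keep the
#' standard diffuse dielectric behaviour derived from the refractive index
#' (`interfaces = "internal"`); `interfaces = "none"` removes them too,
#' leaving a purely absorbing stack, and is provided for sensitivity checks.
#'
#' Non-integer `N` is supported through the closed-form Stokes expressions.
#'
#' @inheritParams absorption_spectrum
#' @param interfaces `"internal"` (default) or `"none"`.
#' @return A list with `leaf_spectrum` elements `R` and `T`;
#'   `R + T <= 1` everywhere.
#' @export
leaf_volume_rt <- function(p, coefs, brown = p$Cbp > 0,
                           interfaces = c("internal", "none")) {
  interfaces <- match.arg(interfaces)
  .check_params_version(p, coefs, brown = brown)
  k <- .absorption_vec(coefs, unlist(p[names(coefs$sac)]), p$N)
  rt <- .leaf_volume_vec(k, p$N, coefs, interfaces)
  list(R = spectrum(coefs$wavelength, rt$R),
       T = spectrum(coefs$wavelength, rt$T))
}

# vectorized core: the volume is  slab(sqrt(tau)) | [unit]^(N-1) | slab(sqrt(tau))
# where the symmetric repeat unit is  slab(sqrt(tau)) | internal interface |
# slab(sqrt(tau)); consecutive half-slabs merge multiplicatively, so for
# integer N this is exactly N full absorbing slabs separated by N-1
# leaf-air-leaf interfaces, and the Stokes power extends it continuously.
.leaf_volume_vec <- function(k, N, coefs, interfaces = "internal") {
  tau <- layer_transmission(k)
  if (interfaces == "none") {
    return(list(R = numeric(length(tau)), T = tau^N))
  }
  st <- .stokes_power(tau * coefs$j_r, tau * coefs$j_t, N - 1)
  list(R = tau * st$R, T = tau * st$T)
}
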