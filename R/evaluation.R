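#' Slope-corrected RMSE
#'
#' RMSE after removing a systematic linear deviation between estimated and
#' measured values: the estimates are regressed on the measurements
#' (`estimated = a * measured + b` by least squares), corrected as
#' `(estimated - b) / a`, and the RMSE of the corrected values against the
#' measurements is returned together with the slope `a`. With
#' `intercept = FALSE` a through-origin (slope-only) correction is applied
#' instead.
#'
#' @param measured,estimated Paired numeric vectors, `n >= 3`.
#' @param intercept Logical; fit and remove an offset as well as a slope.
#' @return A list with `rmse_corr`, `slope` and `intercept`.
#' @export
rmse_corr <- function(measured, estimated, intercept = TRUE) {
  n <- length(measured)
  if (length(estimated) != n || n < 3) stop("need paired vectors, n >= 3")
  if (stats::sd(measured) == 0)
    stop("zero variance in measured values: correction undefined")
  if (intercept) {
    fit <- stats::lm(estimated ~ measured)
    b <- stats::coef(fit)[[1]]
    a <- stats::coef(fit)[[2]]
  } else {
    a <- sum(measured * estimated) / sum(measured^2)
    b <- 0
  }
  if (!is.finite(a) || abs(a) < 1e-10)
    stop("near-zero regression slope: linear correction is not invertible")
  corrected <- (estimated - b) / a
  list(rmse_corr = sqrt(mean((corrected - measured)^2)), slope = a,
       intercept = b)
}

#' Relative RMSE after bias correction
#'
#' The slope-corrected RMSE expressed as a percentage of the mean measured
#' value.
#'
#' @param rmse_corr Slope-corrected RMSE (content units).
#' @param measured_mean Mean of the measured contents, `> 0`.
#' @return Percentage.
#' @export
rrmse <- function(rmse_corr, measured_mean) {
  stopifnot(rmse_corr >= 0)
  if (measured_mean <= 0) stop("mean measured content must be > 0")
  100 * rmse_corr / measured_mean
}

#' Agreement metrics between measured and estimated contents
#'
#' The full metric set used to evaluate trait retrieval: squared Pearson
#' correlation (`r2`), Spearman rank correlation (`spearman_rho`), RMSE,
#' slope-corrected RMSE (`rmse_corr`, see [rmse_corr()]), the regression
#' slope of estimated on measured, the bias (mean measured minus mean
#' estimated) and the relative RMSE after correction (`rrmse_pct`).
#'
#' @inheritParams rmse_corr
#' @return A one-row data.frame.
#' @export
agreement_metrics <- function(measured, estimated, intercept = TRUE) {
  n <- length(measured)
  if (length(estimated) != n || n < 3) stop("need paired vectors, n >= 3")
  if (stats::sd(measured) == 0 || stats::sd(estimated) == 0)
    stop("zero variance: correlation metrics undefined")
  rc <- rmse_corr(measured, estimated, intercept = intercept)
  data.frame(
    r2 = stats::cor(measured, estimated)^2,
    spearman_rho = stats::cor(measured, estimated, method = "spearman"),
    rmse = sqrt(mean((estimated - measured)^2)),
    rmse_corr = rc$rmse_corr,
    slope = rc$slope,
    bias = mean(measured) - mean(estimated),
    rrmse_pct = if (mean(measured) > 0)
      rrmse(rc$rmse_corr, mean(measured)) else NA_real_,
    n = n)
}

#' Spectral goodness-of-fit diagnostics
#'
#' Per-sample RMSE between measured and fitted spectra (box-plot-ready) and
#' the per-wavelength RMSE across samples, also split into the visible/NIR
#' (400--1000 nm) and SWIR (1000--2200 nm) panels used to localize model
#' deficiencies around pigment and water absorption features.
#'
#' @param measured,fitted Lists of `leaf_spectrum` objects on one common
#'   grid, paired by position.
#' @return A list with `per_sample` (numeric vector), `per_wavelength`
#'   (data.frame `wavelength_nm`, `rmse`) and `panels` (the same split at
#'   1000 nm).
#' @export
spectral_fit_diagnostics <- function(measured, fitted) {
  if (inherits(measured, "leaf_spectrum")) measured <- list(measured)
  if (inherits(fitted, "leaf_spectrum")) fitted <- list(fitted)
  if (length(measured) != length(fitted) || !length(measured))
    stop("need equal-length non-empty lists of spectra")
  wl <- measured[[1]]$wavelength
  getv <- function(s) {
    if (length(s$wavelength) != length(wl) || any(s$wavelength != wl))
      stop("spectra are not on a common grid")
    s$value
  }
  M <- do.call(rbind, lapply(measured, getv))
  Fm <- do.call(rbind, lapply(fitted, getv))
  D <- M - Fm
  per_sample <- apply(D, 1, .spectral_rmse)
  per_wl <- sqrt(colMeans(D^2))
  pw <- data.frame(wavelength_nm = wl, rmse = per_wl)
  list(per_sample = per_sample,
       per_wavelength = pw,
       panels = list(vnir = pw[wl <= 1000, ], swir = pw[wl >= 1000, ]))
}
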