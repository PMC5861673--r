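#' Vegetation index definitions
#'
#' The four indices evaluated as the empirical alternative to model
#' inversion. `Dx4` and `CIre` target the pooled chlorophyllian pigment
#' content with a linear calibration; `SRw` (linear) and `NDw` (quadratic)
#' target water content. Band ranges are read as band means, single bands
#' as nearest-grid samples. `Dx4`, defined on transmittance by its source
#' instrument, is computed here from the white-background reflectance
#' spectrum, on which it is expected to behave equivalently.
#'
#' @return A data.frame with columns `name`, `target`, `form`, `degree`.
#' @export
vi_definitions <- function() {
  data.frame(
    name = c("Dx4", "CIre", "SRw", "NDw"),
    target = c("Cabc", "Cabc", "Cw", "Cw"),
    form = c("linear", "linear", "linear", "quadratic"),
    degree = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

.vi_def <- function(name) {
  d <- vi_definitions()
  i <- match(name, d$name)
  if (is.na(i)) stop("unknown vegetation index: ", name,
                     " (expected Dx4, CIre, SRw or NDw)")
  d[i, ]
}

#' Compute a vegetation index from a spectrum
#'
#' * `Dx4  = R(850) / R(710) - 1`
#' * `CIre = mean R(760-800) / mean R(690-710) - 1`
#' * `SRw  = R(1300) / R(1450)`
#' * `NDw  = (R(1062) - R(1393)) / (R(1062) + R(1393))`
#'
#' @param s A [spectrum()] covering the index bands.
#' @param name Index name.
#' @return Scalar index value.
#' @export
compute_vi <- function(s, name) {
  stopifnot(inherits(s, "leaf_spectrum"))
  name <- .vi_def(name)$name
  div <- function(num, den) {
    if (den == 0) stop("zero denominator in ", name,
                       " (degenerate flat-zero spectrum)")
    num / den
  }
  switch(name,
    Dx4 = div(band_mean(s, 850), band_mean(s, 710)) - 1,
    CIre = div(band_mean(s, 760, 800), band_mean(s, 690, 710)) - 1,
    SRw = div(band_mean(s, 1300), band_mean(s, 1450)),
    NDw = {
      a <- band_mean(s, 1062); b <- band_mean(s, 1393)
      div(a - b, a + b)
    })
}

#' Calibrate an empirical content-index relationship
#'
#' Least-squares polynomial fit of the biochemical content on the index
#' value (content is the predicted quantity), with the degree fixed by the
#' index definition (1 for Dx4/CIre/SRw, 2 for NDw). Leave-one-out
#' statistics are attached by [loo_evaluate()].
#'
#' @param index Numeric vector of index values.
#' @param content Matched vector of destructively measured contents.
#' @param name Index name (fixes target and polynomial degree).
#' @return An object of class `vi_calibration` with the coefficients
#'   (increasing powers), full-fit RMSE and leave-one-out `r2`/`RMSE`.
#' @export
calibrate_vi <- function(index, content, name) {
  def <- .vi_def(name)
  n <- length(index)
  if (length(content) != n) stop("index and content lengths differ")
  if (n < def$degree + 2) stop("too few samples to calibrate ", name)
  if (anyNA(index) || anyNA(content) || any(!is.finite(index)))
    stop("non-finite calibration data")
  if (stats::sd(index) == 0) stop("degenerate design: all indices equal")
  fit <- stats::lm(content ~ stats::poly(index, def$degree, raw = TRUE))
  coefs <- stats::setNames(as.numeric(stats::coef(fit)),
                           paste0("a", 0:def$degree))
  loo <- if (n >= 5) loo_evaluate(index, content, name) else
    list(r2 = NA_real_, rmse = NA_real_)
  structure(list(name = def$name, target = def$target, degree = def$degree,
                 coefficients = coefs,
                 fit_rmse = sqrt(mean(stats::resid(fit)^2)),
                 loo_r2 = loo$r2, loo_rmse = loo$rmse, n = n),
            class = "vi_calibration")
}

#' @export
print.vi_calibration <- function(x, ...) {
  cat(sprintf("<vi_calibration> %s -> %s (degree %d, n = %d)\n",
              x$name, x$target, x$degree, x$n))
  cat("  coefficients:", paste(sprintf("%.4g", x$coefficients),
                               collapse = ", "), "\n")
  cat(sprintf("  fit RMSE %.4g | LOO r2 %.3f, LOO RMSE %.4g\n",
              x$fit_rmse, x$loo_r2, x$loo_rmse))
  invisible(x)
}

#' Predict content from an index value
#'
#' @param object A `vi_calibration`.
#' @param index Numeric vector of index values.
#' @param ... Unused.
#' @return Predicted contents.
#' @export
predict.vi_calibration <- function(object, index, ...) {
  powers <- outer(index, 0:object$degree, `^`)
  as.numeric(powers %*% object$coefficients)
}

#' Leave-one-out evaluation of an index calibration
#'
#' For each sample the calibration is refitted on the remaining samples and
#' used to predict the held-out content; `r2` (squared Pearson correlation)
#' and RMSE are computed over the held-out predictions.
#'
#' @inheritParams calibrate_vi
#' @return A list with `r2`, `rmse` and the vector of `predictions`.
#' @export
loo_evaluate <- function(index, content, name) {
  def <- .vi_def(name)
  n <- length(index)
  if (n < 5) stop("leave-one-out requires at least 5 samples")
  if (stats::sd(index) == 0) stop("degenerate design: all indices equal")
  pred <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(content[-i] ~ stats::poly(index[-i], def$degree,
                                               raw = TRUE))
    powers <- index[i]^(0:def$degree)
    sum(as.numeric(stats::coef(fit)) * powers)
  }, numeric(1))
  list(r2 = stats::cor(pred, content)^2,
       rmse = sqrt(mean((pred - content)^2)),
       predictions = pred)
}

#' Save or load vegetation-index calibrations
#'
#' Serialized as a small JSON text file (index name, coefficients,
#' leave-one-out statistics).
#'
#' @param calibrations A `vi_calibration` or list of them.
#' @param path JSON file path.
#' @return `read_vi_calibrations()` returns a named list of
#'   `vi_calibration` objects.
#' @export
write_vi_calibrations <- function(calibrations, path) {
  if (inherits(calibrations, "vi_calibration"))
    calibrations <- list(calibrations)
  payload <- lapply(calibrations, function(x) {
    x <- unclass(x)
    x$coefficients <- as.list(x$coefficients) # keep names through JSON
    x
  })
  names(payload) <- vapply(calibrations, `[[`, character(1), "name")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_vi_calibrations
#' @export
read_vi_calibrations <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(x) {
    x$coefficients <- unlist(x$coefficients)
    structure(x, class = "vi_calibration")
  })
}
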