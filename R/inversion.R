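#' Default fitting bounds
#'
#' Bounding limits of every model variable used by the bounded minimization,
#' in canonical order. Contents have lower bound zero; upper bounds cover
#' the full range observed on wheat leaves with a wide margin. These
#' defaults are editable: pass a modified copy to [inversion_config()].
#'
#' @return A list with numeric vectors `lower` and `upper`, named by
#'   variable.
#' @export
default_bounds <- function() {
  lower <- c(Cc = 0, Cab = 0, Cabc = 0, Canth = 0, Cm = 0, Cw = 0, Cbp = 0,
             N = 1, Rsurf = 0, fwb = 0)
  upper <- c(Cc = 80, Cab = 140, Cabc = 140, Canth = 20, Cm = 5, Cw = 30,
             Cbp = 1, N = 3.5, Rsurf = 0.5, fwb = 1)
  list(lower = lower, upper = upper)
}

#' Default initial guesses
#'
#' Three full parameter vectors spread over the bounded domain, used as
#' multi-start seeds so the local optimizer is not trapped in a single
#' basin. The final estimate is the per-variable mean of the three
#' solutions.
#'
#' @return A list of three named numeric vectors.
#' @export
default_starts <- function() {
  list(
    c(Cc = 10, Cab = 50, Cabc = 60, Canth = 5, Cm = 1, Cw = 25,
      Cbp = 0.01, N = 1.4, Rsurf = 0.05, fwb = 0.01),
    c(Cc = 5, Cab = 20, Cabc = 20, Canth = 1, Cm = 1.5, Cw = 8,
      Cbp = 0.2, N = 2, Rsurf = 0.1, fwb = 0.2),
    c(Cc = 50, Cab = 80, Cabc = 90, Canth = 10, Cm = 4, Cw = 18,
      Cbp = 0.001, N = 1.1, Rsurf = 0.01, fwb = 0.1)
  )
}

#' Inversion configuration
#'
#' @param version Model version: `"P3"`, `"P4"`, `"P5"`, `"PD"`, optionally
#'   with a `"b"` suffix (brown-pigment variant).
#' @param brown Logical; fit the brown pigment content (implied by a `"b"`
#'   suffix on `version`).
#' @param bounds As [default_bounds()].
#' @param starts As [default_starts()]; each start must lie strictly within
#'   the bounds.
#' @param grid Working grid of the fit (default 400--2200 nm at 1 nm).
#' @param tol Relative tolerance on the cost decrease (convergence).
#' @param max_iter Maximum optimizer iterations per start.
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(version = "PD", brown = FALSE,
                             bounds = default_bounds(),
                             starts = default_starts(),
                             grid = working_grid(),
                             tol = 1e-10, max_iter = 500) {
  pv <- .parse_version(version, brown)
  stopifnot(is.list(bounds), all(c("lower", "upper") %in% names(bounds)),
            length(starts) >= 1, inherits(grid, "working_grid"),
            tol > 0, max_iter >= 1)
  if (!all(.PWB_VARS %in% names(bounds$lower)) ||
      !all(.PWB_VARS %in% names(bounds$upper)))
    stop("bounds must name every model variable")
  if (any(bounds$lower[.PWB_VARS] >= bounds$upper[.PWB_VARS]))
    stop("each lower bound must be below its upper bound")
  for (s in starts) {
    if (!all(.PWB_VARS %in% names(s)))
      stop("every start must name every model variable")
    if (any(s[.PWB_VARS] < bounds$lower[.PWB_VARS]) ||
        any(s[.PWB_VARS] > bounds$upper[.PWB_VARS]))
      stop("initial guesses must lie within the bounds")
  }
  structure(list(version = pv$version, brown = pv$brown, bounds = bounds,
                 starts = starts, grid = grid, tol = tol,
                 max_iter = max_iter),
            class = "inversion_config")
}

#' @export
print.inversion_config <- function(x, ...) {
  cat(sprintf("<inversion_config> %s%s, %d starts, grid %g-%g nm step %g\n",
              x$version, if (x$brown) "b" else "", length(x$starts),
              x$grid$start, x$grid$stop, x$grid$step))
  cat("  free variables:", paste(active_variables(x$version, x$brown),
                                 collapse = ", "), "\n")
  invisible(x)
}

# root-mean-square distance with the study's normalization: the divisor is
# the number of grid intervals, i.e. 1800 on the default 1-nm 400-2200 nm
# grid (as printed, one less than the 1801 grid points; the constant does
# not change the argmin)
.spectral_rmse <- function(resid) {
  sqrt(sum(resid^2) / max(length(resid) - 1, 1))
}

#' Spectral cost of a candidate parameter vector
#'
#' Root-mean-square distance between the forward-simulated and the measured
#' white-background reflectance over the working grid:
#' \deqn{J(V) = \sqrt{\tfrac{1}{1800}\sum_{\lambda=400}^{2200}
#'   (R_{sim}(\lambda) - R_{meas}(\lambda))^2}}
#' (the divisor is the number of grid intervals of the fitting grid).
#'
#' @param p A [leaf_params()].
#' @param measured Measured `leaf_spectrum` on the coefficient grid.
#' @param coefs A [coefficient_set].
#' @param bg Background spectrum or scalar.
#' @param brown Logical.
#' @return Non-negative scalar.
#' @export
spectral_cost <- function(p, measured, coefs,
                          bg = background_spectrum(coefs$grid),
                          brown = p$Cbp > 0) {
  stopifnot(inherits(measured, "leaf_spectrum"))
  if (length(measured$wavelength) != length(coefs$wavelength) ||
      any(measured$wavelength != coefs$wavelength))
    stop("measured spectrum is not on the coefficient grid")
  sim <- system_reflectance(p, coefs, bg, brown = brown)
  .spectral_rmse(sim$value - measured$value)
}

.params_from_theta <- function(theta, active) {
  full <- stats::setNames(rep(0, length(.PWB_VARS)), .PWB_VARS)
  full["N"] <- 1
  full[active] <- theta
  do.call(leaf_params, as.list(full))
}

#' Invert one measured spectrum
#'
#' Bounded multi-start least-squares estimation of the active model
#' variables from a measured white-background reflectance spectrum. The
#' variables are mapped to unbounded coordinates by a logistic (interior)
#' transform of their bounds, so iterates remain strictly inside the box
#' and cannot stall on a bound, and each configured initial guess is
#' refined by Levenberg-Marquardt descent on the spectral residual vector.
#' The reported estimate is the per-variable arithmetic mean of the
#' per-start solutions that reached the consensus (best) minimum --
#' averaging is meant to smooth numerically equivalent solutions, not to
#' mix distinct local minima; starts whose final cost exceeds the best by
#' more than 5\% (plus a 1e-6 floor) are excluded and flagged. The spread
#' across all successful starts is reported as a stability diagnostic.
#' Deterministic given the configuration.
#'
#' @param measured Measured `leaf_spectrum` on the configuration grid.
#' @param config An [inversion_config()].
#' @param coefs A [coefficient_set] matching `config$version`.
#' @param bg Background spectrum or scalar.
#' @return An object of class `inversion_result` with elements `per_start`
#'   (params, cost and convergence per start), `estimate` (a
#'   [leaf_params()]), `fit_rmse` (cost at the estimate) and `spread`
#'   (per-variable max minus min across starts).
#' @export
invert_spectrum <- function(measured, config, coefs,
                            bg = background_spectrum(config$grid)) {
  stopifnot(inherits(config, "inversion_config"),
            inherits(coefs, "coefficient_set"),
            inherits(measured, "leaf_spectrum"))
  if (coefs$version != config$version)
    stop("coefficient set is for version ", coefs$version,
         ", configuration asks for ", config$version)
  wl <- grid_wavelengths(config$grid)
  if (length(measured$wavelength) != length(wl) ||
      any(measured$wavelength != wl))
    measured <- resample_to_grid(measured, config$grid)
  if (length(coefs$wavelength) != length(wl) || any(coefs$wavelength != wl))
    stop("coefficient set is not on the configuration grid")

  active <- active_variables(config$version, config$brown)
  lower <- config$bounds$lower[active]
  upper <- config$bounds$upper[active]
  rwb <- .bg_values(bg, coefs)
  meas <- measured$value
  constituents <- names(coefs$sac)

  residfun <- function(theta) {
    contents <- stats::setNames(rep(0, length(constituents)), constituents)
    shared <- intersect(constituents, names(theta))
    contents[shared] <- theta[shared]
    .system_reflectance_vec(coefs, rwb, contents, theta[["N"]],
                            theta[["Rsurf"]], theta[["fwb"]]) - meas
  }
  # interior (logistic) change of variables over the bounded box
  to_x <- function(theta) stats::qlogis(
    pmin(pmax((theta - lower) / (upper - lower), 1e-8), 1 - 1e-8))
  to_theta <- function(x) stats::setNames(
    lower + (upper - lower) * stats::plogis(x), active)
  residfun_x <- function(x) residfun(to_theta(x))

  per_start <- vector("list", length(config$starts))
  for (i in seq_along(config$starts)) {
    start <- config$starts[[i]][active]
    fit <- try(minpack.lm::nls.lm(
      par = to_x(start), fn = residfun_x,
      control = minpack.lm::nls.lm.control(
        maxiter = min(config$max_iter, 1024), ftol = config$tol,
        ptol = config$tol, gtol = 0)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      per_start[[i]] <- list(params = NULL, theta = NULL, cost = NA_real_,
                             converged = FALSE, consensus = FALSE,
                             message = attr(fit, "condition")$message)
      next
    }
    theta <- to_theta(unlist(fit$par))
    per_start[[i]] <- list(params = .params_from_theta(theta, active),
                           theta = theta,
                           cost = .spectral_rmse(fit$fvec),
                           converged = fit$info %in% 1:4,
                           consensus = NA, # filled below
                           message = fit$message)
  }
  ok <- !vapply(per_start, function(s) is.null(s$theta), logical(1))
  if (!any(ok)) stop("all optimization starts failed")

  costs <- vapply(per_start[ok], `[[`, numeric(1), "cost")
  best <- min(costs)
  keep <- costs <= best * 1.05 + 1e-6
  j <- 0
  for (i in seq_along(per_start)) {
    if (ok[i]) { j <- j + 1; per_start[[i]]$consensus <- keep[j] }
  }
  thetas <- do.call(rbind, lapply(per_start[ok], `[[`, "theta"))
  est_theta <- colMeans(thetas[keep, , drop = FALSE])
  estimate <- .params_from_theta(est_theta, active)
  spread <- apply(thetas, 2, function(v) max(v) - min(v))
  fit_rmse <- .spectral_rmse(residfun(est_theta))

  structure(list(per_start = per_start, estimate = estimate,
                 fit_rmse = fit_rmse,
                 spread = stats::setNames(spread, active),
                 n_consensus = sum(keep),
                 active = active, version = config$version,
                 brown = config$brown),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> %s%s, fit RMSE %.5f\n", x$version,
              if (x$brown) "b" else "", x$fit_rmse))
  est <- unlist(x$estimate)[x$active]
  print(round(rbind(estimate = est, spread = x$spread[x$active]), 4))
  invisible(x)
}

#' Invert a list of leaf samples
#'
#' Batch driver: one [invert_spectrum()] call per sample, order preserved.
#' Per-sample failures are collected and reported with a warning instead of
#' aborting the batch.
#'
#' @param samples List of `leaf_sample` objects (see [read_leaf_dataset()]).
#' @param config An [inversion_config()].
#' @param coefs A [coefficient_set].
#' @param bg Background spectrum or scalar.
#' @param progress Print one line per sample.
#' @return An object of class `inversion_set`: list with `results` (named
#'   list of `inversion_result`), `failures` (named character vector of
#'   error messages) and the configuration. Use `as.data.frame()` for a
#'   tidy table.
#' @export
invert_dataset <- function(samples, config, coefs,
                           bg = background_spectrum(config$grid),
                           progress = FALSE) {
  stopifnot(is.list(samples))
  results <- list()
  failures <- character()
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    id <- if (!is.null(smp$leaf_id)) as.character(smp$leaf_id) else
      as.character(i)
    res <- tryCatch(invert_spectrum(smp$spectrum, config, coefs, bg),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[id] <- res
    } else {
      results[[id]] <- res
    }
    if (progress)
      message(sprintf("[%d/%d] %s: %s", i, length(samples), id,
                      if (is.character(res)) "FAILED" else
                        sprintf("RMSE %.5f", res$fit_rmse)))
  }
  if (length(failures))
    warning(length(failures), " of ", length(samples),
            " inversions failed and were excluded")
  structure(list(results = results, failures = failures,
                 version = config$version, brown = config$brown),
            class = "inversion_set")
}

#' @export
as.data.frame.inversion_set <- function(x, ...) {
  if (!length(x$results)) return(data.frame())
  rows <- lapply(names(x$results), function(id) {
    r <- x$results[[id]]
    est <- unlist(r$estimate)
    data.frame(leaf_id = id, version = paste0(x$version,
                                              if (x$brown) "b" else ""),
               t(est), fit_rmse = r$fit_rmse,
               converged = all(vapply(r$per_start, function(s)
                 isTRUE(s$converged), logical(1))),
               row.names = NULL, check.names = FALSE)
  })
  do.call(rbind, rows)
}
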