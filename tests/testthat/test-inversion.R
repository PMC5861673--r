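# Cost function and bounded multi-start inversion (coarse grids for speed;
# the acceptance suite exercises the full 1-nm grid).

test_that("spectral cost has the printed normalization", {
  co <- synthetic_coefficients("P3")
  bg <- background_spectrum()
  p <- leaf_params(Cabc = 40, Cw = 10, Cm = 3, N = 1.5, Rsurf = 0.05,
                   fwb = 0.02)
  sim <- system_reflectance(p, co, bg)
  expect_equal(spectral_cost(p, sim, co, bg), 0)

  # constant offset delta at all 1801 points -> sqrt(1801/1800) * delta
  delta <- 0.01
  shifted <- spectrum(sim$wavelength, sim$value - delta)
  expect_equal(spectral_cost(p, shifted, co, bg),
               sqrt(1801 / 1800) * delta, tolerance = 1e-12)

  # random perturbation: direct re-evaluation of the RMS formula
  set.seed(5)
  eps <- rnorm(1801, 0, 0.003)
  pert <- spectrum(sim$wavelength, pmin(pmax(sim$value + eps, 0), 1))
  expect_equal(spectral_cost(p, pert, co, bg),
               sqrt(sum((sim$value - pert$value)^2) / 1800),
               tolerance = 1e-14)
})

test_that("configuration validates bounds, starts and version dispatch", {
  expect_s3_class(inversion_config("P5b"), "inversion_config")
  expect_true(inversion_config("P5b")$brown)
  expect_error(inversion_config("P9"), "unknown model version")
  b <- default_bounds()
  b$lower["Cw"] <- 40
  expect_error(inversion_config("P3", bounds = b), "lower bound")
  s <- default_starts()
  s[[2]]["Cw"] <- 99
  expect_error(inversion_config("P3", starts = s), "within the bounds")
  expect_equal(active_variables("P3"),
               c("Cabc", "Cm", "Cw", "N", "Rsurf", "fwb"))
  expect_equal(active_variables("PDb"),
               c("Cc", "Cab", "Canth", "Cm", "Cw", "Cbp", "N", "Rsurf",
                 "fwb"))
})

test_that("noiseless spectra are recovered on a coarse grid", {
  g <- coarse_grid(10)
  co <- synthetic_coefficients("P3", g)
  bg <- background_spectrum(g)
  cfg <- inversion_config("P3", grid = g)
  truth <- leaf_params(Cabc = 55, Cw = 12, Cm = 4, N = 1.6, Rsurf = 0.05,
                       fwb = 0.05)
  meas <- system_reflectance(truth, co, bg)
  res <- invert_spectrum(meas, cfg, co, bg)
  est <- unlist(res$estimate)
  expect_lt(abs(est["Cabc"] / 55 - 1), 0.01)
  expect_lt(abs(est["Cw"] / 12 - 1), 0.01)
  expect_lt(abs(est["Cm"] / 4 - 1), 0.10)
  expect_lt(abs(est["N"] / 1.6 - 1), 0.10)
  expect_lt(res$fit_rmse, 1e-6)
  # estimates inside the bounds
  act <- res$active
  expect_true(all(est[act] >= cfg$bounds$lower[act] &
                    est[act] <= cfg$bounds$upper[act]))
  # descent: each converged start improved on its initial guess
  for (i in seq_along(cfg$starts)) {
    s <- res$per_start[[i]]
    start_cost <- spectral_cost(
      do.call(leaf_params, as.list(replace(
        stats::setNames(rep(0, 10), names(cfg$starts[[i]])),
        res$active, cfg$starts[[i]][res$active]))),
      meas, co, bg)
    expect_lte(s$cost, start_cost + 1e-12)
  }
})

test_that("a pure-background measurement drives fwb to one", {
  g <- coarse_grid(10)
  co <- synthetic_coefficients("P3", g)
  bg <- background_spectrum(g)
  cfg <- inversion_config("P3", grid = g)
  truth <- leaf_params(Cabc = 40, Cw = 10, Cm = 3, N = 1.5, fwb = 1)
  meas <- system_reflectance(truth, co, bg)
  res <- invert_spectrum(meas, cfg, co, bg)
  expect_gte(unlist(res$estimate)["fwb"], 0.95)
})

test_that("the estimate is invariant to the order of the starts", {
  g <- coarse_grid(20)
  co <- synthetic_coefficients("P4", g)
  bg <- background_spectrum(g)
  truth <- leaf_params(Cabc = 30, Cw = 8, Cm = 2, N = 1.4, Rsurf = 0.03,
                       fwb = 0.1)
  meas <- system_reflectance(truth, co, bg)
  cfg1 <- inversion_config("P4", grid = g)
  cfg2 <- inversion_config("P4", grid = g, starts = rev(default_starts()))
  e1 <- unlist(invert_spectrum(meas, cfg1, co, bg)$estimate)
  e2 <- unlist(invert_spectrum(meas, cfg2, co, bg)$estimate)
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("batch inversion preserves order and collects failures", {
  g <- coarse_grid(20)
  co <- synthetic_coefficients("P3", g)
  bg <- background_spectrum(g)
  cfg <- inversion_config("P3", grid = g)
  expect_length(invert_dataset(list(), cfg, co, bg)$results, 0)

  spec <- simulation_spec(6, version = "P3", noise_sigma = 0, seed = 3)
  ds <- generate_dataset(spec, synthetic_coefficients("P3", g),
                         background_spectrum(g))
  # corrupt two spectra so their inversion cannot even start
  ds$samples[[2]]$spectrum <- spectrum(c(500, 600), c(0.5, 0.5))
  ds$samples[[5]]$spectrum <- spectrum(c(500, 600), c(0.5, 0.5))
  expect_warning(inv <- invert_dataset(ds$samples, cfg, co, bg),
                 "2 of 6")
  expect_length(inv$results, 4)
  expect_length(inv$failures, 2)
  expect_named(inv$failures, c("synth_002", "synth_005"))
  df <- as.data.frame(inv)
  expect_equal(nrow(df), 4)
  expect_true(all(c("leaf_id", "Cabc", "fit_rmse", "converged") %in%
                    names(df)))
  # singleton batch consistent with the single-spectrum path
  single <- invert_spectrum(ds$samples[[1]]$spectrum, cfg, co, bg)
  expect_equal(unlist(inv$results[["synth_001"]]$estimate),
               unlist(single$estimate))
})
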