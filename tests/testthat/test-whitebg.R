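# Coupling of surface, leaf volume and white background.

test_that("surface-over-background reduces correctly in its limits", {
  g <- coarse_grid()
  wl <- grid_wavelengths(g)
  rwb <- spectrum(wl, rep(0.99, length(wl)))
  expect_equal(surface_over_background(0, rwb)$value, rwb$value)
  expect_equal(surface_over_background(0.07, rep(0, 5)), rep(0.07, 5))
})

test_that("surface-over-background equals the multiple-bounce series", {
  rsurf <- 0.05
  rwb <- 0.99
  # surface reflect + background bounces trapped under the surface
  kterms <- 0:200
  series <- rsurf + (1 - rsurf)^2 * rwb * sum((rsurf * rwb)^kterms)
  expect_equal(surface_over_background(rsurf, rwb), series,
               tolerance = 1e-12)
})

test_that("leaf-on-background composition reduces correctly in its limits", {
  n <- 5
  rl <- rep(0.4, n); tl <- rep(0, n) # opaque leaf: background invisible
  expect_equal(leaf_on_background(rl, tl, rep(0.99, n), 0), rl)
  # transparent volume, no surface: see the backed surface alone
  expect_equal(leaf_on_background(rep(0, n), rep(1, n), rep(0.87, n), 0),
               rep(0.87, n))
})

test_that("coupling equations match a 4-layer adding-doubling oracle", {
  co <- coarse_coefs("PD")
  p <- leaf_params(Cab = 35, Cc = 7, Cw = 9, Cm = 3, N = 1.8,
                   Rsurf = 0.06, fwb = 0)
  rwb <- rep(0.97, length(co$wavelength))
  rt <- leaf_volume_rt(p, co)
  # oracle: surface / volume / surface / background, raw pairwise adding
  surf <- sym_layer(rep(0.06, length(rwb)), rep(1 - 0.06, length(rwb)))
  vol <- sym_layer(rt$R$value, rt$T$value)
  bgl <- list(Rf = rwb, Tf = 0 * rwb, Rb = 0 * rwb, Tb = 0 * rwb)
  oracle <- add_layers(surf, add_layers(vol, add_layers(surf, bgl)))$Rf

  rswb <- surface_over_background(0.06, rwb)
  got <- leaf_on_background(rt$R$value, rt$T$value, rswb, 0.06)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("system reflectance mixes linearly with the illuminated fraction", {
  co <- coarse_coefs("P3")
  bg <- background_spectrum(co$grid, 0.99)
  base <- list(Cabc = 45, Cw = 11, Cm = 3.5, N = 1.5, Rsurf = 0.04)
  at_fwb <- function(f) system_reflectance(
    do.call(leaf_params, c(base, fwb = f)), co, bg)$value
  r0 <- at_fwb(0)
  r1 <- at_fwb(1)
  rhalf <- at_fwb(0.5)
  expect_equal(r1, bg$value) # leaf absent from the beam
  expect_equal(rhalf, (r0 + r1) / 2, tolerance = 1e-12)

  # fwb = 0 equals the explicit coupling chain
  rt <- leaf_volume_rt(do.call(leaf_params, c(base, fwb = 0)), co)
  rswb <- surface_over_background(0.04, bg$value)
  expect_equal(r0, leaf_on_background(rt$R$value, rt$T$value, rswb, 0.04))
})

test_that("system reflectance responds to absorbers in their bands", {
  co <- coarse_coefs("P3", step = 10)
  bg <- background_spectrum(co$grid, 0.99)
  r_of <- function(...) system_reflectance(leaf_params(...), co, bg)
  base <- r_of(Cabc = 30, Cw = 8, Cm = 3, N = 1.5, fwb = 0.02)
  more_w <- r_of(Cabc = 30, Cw = 16, Cm = 3, N = 1.5, fwb = 0.02)
  more_p <- r_of(Cabc = 60, Cw = 8, Cm = 3, N = 1.5, fwb = 0.02)
  expect_lt(band_mean(more_w, 1450), band_mean(base, 1450))
  expect_lt(band_mean(more_w, 1900), band_mean(base, 1900))
  expect_lt(band_mean(more_p, 670), band_mean(base, 670))
  # all outputs stay within [0, 1]
  expect_true(all(base$value >= 0 & base$value <= 1))
})

test_that("the white background amplifies water sensitivity at 1150 nm", {
  co <- coarse_coefs("P4", step = 10)
  p1 <- leaf_params(Cabc = 30, Cw = 8, Cm = 2, N = 1.5)
  p2 <- leaf_params(Cabc = 30, Cw = 9, Cm = 2, N = 1.5)
  # sensitivity of the white-background system reflectance ...
  s_sys <- abs(band_mean(system_reflectance(p2, co, 0.99), 1150) -
               band_mean(system_reflectance(p1, co, 0.99), 1150))
  # ... versus the bare leaf-volume reflectance
  s_vol <- abs(band_mean(leaf_volume_rt(p2, co)$R, 1150) -
               band_mean(leaf_volume_rt(p1, co)$R, 1150))
  expect_gt(s_sys, s_vol)
})

test_that("background spectrum validates its range", {
  expect_error(background_spectrum(coarse_grid(), 0), "\\(0, 1\\]")
  g <- coarse_grid()
  wl <- grid_wavelengths(g)
  bg <- background_spectrum(g, spectrum(seq(350, 2500, 10),
                                        rep(0.95, 216)))
  expect_equal(bg$value, rep(0.95, length(wl)))
})
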