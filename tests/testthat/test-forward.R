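# Leaf-volume forward model.

test_that("absorption spectrum is the content-weighted SAC sum per layer", {
  co <- coarse_coefs("P4")
  p0 <- leaf_params(N = 1.5)
  expect_true(all(absorption_spectrum(p0, co)$value == 0))

  p1 <- leaf_params(Cabc = 30, Cw = 10, Cm = 2, N = 2)
  p2 <- leaf_params(Cabc = 60, Cw = 20, Cm = 4, N = 2)
  k1 <- absorption_spectrum(p1, co)$value
  k2 <- absorption_spectrum(p2, co)$value
  expect_equal(k2, 2 * k1) # linear in contents at fixed N

  # single constituent: direct table lookup
  pw <- leaf_params(Cw = 10, N = 2)
  kw <- absorption_spectrum(pw, co)
  i <- which(co$wavelength == 1460)
  expect_equal(kw$value[i], co$sac$Cw[i] * 10 / 2)

  # version dispatch: pooled versions reject split pigments and vice versa
  expect_error(absorption_spectrum(leaf_params(Cab = 30, N = 1.5), co),
               "no absorption table")
  co5 <- coarse_coefs("P5")
  expect_error(absorption_spectrum(leaf_params(Cabc = 30, N = 1.5), co5),
               "no absorption table")
  expect_error(absorption_spectrum(leaf_params(Cbp = 0.3, N = 1.5), co,
                                   brown = FALSE), "brown")
})

test_that("leaf volume has transparent external boundaries", {
  co <- coarse_coefs("PD")
  # no absorption, single layer: nothing reflects, everything passes
  rt <- leaf_volume_rt(leaf_params(N = 1), co)
  expect_equal(rt$R$value, rep(0, length(co$wavelength)))
  expect_equal(rt$T$value, rep(1, length(co$wavelength)))

  # water absorption strictly reduces transmission at its 1450 nm band
  t_at_1450 <- vapply(c(2, 6, 12, 20), function(cw) {
    rt <- leaf_volume_rt(leaf_params(Cw = cw, N = 1.6), co)
    band_mean(rt$T, 1460)
  }, numeric(1))
  expect_true(all(diff(t_at_1450) < 0))
})

test_that("leaf volume matches explicit slab/interface adding composition", {
  co <- coarse_coefs("PD")
  p <- leaf_params(Cab = 40, Cc = 8, Cw = 12, Cm = 4, N = 3,
                   Rsurf = 0, fwb = 0)
  k <- absorption_spectrum(p, co)$value
  tau <- layer_transmission(k)
  # independent oracle: slab | (leaf-air-leaf interface | slab) x (N-1),
  # built from raw asymmetric layer adding
  slab <- list(Rf = 0 * tau, Tf = tau, Rb = 0 * tau, Tb = tau)
  J <- add_layers(iface_up(co$n), iface_down(co$n))
  stack <- slab
  for (i in 1:2) stack <- add_layers(stack, add_layers(J, slab))
  rt <- leaf_volume_rt(p, co)
  expect_equal(rt$R$value, stack$Rf, tolerance = 1e-10)
  expect_equal(rt$T$value, stack$Tf, tolerance = 1e-10)
})

test_that("leaf volume is continuous in N across integer values", {
  co <- coarse_coefs("P3")
  base <- leaf_params(Cabc = 50, Cw = 10, Cm = 3)
  for (N in c(1.3, 2, 2.7, 3)) {
    lo <- leaf_volume_rt(leaf_params(Cabc = 50, Cw = 10, Cm = 3,
                                     N = N - 1e-6), co)
    hi <- leaf_volume_rt(leaf_params(Cabc = 50, Cw = 10, Cm = 3,
                                     N = N + 1e-6), co)
    expect_equal(lo$R$value, hi$R$value, tolerance = 1e-4)
    expect_equal(lo$T$value, hi$T$value, tolerance = 1e-4)
  }
})

test_that("energy is conserved and absorption is monotone in contents", {
  set.seed(101)
  for (version in c("P3", "P4", "P5", "PD")) {
    co <- coarse_coefs(version)
    for (p in random_params(version, brown = TRUE, n = 25)) {
      rt <- leaf_volume_rt(p, co, brown = TRUE)
      expect_true(all(rt$R$value >= 0 & rt$R$value <= 1))
      expect_true(all(rt$T$value >= 0 & rt$T$value <= 1))
      expect_true(all(rt$R$value + rt$T$value <= 1 + 1e-12))
      # bump each content: absorption may only grow, at every wavelength
      A <- 1 - rt$R$value - rt$T$value
      for (v in setdiff(active_variables(version, TRUE),
                        c("N", "Rsurf", "fwb"))) {
        pb <- unclass(p)
        pb[[v]] <- pb[[v]] * 1.1 + 0.1
        rtb <- leaf_volume_rt(do.call(leaf_params, pb), co, brown = TRUE)
        expect_true(all(1 - rtb$R$value - rtb$T$value >= A - 1e-10))
      }
    }
  }
})

test_that("pooled and split pigment versions both run and conserve energy", {
  co4 <- coarse_coefs("P4")
  co5 <- coarse_coefs("P5")
  p4 <- leaf_params(Cabc = 48, Cw = 10, Cm = 3, N = 1.5)
  p5 <- leaf_params(Cab = 40, Cc = 8, Cw = 10, Cm = 3, N = 1.5)
  rt4 <- leaf_volume_rt(p4, co4)
  rt5 <- leaf_volume_rt(p5, co5)
  expect_true(all(rt4$R$value + rt4$T$value <= 1 + 1e-12))
  expect_true(all(rt5$R$value + rt5$T$value <= 1 + 1e-12))
  # different SAC tables: similar but not identical spectra
  expect_false(isTRUE(all.equal(rt4$R$value, rt5$R$value)))
})

test_that("interface-free stack variant reduces to pure absorption", {
  co <- coarse_coefs("P3")
  p <- leaf_params(Cabc = 30, Cw = 8, Cm = 2, N = 2.2)
  rt <- leaf_volume_rt(p, co, interfaces = "none")
  k <- absorption_spectrum(p, co)$value
  expect_equal(rt$R$value, rep(0, length(k)))
  expect_equal(rt$T$value, layer_transmission(k)^2.2)
})

test_that("coefficient tables validate and round-trip through CSV", {
  co <- coarse_coefs("P5")
  path <- withr::local_tempfile(fileext = ".csv")
  write_coefficients(co, path)
  back <- read_coefficients(path, "P5", coarse_grid())
  expect_equal(back$n, co$n)
  expect_equal(back$sac, co$sac)
  expect_error(read_coefficients(path, "PD", coarse_grid()),
               "requires SAC tables")
  for (v in c("P3", "P4", "P5", "PD")) {
    cv <- coarse_coefs(v)
    expect_true(all(cv$n >= 1 & cv$n <= 1.7))
    expect_true(all(unlist(cv$sac) >= 0))
  }
})
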