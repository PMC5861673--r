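# Shared fixtures and independent numerical oracles. Everything is built in
# code; unit tests mostly run on coarse grids for speed, the acceptance
# suite uses the full 1-nm fitting grid.

coarse_grid <- function(step = 20) working_grid(400, 2200, step)

coarse_coefs <- function(version = "PD", step = 20)
  synthetic_coefficients(version, coarse_grid(step))

# --- generic incoherent adding of two layers (front/back resolved) -------
# A and B are lists with Rf, Tf, Rb, Tb (vectors); A sits on top of B.
add_layers <- function(A, B) {
  d <- 1 - A$Rb * B$Rf
  list(Rf = A$Rf + A$Tf * B$Rf * A$Tb / d,
       Tf = A$Tf * B$Tf / d,
       Rb = B$Rb + B$Tb * A$Rb * B$Tf / d,
       Tb = B$Tb * A$Tb / d)
}

sym_layer <- function(R, T) list(Rf = R, Tf = T, Rb = R, Tb = T)

# diffuse dielectric interface crossed from air into the medium
iface_down <- function(n) {
  t12 <- tav(90, n)
  t21 <- t12 / n^2
  list(Rf = 1 - t12, Tf = t12, Rb = 1 - t21, Tb = t21)
}

# the same interface crossed from the medium into air
iface_up <- function(n) {
  d <- iface_down(n)
  list(Rf = d$Rb, Tf = d$Tb, Rb = d$Rf, Tb = d$Tf)
}

# --- independent oracles -------------------------------------------------

# transmission of isotropic flux through an absorbing slab, by quadrature
tau_quadrature <- function(k) {
  vapply(k, function(ki) {
    if (ki == 0) return(1)
    stats::integrate(function(th) exp(-ki / cos(th)) * 2 * sin(th) * cos(th),
                     0, pi / 2, rel.tol = 1e-12)$value
  }, numeric(1))
}

# average Fresnel transmissivity over the incidence hemisphere, by quadrature
tav90_quadrature <- function(n) {
  fres <- function(th) {
    st <- sin(th); ct <- cos(th)
    ctt <- sqrt(1 - (st / n)^2)
    rs <- ((ct - n * ctt) / (ct + n * ctt))^2
    rp <- ((n * ct - ctt) / (n * ct + ctt))^2
    1 - (rs + rp) / 2
  }
  stats::integrate(function(th) fres(th) * 2 * sin(th) * cos(th),
                   0, pi / 2, rel.tol = 1e-12)$value
}

# truncated bounce-series summation for one absorbing plate
plate_series <- function(tau, n, t_in, t_out, terms = 1e4) {
  t1i <- if (t_in >= 1) 1 else t_in / n^2
  t2i <- if (t_out >= 1) 1 else t_out / n^2
  g <- (1 - t1i) * (1 - t2i) * tau^2
  s <- sum(g^(0:terms))
  list(R = (1 - t_in) + t_in * t1i * (1 - t2i) * tau^2 * s,
       T = t_in * tau * t2i * s)
}

# iterated pairwise doubling of m identical symmetric layers
doubling_stack <- function(R, T, m) {
  Rm <- R; Tm <- T
  if (m >= 2) for (i in 2:m) {
    d <- 1 - Rm * R
    Tn <- Tm * T / d
    Rm <- R + T^2 * Rm / d
    Tm <- Tn
  }
  list(R = Rm, T = Tm)
}

# quick forward simulation of one leaf (returns plain vector)
simulate_system <- function(p, coefs, rwb = 0.99) {
  system_reflectance(p, coefs, bg = rwb)$value
}

random_params <- function(version = "PD", brown = FALSE, n = 1) {
  active <- active_variables(version, brown)
  b <- default_bounds()
  lapply(seq_len(n), function(i) {
    draw <- stats::setNames(
      stats::runif(length(active), b$lower[active], b$upper[active]),
      active)
    do.call(leaf_params, as.list(draw))
  })
}
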