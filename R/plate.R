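#' Average transmissivity of a dielectric interface
#'
#' Closed-form average Fresnel transmissivity of a plane dielectric boundary
#' for unpolarized light incident from all directions within a cone of
#' half-angle `theta` (degrees). `theta = 90` gives the diffuse (isotropic)
#' transmissivity used for the interfaces between elementary leaf layers.
#' The expression is the standard closed form of the plate-model literature;
#' the test suite checks it against direct numerical integration of the
#' Fresnel coefficients over the incidence hemisphere.
#'
#' @param theta Cone half-angle in degrees, in (0, 90].
#' @param n Refractive index (scalar or vector), `n >= 1`.
#' @return Transmissivity in (0, 1], vectorized over `n`.
#' @export
tav <- function(theta, n) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta > 0, theta <= 90,
            is.numeric(n), all(n >= 1))
  # n == 1: no interface
  out <- rep(1, length(n))
  idx <- n > 1
  if (!any(idx)) return(out)
  n <- n[idx]
  thetar <- theta * pi / 180
  n2 <- n^2
  np <- n2 + 1
  nm <- n2 - 1
  a <- (n + 1)^2 / 2
  k <- -nm^2 / 4
  sa <- sin(thetar)^2
  b1 <- if (theta == 90) 0 else sqrt((sa - np / 2)^2 + k)
  b2 <- sa - np / 2
  b <- b1 - b2
  ts <- (k^2 / (6 * b^3) + k / b - b / 2) -
        (k^2 / (6 * a^3) + k / a - a / 2)
  tp1 <- -2 * n2 * (b - a) / np^2
  tp2 <- -2 * n2 * np * log(b / a) / nm^2
  tp3 <- n2 * (1 / b - 1 / a) / 2
  tp4 <- 16 * n2^2 * (n2^2 + 1) *
    log((2 * np * b - nm^2) / (2 * np * a - nm^2)) / (np^3 * nm^2)
  tp5 <- 16 * n2^3 *
    (1 / (2 * np * b - nm^2) - 1 / (2 * np * a - nm^2)) / np^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5
  out[idx] <- (ts + tp) / (2 * sa)
  out
}

#' Transmission of an elementary absorbing layer for isotropic flux
#'
#' Fraction of perfectly diffuse incident flux transmitted through a slab of
#' optical depth `k` (normal incidence), integrating the path lengthening
#' over all incidence angles:
#' \deqn{\tau(k) = (1-k)e^{-k} + k^2 E_1(k)}
#' with \eqn{E_1} the exponential integral. \eqn{\tau(0)=1}, strictly
#' decreasing, \eqn{\tau \to 0} as \eqn{k \to \infty}.
#'
#' @param k Non-negative absorption optical depth (vectorized).
#' @return \eqn{\tau(k)} in (0, 1].
#' @export
layer_transmission <- function(k) {
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0")
  tau <- numeric(length(k))
  z <- k == 0
  tau[z] <- 1
  big <- !z & k > 700   # below double-precision underflow of exp(-k)
  tau[big] <- 0
  mid <- !z & !big
  if (any(mid)) {
    km <- k[mid]
    tau[mid] <- (1 - km) * exp(-km) + km^2 * pracma::expint(km)
  }
  pmin(pmax(tau, 0), 1)
}

# internal-side transmissivity of an interface given its air-side
# transmissivity; t = 1 encodes "no interface" (fully transparent both ways)
.t_inside <- function(t_air, n) {
  ifelse(t_air >= 1, 1, t_air / n^2)
}

#' Reflectance and transmittance of a single absorbing plate
#'
#' Closed-form sum of all internal bounces inside one absorbing layer
#' bounded above and below by (possibly different) interfaces. Interface
#' transmissivities are given for the air side; the leaf-side values follow
#' the standard \eqn{t_{21} = t_{12}/n^2} relation. A transmissivity of 1
#' denotes an absent (fully transparent) interface.
#'
#' @param tau Layer transmission for diffuse flux, in \[0, 1\] (vectorized).
#' @param n Refractive index of the layer material (scalar or vector).
#' @param t_in Air-side transmissivity of the top interface.
#' @param t_out Air-side transmissivity of the bottom interface.
#' @return A list with vectors `R` and `T`; `R + T <= 1` with equality iff
#'   `tau = 1`.
#' @export
plate_rt <- function(tau, n, t_in, t_out) {
  stopifnot(all(tau >= 0 & tau <= 1), all(n >= 1),
            all(t_in >= 0 & t_in <= 1), all(t_out >= 0 & t_out <= 1))
  t1i <- .t_inside(t_in, n)   # top interface, leaf side
  t2i <- .t_inside(t_out, n)  # bottom interface, leaf side
  r1i <- 1 - t1i
  r2i <- 1 - t2i
  denom <- 1 - r1i * r2i * tau^2
  # denom >= 1 - tau^2 > 0 for tau < 1 and equals 1 - r1i*r2i >= 0 at tau = 1;
  # the fully mirrored degenerate case is excluded by t in [0,1], n >= 1
  denom[denom <= 0] <- .Machine$double.eps
  T1 <- t_in * tau * t2i / denom
  R1 <- (1 - t_in) + t_in * t1i * r2i * tau^2 / denom
  list(R = pmin(pmax(R1, 0), 1), T = pmin(pmax(T1, 0), 1))
}

#' Stokes extension of one layer to a stack of N identical layers
#'
#' Closed-form solution of the Stokes system for the reflectance and
#' transmittance of `N` identical symmetric layers, valid for non-integer
#' `N`. Degenerate inputs (opaque, purely transmitting, or energy-conserving
#' layers) are handled by their analytic limits.
#'
#' @param R1,T1 Single-layer reflectance and transmittance (vectors),
#'   `R1 + T1 <= 1`.
#' @param N Number of layers, real-valued, `N >= 1`.
#' @return A list with vectors `R` and `T` of the stack.
#' @export
stokes_extension <- function(R1, T1, N) {
  stopifnot(length(N) == 1, is.finite(N), N >= 1)
  if (any(R1 < 0) || any(T1 < 0) || any(R1 + T1 > 1 + 1e-12))
    stop("invalid single-layer R/T")
  .stokes_power(R1, T1, N)
}

# Stokes power for real exponent m >= 0 (m = 0 gives the identity layer).
.stokes_power <- function(R1, T1, m) {
  len <- max(length(R1), length(T1))
  R1 <- rep_len(pmin(pmax(R1, 0), 1), len)
  T1 <- rep_len(pmin(pmax(T1, 0), 1), len)
  Rm <- numeric(len)
  Tm <- numeric(len)
  if (m == 0) return(list(R = Rm, T = Tm + 1))
  tiny <- 1e-14
  opaque <- T1 <= tiny
  noref <- !opaque & R1 <= tiny
  cons <- !opaque & !noref & (1 - R1 - T1) <= 1e-10
  gen <- !(opaque | noref | cons)

  Rm[opaque] <- R1[opaque]
  Tm[opaque] <- 0
  Rm[noref] <- 0
  Tm[noref] <- T1[noref]^m
  if (any(cons)) { # conservative layer: classic pile-of-plates limit
    r <- R1[cons] / (R1[cons] + T1[cons]) # renormalize residual rounding
    Rm[cons] <- m * r / (1 + (m - 1) * r)
    Tm[cons] <- 1 - Rm[cons]
  }
  if (any(gen)) {
    R <- R1[gen]
    T <- T1[gen]
    D <- sqrt(pmax((1 + R + T) * (1 + R - T) * (1 - R + T) * (1 - R - T), 0))
    a <- (1 + R^2 - T^2 + D) / (2 * R)
    b <- (1 - R^2 + T^2 + D) / (2 * T)
    bm <- b^m
    denom <- a * bm - (1 / a) / bm
    Rm[gen] <- (bm - 1 / bm) / denom
    Tm[gen] <- (a - 1 / a) / denom
  }
  list(R = pmin(pmax(Rm, 0), 1), T = pmin(pmax(Tm, 0), 1))
}
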