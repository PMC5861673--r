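---
title: "The white-background leaf model: theory, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The white-background leaf model: theory, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospectwb)
```

## The measurement configuration

Leaf biochemical traits — chlorophyllian pigments ($C_{abc}$ or split
$C_{ab}$/$C_c$, in µg/cm²), water ($C_w$, mg/cm²) and dry matter ($C_m$,
mg/cm²) — leave absorption signatures in the 400–2200 nm
directional-hemispherical reflectance of a leaf. Measuring the leaf over a
*white Teflon background* roughly doubles the optical path (light that
crosses the leaf is reflected back through it), which deepens the
absorption features and improves the sensitivity of reflectance-only
measurements to the absorbers. The price is that the measured quantity is
no longer the leaf reflectance but the reflectance of a coupled
*leaf + background system*, which the forward model must describe.

## The leaf volume: a generalized plate model

The leaf volume is modelled as a stack of $N$ identical homogeneous
absorbing layers ($N \ge 1$, real-valued — the mesophyll structure
parameter). Each layer attenuates perfectly diffuse flux by

$$\tau(k) = (1-k)\,e^{-k} + k^2 E_1(k),$$

where $E_1$ is the exponential integral and the optical depth
$k(\lambda) = \sum_i \mathrm{sac}_i(\lambda)\, C_i / N$ sums the specific
absorption coefficients (SAC) of the version's constituents weighted by
their contents. Four model generations are supported, differing in their
pigment separation (P3/P4 pool $C_{abc}$; P5 splits $C_{ab}$ and $C_c$;
PD adds $C_{Anth}$) and, in each, brown pigments $C_{bp}$ can be enabled
("b" variants) to describe senescent tissue.

Interfaces between consecutive elementary layers keep the standard
diffuse dielectric behaviour: the air-side transmissivity is the
closed-form average Fresnel transmissivity $t_{12} = tav(90^\circ, n)$,
the leaf-side one $t_{21} = t_{12}/n^2$. The two boundaries of a
leaf–air–leaf gap combine into one symmetric internal interface with
transmission $t_{21}/(2 - t_{12})$ — an exact multiple-bounce sum, and
energy-conserving by construction.

**External boundaries carry no reflectivity.** The measured surface
reflectance of the epidermis is handled *outside* the volume by a single
scalar (below), so the volume's top and bottom boundaries are fully
transparent. Algebraically the volume is

$$\text{slab}(\sqrt{\tau}) \;\oplus\;
  \big[\text{unit}\big]^{N-1} \;\oplus\; \text{slab}(\sqrt{\tau}),$$

where $\oplus$ is incoherent layer adding and the symmetric repeat unit is
half-slab | internal interface | half-slab. Adjacent half-slabs merge
multiplicatively, so for integer $N$ this is exactly $N$ full slabs
separated by $N-1$ internal interfaces; the closed-form Stokes solution
raises the unit to the real power $N-1$, extending the stack continuously
to non-integer $N$ (the fitted $N$ on wheat is typically 1.4–1.6, so this
matters). Degenerate Stokes cases (opaque, purely transmitting, or
energy-conserving layers, the last arising wherever $k = 0$) use their
analytic limits. The test suite checks every closed form against
independent numerical oracles: bounce-series summation, iterated
adding-doubling, and quadrature of the defining integrals.

An open modelling question is whether the internal interfaces should keep
their refractive behaviour once the external ones are removed. We keep
them (the mesophyll structure is real; only the *surface* treatment is
replaced) and expose `interfaces = "none"` on the forward functions as a
sensitivity switch for the fully interface-free alternative. Residual
mismatch between either convention and a real leaf is absorbed by the
fitted $R_{surf}$ and $N$.

## Coupling with the surface and the background

The epidermis is described by a wavelength-independent reflectivity
$R_{surf} \in [0, 1)$, identical for both faces, with transmissivity
$1 - R_{surf}$ and no absorption (the refractive index varies little over
350–2500 nm, and for wheat the two faces differ little). Three closed
multiple-bounce compositions couple the system, in order: the lower
surface over the background,

$$R_{surf}^{wb}(\lambda) = R_{surf} +
  \frac{R_{wb}(\lambda)\,(1-R_{surf})^2}{1 - R_{surf} R_{wb}(\lambda)},$$

the leaf volume over that,

$$R_{bue}^{wb} = R_{leaf} + \frac{R_{surf}^{wb}\, T_{leaf}^2}
  {1 - R_{leaf} R_{surf}^{wb}},$$

and the upper surface on top,

$$R_{leaf}^{wb} = R_{surf} + \frac{R_{bue}^{wb}(1-R_{surf})^2}
  {1 - R_{surf} R_{bue}^{wb}}.$$

Directional-hemispherical and bi-hemispherical quantities are treated as
equal throughout. Finally, because a narrow leaf may not cover the
illuminated spot, a fraction $f_{wb} \in [0,1]$ of the background is seen
directly:

$$R(\lambda) = R_{wb}(\lambda)\, f_{wb} + (1 - f_{wb})\,
  R_{leaf}^{wb}(\lambda).$$

When no measured background is supplied, a flat synthetic Teflon curve
$R_{wb} = 0.99$ is used; a measured background sheet overrides it.

## Inversion

The state vector (for the richest variant) is
$V = [C_{ab}, C_c, C_{Anth}, C_w, C_m, C_{bp}, N, R_{surf}, f_{wb}]$,
reduced according to the version's pigment separation. The fit minimizes
the spectral root-mean-square distance

$$J(V) = \sqrt{\tfrac{1}{1800} \textstyle\sum_{\lambda=400}^{2200}
  \big(R_{sim}(\lambda) - R_{meas}(\lambda)\big)^2}$$

on the 1-nm grid. The printed divisor 1800 is the number of grid
*intervals* (one less than the 1801 grid points); on other grids the
package scales it accordingly — the constant does not move the minimizer.

Bounds and initial guesses ship as editable defaults
(`default_bounds()`, `default_starts()`): contents are bounded below by
zero ($N \ge 1$) and above by wide wheat-plausible limits
($C_{abc} \le 140$ µg/cm², $C_w \le 30$ mg/cm², $C_m \le 5$ mg/cm²,
$C_{bp} \le 1$, $N \le 3.5$, $R_{surf} \le 0.5$). The three starts spread
over the box (a green leaf, a thin pale leaf, a dense senescing leaf);
they should be reviewed when the model is applied outside wheat.

Two numerical choices matter:

* **Interior parameterization.** The variables are mapped through a
  logistic transform of their bounds, so the optimizer — a deterministic
  Levenberg–Marquardt descent on the residual vector — iterates strictly
  inside the box. A box-clamping optimizer reliably stalls on the
  $f_{wb} = 1$ face: there the leaf vanishes from the model and every
  other gradient is exactly zero, a spurious attractor. The interior
  map removes that failure mode, in the spirit of the interior-point
  method usually used for this fit.
* **Consensus averaging.** Multi-start averaging assumes the starts land
  on (numerically) the same solution, which is what the three defaults do
  in the vast majority of fits. When a start ends in a genuinely
  different local minimum, blending it in corrupts the estimate — on
  noiseless synthetic leaves the median pooled-pigment error degrades
  from ~$10^{-12}$ to ~15%. The estimate is therefore the per-variable
  mean over the starts whose final cost is within 5% (plus a $10^{-6}$
  floor) of the best start; excluded starts are flagged in the result,
  and the full per-start table and spread are always reported.

Convergence uses a $10^{-10}$ relative tolerance on the cost decrease and
at most 500 iterations per start — far below the measurement noise scale
(fit residuals on real leaves are of order $10^{-2}$).

Batch grouping follows the destructive protocol: by default one
inversion per leaf spectrum; since replicate acquisitions are averaged
before the reflectance factor is computed, inverting per-sample means is
achieved simply by passing averaged spectra.

## The empirical alternative: vegetation indices

Four indices are implemented exactly as defined by their sources, band
ranges read as band means and single bands as nearest-grid samples:
`Dx4` $= R_{850}/R_{710} - 1$ and `CIre`
$= \bar R_{760\text{–}800}/\bar R_{690\text{–}710} - 1$ for pigments,
`SRw` $= R_{1300}/R_{1450}$ and `NDw`
$= (R_{1062}-R_{1393})/(R_{1062}+R_{1393})$ for water. `Dx4` was designed
on transmittance; over a white background the measured reflectance is
dominated by doubly-transmitted flux, so it is computed from the same
white-background spectrum as the others. Calibration regresses *content
on index* (prediction of content is the use case; the direction is a
package choice), linearly except `NDw`→$C_w$ which is quadratic, and is
scored by leave-one-out $r^2$ and RMSE.

## Evaluation metrics

`agreement_metrics()` reports $r^2$ (squared Pearson), Spearman $\rho$
(computed on raw pairs; any linear bias correction leaves both
unchanged), RMSE, the slope of estimated-on-measured, bias (mean measured
minus mean estimated), the slope-corrected RMSE — estimates are regressed
on measurements with slope *and* intercept and the fitted distortion
inverted; a slope-only variant is available by flag — and the relative
rRMSE (slope-corrected RMSE as a percentage of the measured mean).
`spectral_fit_diagnostics()` gives per-leaf fit RMSE and the
per-wavelength RMSE curve split at 1000 nm, which localizes model
deficiencies around the pigment and water bands.

## The synthetic generator, and what it does not emulate

`simulation_spec()` + `generate_dataset()` draw ground-truth parameter
vectors uniformly within the fitting bounds (the same ranges the
inversion must search), forward-simulate each leaf through the full
system model, and add i.i.d. Gaussian noise per wavelength (default
$\sigma = 0.005$, the order of the spectral fit residual observed on real
wheat leaves), truncating to $[0,1]$. An optional coupling draws
$C_c = C_{ab}/5 + \text{jitter}$, emulating the strong
chlorophyll–carotenoid correlation of real leaves. A single seed controls
all stochasticity, and the generator writes the same bundle layout the
reader parses, so synthetic data exercise the full pipeline including the
parsers.

What passing the synthetic suite shows: the closed-form optics, the
coupling equations, the optimizer and the bookkeeping are correct, and
the inversion is well-posed under the model's own physics. What it cannot
show: performance on real leaves, where the SAC calibration, pigment
clumping, surface anisotropy, instrument spectral response and correlated
(non-i.i.d.) measurement errors all bias retrievals — on real wheat data
those effects produce systematic slopes around 1.1–1.7 that the
slope-corrected metrics are designed to quantify.

**Coefficient tables.** The shipped SAC library
(`synthetic_coefficients()`) is *synthetic*: smooth parametric bands with
the qualitative spectroscopy and literature magnitudes of each
constituent (chlorophyll Soret/red bands, carotenoid blue band,
anthocyanin green band, water overtones at 970/1200/1450/1940 nm,
dry-matter SWIR features, a decaying visible continuum for brown
pigments), with small inter-version amplitude/width/refractive-index
offsets mirroring successive recalibrations. It is not any published
calibration; quantitative work on real spectra should load calibrated
tables via `read_coefficients()`. The brown-pigment SAC follows the
dimensionless relative-units convention of leaf-model distributions.

## Problem sizes used by the shipped checks

The property suites run 1000 parameter draws (energy conservation and
absorption monotonicity, on a 5-nm grid; the optics are
wavelength-separable, so the grid density is immaterial there). The
round-trip check inverts 50 noiseless leaves per version on the full 1-nm
grid plus 50 noisy leaves, and the acceptance script re-derives its
summary quantities from 30-leaf batches — sizes at which the medians and
interquartile ranges reported are stable across seeds.

Round-trip inversion checks draw *all* variables — including the
geometry ($N$, $R_{surf}$, $f_{wb}$) — over the full fitting bounds: the
inversion must cope with anything inside the box it searches. The
vegetation-index summary instead uses a measurement-realistic
population (contents over their full ranges, but $f_{wb} \le 0.1$,
$R_{surf} \le 0.1$, $N \in [1.2, 1.8]$): a VI is an algebraic content
proxy with no geometry variables, and calibrating it across leaves whose
directly-lit background fraction spans 0–1 would only measure the
confounding, not the index.

## Known limitations

* Retrieval accuracy on real data is bounded by the SAC calibration;
  recalibrating SACs is explicitly out of scope here.
* $C_m$ is weakly constrained by reflectance-only measurements: its
  absorption is faint and masked by water across the SWIR. Synthetic
  experiments reproduce this (largest relative spread under noise), and
  no merit-function or prior-based remedy is attempted.
* The surface is a single scalar reflectivity: no BRDF, no
  wavelength-dependence, no face asymmetry.
* Fluorescence, detector splice artifacts and background translucency
  are not modelled.
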