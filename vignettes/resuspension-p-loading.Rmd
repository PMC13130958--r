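---
title: "Quantifying episodic internal phosphorus loading from sediment resuspension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying episodic internal phosphorus loading from sediment resuspension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedpflux)
```

## The problem

In shallow, wind-exposed lakes, storms episodically resuspend the upper
sediment layers. The resuspended material carries legacy phosphorus back into
the water column, where its labile part can dissolve and feed algal blooms.
This internal, event-driven P flux is missed both by tributary load monitoring
and by the conventional internal-loading term (steady diffusive flux across
the sediment–water interface). `sedpflux` implements a tracer-based framework
to quantify it: beryllium-7 profiles constrain how deep and how fast surface
sediments are reworked, sequential-extraction chemistry says how much of the
sediment P is bioavailable, and a change in suspended particulate matter (SPM)
— measured in situ or retrieved from satellite reflectance — is inverted to an
erosion depth and a P release, scalable from a single station to a whole
basin.

## The beryllium-7 mixing model

Beryllium-7 (half-life 53.3 d) is produced in the atmosphere, delivered to
the lake surface, and sorbs rapidly to fine particles. Any activity found
below the uppermost sediment layer must have been mixed down recently. At
steady state between biodiffusive mixing ($D_b$, cm$^2$ yr$^{-1}$) and decay
($\lambda = \ln 2 / T_{1/2}$), the depth profile is exponential:

$$A(z) = A_T \exp\!\left(-z \sqrt{\lambda / D_b}\right),$$

with $A_T$ the activity at the interface. `be7_fit()` estimates $A_T$ and
$D_b$ by ordinary least squares of $\ln A$ on layer midpoint depth — the
log-space fit matches the multiplicative error of activity counting — and
returns a classed model object with the usual `coef`, `predict`, `residuals`,
`simulate`, `plot` methods:

```{r}
core <- sediment_core("WLE1", "2023-04-15", 7,
  data.frame(top_cm = 0:4, bottom_cm = 1:5,
             be7_dpm_cm2 = c(8, 4, 2, 1, 0.5)))
fit <- be7_fit(core)
fit
```

Three numerical choices deserve note:

* **Functional form.** The exponent is $z\sqrt{\lambda/D_b}$, the standard
  steady-state decay–biodiffusion solution. It is the only form
  dimensionally consistent with the mixing-depth relation
  $h = \sqrt{D_b \tau}$ used below.
* **Midpoint evaluation.** Layer activities are depth-integrated over 1 cm
  slabs; the model is evaluated at slab midpoints (0.5, 1.5, … cm), the
  simplest consistent discretisation, with $A_T$ reported as the $z = 0$
  intercept.
* **Degenerate profiles.** A flat or inverted profile has no finite mixing
  rate. Rather than report a negative $D_b$, the fit flags
  `non_attenuating_profile` and returns `D_b = Inf` with $k = 0$. Layers
  with zero or missing activity are excluded from the regression and
  counted.

From the fit follow the derived rates (all year conversions use 365 d):
mixing depth $h = \sqrt{D_b \tau}$ over the tracer mean lifetime
$\tau = T_{1/2}/\ln 2 \approx 77$ d; steady-state flux
$J_{sed} = \lambda I_{sed}$ from the inventory $I_{sed}$ (the summed layer
activities); particle residence time
$T_{res} = A_w D / (10^4 J_{sed})$ and settling rate $D / T_{res}$ from the
water-column activity; the depositional flux between two sampling dates
$J_{Be} = \lambda[I_2 - I_1 e^{-\lambda t}]/(1 - e^{-\lambda t})$, which is
deliberately *not* clamped at zero — a negative value means the inventory
declined faster than decay, i.e. net erosion — and the accumulation rate
$J_{Be}/A_{spm} \times 365$.

## Phosphorus bookkeeping

Sediment P is carried as the five operationally defined
sequential-extraction fractions (loosely bound, redox-sensitive, Al/Fe
oxide-bound, Ca-bound, residual organic; mg P g$^{-1}$ dry sediment). Total P
is their sum; bioavailable P (BioP) is the labile subset (loosely bound +
redox-sensitive + Al/Fe-bound). A missing fraction is a hard error, never an
implicit zero, because zero is a legitimate measurement. The packing relation
$\rho_b = \rho_d (1 - \phi)$ with particle density $\rho_d = 2.45$ g cm$^{-3}$
converts between dry bulk density and porosity and is cross-checked at load
time wherever a core carries both.

## Erosion-depth inversion and P release

An SPM increase $\Delta SPM$ (g m$^{-3}$) over a water column of depth $D$
corresponds to a resuspended mass $M = \Delta SPM \cdot D$ (g m$^{-2}$) and
an eroded-bed thickness

$$ED = \frac{\Delta SPM \cdot D}{\rho_d (1 - \phi)},$$

with the denominator equal to the dry bulk density — written in terms of
$\rho_d$ and $\phi$ to make explicit that porosity enters exactly once. The
porosity used is the thickness-weighted mean over the sampled profile.
Negative $\Delta SPM$ (net deposition) contributes zero erosion and is
flagged; release is quantified only where SPM increased. The P released is
the thickness-weighted mean concentration over the eroded window — full
layers plus the partially eroded deepest layer — times $M$. Erosion depths
beyond the sampled profile raise an error rather than extrapolate: the caller
must decide, and observed event-scale erosion (order 0.1–1 cm) sits well
inside a 5 cm profile.

## Satellite scaling

SPM is retrieved from water-leaving reflectance $\rho_w = \pi R_{rs}$ at
665 nm with the single-band semiempirical algorithm
$SPM = A_\rho \rho_w / (1 - \rho_w / C_\rho)$. The defaults
($A_\rho = 355.85$ g m$^{-3}$, $C_\rho = 0.1728$) are the published red-band
calibration; both are configurable since regional recalibrations exist.
Reflectances at or above $C_\rho$ (saturation) or below zero are masked
invalid and propagate as no-data. Atmospheric correction is upstream and out
of scope — the package accepts either reflectance or precomputed SPM grids.

A pre/post scene pair yields per-pixel $\Delta SPM$; pixels are classified as
resuspended when the *relative* increase exceeds the retrieval uncertainty
(NRMSE of validation matchups, 13.9% by default), one-sided by construction.
Basin totals apply the first-order scaling
$P_{scaled} = \bar P_{sediment} \times 10^{-3} \times \Delta SPM$ per masked
pixel, multiply by pixel depth and area (from the grid georeference, e.g.
$9 \times 10^4$ m$^2$ for 300 m pixels), and sum to kg. $\bar P_{sediment}$
is the mean over all sampled depths, stations and dates unless overridden.

Grids are handled as plain-text ESRI ASCII rasters through the package's
lightweight `spm_grid` container, which keeps the cell size, origin and
no-data convention explicit and the whole pipeline text-only and portable.

## Synthetic data: what it emulates, and what it does not

Every stage is testable without field data through seed-deterministic
generators:

* `simulate_be7_core()` — the forward exponential profile with
  multiplicative lognormal noise (activity counting is positive and
  multiplicative; default $\sigma = 0.1$ in tests, i.e. 10%).
* `simulate_p_profiles()` — near-depth-invariant fractions with truncated
  normal multiplicative perturbations (relative SD 0.035, matching the low
  compositional variability of actively mixed surface sediments).
* `simulate_event()` — a uniform-background scene pair with a Gaussian
  resuspension plume, optional additive pixel noise, bathymetry defaulting
  to 7.5 m (a shallow-basin mean depth), and ground truth computed from the
  same closed forms the pipeline inverts, under the same classification
  threshold. The default plume sigma is 15% of the smaller grid dimension,
  so the emulated event is basin-scale at any grid resolution, as observed
  events are. Test problem sizes: 200 × 200 pixels, 50 noise seeds for the
  stochastic recovery checks; 200 seeds for mixing-rate recovery.

The generators reproduce the statistical *structure* the analysis assumes —
exponential tracer profiles, depth-invariant P composition, a smooth plume
over a uniform background. They do not emulate heterogeneous bathymetry,
spatially correlated retrieval error, patchy sediment properties, or plume
transport physics. Passing recovery tests therefore demonstrate that the
estimators invert their own forward models at realistic noise levels — not
that field estimates carry those error bars.

## Design choices on open points

* CV across stations uses the sample (n−1) standard deviation — appropriate
  at the small station counts involved.
* The half-life default is the physical 53.3 d; the mean lifetime then
  rounds to the conventional ~77 d.
* Negative fluxes (depositional flux, accumulation rate) are reported with a
  `net_erosion` flag; zero-clamping happens only where the quantity is
  physically one-sided (erosion depth, resuspended mass).
* Percent-of-target comparisons report unrounded values; fold comparisons of
  release versus diffusive flux report whole folds (lower bound = smallest
  release / largest flux, upper = largest release / smallest flux) with the
  exact ratios preserved in an attribute.
* The orchestrator `run_event_analysis()` is configuration-driven (YAML or
  list), runs only the stages whose inputs are present, echoes the resolved
  configuration and input checksums into the report, and surfaces numerical
  warnings (flagged fits, excluded pixels) in the report itself, not only in
  logs.

## Limitations

Single, depth-constant $D_b$ per core (no depth-dependent mixing or
non-steady transport); no hydrodynamic resuspension prediction; no P
sorption–desorption kinetics; the satellite scaling uses one basin-mean
sediment P concentration, so spatial covariance between $\Delta SPM$ and
sediment P enters only through the site-level workflow.
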