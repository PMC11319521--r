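---
title: "Projection integration of collimated beam profiles: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection integration of collimated beam profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamproj)
```

## The problem

Stereotactic radiosurgery delivers millimetre-scale photon fields whose
clinical quality is judged by three numbers read off the lateral beam
profile at the treatment plane: the field size (FWHM), the 20--80%
penumbra, and the output (peak dose rate). All three are governed by the
interplay between the finite focal spot of the X-ray source and the stack
of circular apertures that collimate the beam. Full Monte-Carlo transport
resolves this interplay but is far too slow for iterative collimator
design; single-ray geometric estimates are fast but ignore the focal-spot
distribution that dominates the penumbra of small fields.

`beamproj` implements a middle path: the focal spot is treated as a
distribution, sliced into elements narrow enough to act as point sources,
and each slice is *projected* through the aperture stack onto the
treatment plane. Summing the projected slice intensities yields the full
profile in well under a second, at any spot model, for any number of
collimation levels.

## The model

Heights are measured upward from the treatment plane; the source sits at
$H_\mathrm{beam}$ and an aperture of radius $R_a$ at height $H_a$. A point
source (slice) at lateral position $r_0$ illuminates, through one
aperture of center $c$, the signed interval

$$
\mathrm{left} = r_0 + M\,(c - R_a - r_0), \qquad
\mathrm{right} = r_0 + M\,(c + R_a - r_0), \qquad
M = \frac{H_\mathrm{beam}}{H_\mathrm{beam} - H_a},
$$

the pinhole projection of the two aperture edges ($M$ is the
magnification of the aperture level). With several collimation levels the
slice sees the intersection of the per-level intervals: the largest left
edge and the smallest right edge. Inside that interval the slice
deposits its own intensity $S(r_0)$; outside it deposits nothing. The
profile is the sum over slices,

$$
P(r) \;=\; \Delta\!\sum_k S(r_{0,k})\,
           \mathbf{1}\!\left[\mathrm{left}_k \le r \le \mathrm{right}_k\right],
$$

with $\Delta$ the slice spacing, i.e. a rectangle-rule integral of the
source distribution over the set of slice positions whose projected
interval contains $r$. Air attenuation, scatter, penetration through the
aperture material, and the angular dependence of the source emission are
all outside the model; consequences are discussed under *Limitations*.

Everything is signed throughout. The positive-magnitude "left edge"
common in reporting is produced only at output boundaries; keeping signed
coordinates internally removes a whole class of sign errors in the
intersection step and makes off-center apertures and sources (for
misalignment studies) come out of the same formulas with no extra cases.

## Parameters and defaults

* **`grid_step` = 0.1 mm.** The treatment-plane resolution of the
  computed profile. Grids symmetric about the axis are built by mirroring
  the positive half, so a symmetric system produces an exactly symmetric
  profile (position pairs are bitwise negatives of each other).
* **`slice_step` = 0.002 mm.** Spacing of the source slices. The
  rectangle-rule error at a projected edge is roughly
  $\Delta\,S(\text{edge})/2$ relative to the source integral, i.e.
  $\sim 6\times 10^{-4}$ of peak at 0.002 mm for a 1.5 mm FWHM spot. This
  keeps the whole profile within $10^{-3}$ of the closed-form reference
  (below) at negligible cost (about 500--5000 slices depending on the
  step; a profile still computes in tens of milliseconds).
* **`truncation` = 4 (Gaussian spots).** Slices span $\pm 4\sigma$; the
  neglected tail mass is $6\times 10^{-5}$, below every tolerance used.
* **Interval membership is closed on both ends.** At any finite
  `slice_step` the choice only moves mass of order one slice; it is fixed
  for reproducibility.
* **Spot models.** Gaussian spots are parametrized by FWHM
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$); arbitrary measured spots
  enter as two-column tables interpolated linearly onto the slice grid
  and clamped at zero. Slice weights are the one-dimensional intensity
  along a diameter (slab approximation) — see the 2D discussion.

## Normalization conventions

Profiles are computed unnormalized and carry their source integral, so
three scales are available: raw values, peak-normalized shapes (used for
FWHM/penumbra), and *transmitted fraction* (values divided by the source
integral), which is the probability that a photon emitted by the spot
reaches the point — the scale on which the oracles operate.

Peak dose-rate comparisons across different spot sizes use the
**equal-total-output** convention (`source_norm = "total"`): shrinking
the focal spot at fixed beam current redistributes the same output, so
the peak rises exactly insofar as the collimator clips less of the spot.
Comparing unit-peak sources instead (`source_norm = "peak"`) would
conflate clipping with the raw loss of total output of a narrower
Gaussian and would show the *opposite* sign; it is retained as an option
because it answers a different question (what does one emitting element
contribute).

## The worked-example fixtures

Two conical collimators for a 457 mm source-to-treatment-plane distance
and a 1.5 mm FWHM Gaussian spot, each represented by its entrance and
exit apertures:

* **collimator4** — 4 mm design field; published aperture diameters
  2.3 mm (entrance) and 1.8 mm (exit).
* **collimator25** — 25 mm design field.

The aperture *heights* are not published and are reconstructed, and every
reconstructed number is carried in the fixture notes and overridable in
the configuration:

* The exit aperture sits where its bore is tangent to the point-source
  cone of the nominal field: $H_a = H_\mathrm{beam}(1 - d/F)$, giving
  251.35 mm for the 4 mm system ($d$ = 1.8 mm, $F$ = 4 mm). The 25 mm
  system shares the level; its tangent exit radius is then 5.625 mm.
* The entrance level is assumed 50 mm below the source (height 407 mm).
  For the 4 mm system the published 2.3 mm entrance then trims the
  off-focus tails of the spot (slices beyond $\pm 1.29$ mm never reach
  the axis), which is what sharpens its penumbra below the single-
  aperture value and makes the peak rate sensitive to spot size.
* The 25 mm entrance radius is not published. It is sized to pass the
  full truncated spot for the nominal field,
  $R_e = 4\sigma H_e/H_\mathrm{beam} + (F/2)(H_\mathrm{beam}-H_e)/H_\mathrm{beam}
  \approx 3.64$ mm, leaving the 25 mm penumbra exit-dominated. A
  substantially tighter entrance is geometrically untenable for this
  system: scanning the entrance radius shows the penumbra either stays at
  the exit-dominated value (1.31 mm) or, once the entrance shadow reaches
  the profile shoulder (below about 1.8 mm radius), degrades past 1.5 mm
  within a 0.05 mm change — there is no stable intermediate regime.

## Independent validation

Two oracles are built *without* the edge-projection algebra:

1. **Closed form** (single aperture, Gaussian spot): the membership
   condition is linear in $r_0$, so the profile is a difference of normal
   CDFs, $\Phi\!\big(\tfrac{M R_a - r}{(M-1)\sigma}\big) -
   \Phi\!\big(\tfrac{-M R_a - r}{(M-1)\sigma}\big)$. The integrator
   matches it to better than $10^{-3}$ of peak at default settings.
   A useful corollary: the single-aperture 20--80% penumbra is
   $\sigma_p\,[\Phi^{-1}(0.8p) - \Phi^{-1}(0.2p)]$ with
   $\sigma_p = (M-1)\sigma$ and $p$ the clipped peak
   $2\Phi(MR_a/\sigma_p)-1$; only in the sharp-plateau limit $p \to 1$
   does this reduce to the familiar $1.6832\,\sigma_p$.
2. **Monte-Carlo rays**: source positions sampled from the untruncated
   spot distribution; a ray to each grid point is tested against every
   aperture by direct point-in-opening evaluation. At $10^6$ samples the
   integrator sits inside the 3-standard-error band essentially
   everywhere; the test requires at least 99% of grid points inside,
   since a handful of 3-SE excursions is expected from sampling noise
   alone even for an exact integrator.

## Rectangular fields and 2D maps

Rectangular fields are composed from two orthogonal planes computed
independently with the same 1D machinery. The 2D mode instead divides an
isotropic Gaussian spot into pixels and applies a point-in-disc test at
every aperture along each source-pixel-to-target-pixel ray. The 1D slab
weighting and the 2D radial weighting agree on the axis location, field
size (central-row FWHM within a few tenths of a millimetre) and all
symmetries, but differ near the field edge by several percent of peak —
a slab integrates the full length of each source strip, a disc does not.
The 1D mode is the fast design tool; the 2D mode is the cross-check and
the route to genuinely non-circular problems.

## What the tests do and do not show

The test suite exercises synthetic systems whose ground truth is known
analytically (top-hats, trapezoids, triangular spots, erf edges) plus the
two fixtures. Passing it shows the geometric transport, integration and
profile analytics are correct *within the model*: no scatter, no
collimator transmission, no detector blur (the top-hat detector
convolution emulates the latter qualitatively), no angular source
dependence, no depth dose. Measured profiles include all of these;
comparisons against measurement should expect the model's sharper
shoulders and lower tails, concentrated at the field edge. Problem sizes
in routine tests are the fixture defaults (241--451 grid points, 500--
5100 slices, $10^5$--$10^6$ Monte-Carlo rays), which keep the full suite
under half a minute.

## Known limitations

* Collimator walls are represented by entrance/exit apertures only; bore
  shape between them (cylindrical vs conical) is not modelled.
* No transmission or scatter: profile tails go to exactly zero, so
  low-dose quantities (e.g. 10% widths) are underestimated.
* The slab approximation makes 1D profiles of *circular* apertures an
  approximation whose edge shape differs from the radial truth; FWHM and
  relative comparisons (sweeps, misalignment trends) are insensitive to
  this, absolute penumbras less so.
* Reconstructed fixture heights are assumptions, documented as such;
  published per-method FWHM/penumbra tables for the 25 mm system reflect
  a geometry whose governing heights are not in the text, so agreement is
  held to the design field size and the published penumbra band rather
  than to every printed cell.
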