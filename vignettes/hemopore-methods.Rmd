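---
title: "Methods: the tortuous pore diffusion model and SPM pore measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tortuous pore diffusion model and SPM pore measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopore)
```

## The problem

Hemoconcentrators are hollow-fibre ultrafiltration devices that remove excess
water from blood during cardiopulmonary bypass. Their membranes must combine
a high pure water permeability with near-total retention of albumin, and both
properties are governed by the nanometre-scale pore structure of the inner
lumen surface — the surface that blood touches and fouls with an adsorbed
protein layer. This package provides the two complementary ways of getting at
that structure and the machinery to compare them:

* a **transport route**: infer an equivalent pore diameter from the measured
  pure water permeability via the tortuous pore diffusion (TPD) model;
* an **imaging route**: measure pore axes directly on scanning probe
  microscopy (SPM) topographies of the lumen surface;
* a **fouling comparison**: quantify how blood contact changes permeability,
  inferred pore size and albumin sieving.

Because raw instrument scans of clinical membranes are rarely available, the
package also contains a first-class synthetic topography generator with known
ground truth, so the entire imaging pipeline is validated by parameter
recovery rather than by eye.

## The TPD model

The membrane wall is idealised as a bundle of cylindrical pores of one radius
$r_P$, tortuous so that the permeation path $L = \tau\,\Delta x$ exceeds the
wall thickness $\Delta x$. Hagen–Poiseuille flow through that bundle gives

$$ L_P = \frac{r_P^2\, H}{8 \mu\, \tau^2\, \Delta x}
   \qquad\Longleftrightarrow\qquad
   r_P = \sqrt{\frac{8 \mu\, \tau^2\, \Delta x}{H}\, L_P}, $$

where $H$ is the volumetric water content of the wetted wall and the surface
porosity is $A_K = H/\tau$. Diffusive solute transport through the same
bundle is

$$ P_m = \frac{D_O\, f(q)\, S_D\, A_K}{\tau\, \Delta x}, $$

with $q = r_s/r_P$ the solute-to-pore radius ratio, $S_D = (1-q)^2$ the
steric partitioning factor at the pore inlet and $f(q)$ the wall-friction
factor. The $f(q)$ and $S_D$ forms are those of the classical Verniory pore
model (Haberman–Sayre centreline drag polynomial); `hindrance_factors()`
takes the friction form as a pluggable argument, because several published
variants exist and the choice matters above $q \approx 0.3$.

**Assumptions worth remembering.** The model treats the wall as homogeneous
and the pores as circular and monodisperse. Clinical hemoconcentration
membranes are asymmetric (a selective skin over a support), so the TPD
diameter reflects an effective pore over the whole wall; it is expected to
run slightly larger than the skin-surface pores seen by SPM. The model is
not extended to explicit skin-layer geometries here.

### Units

Inputs arrive in the units in which practitioners report them: $L_P$ in
mL/(hr·mmHg·m²), $\mu$ in cP, $\Delta x$ in µm. Everything is converted to
one canonical SI system (m, s, Pa; 1 mmHg = 133.322 Pa, 1 cP = $10^{-3}$
Pa·s) before any algebra, and pore radii/diameters are reported in nm. This
single conversion point is deliberate: the mixed clinical/SI unit landscape
is the main practical source of silent error in this calculation.

Defaults: $\mu = 0.695$ cP (pure water at 310 K, the temperature at which
the permeability measurements are made) and $\tau = 1.6$ (the accepted
empirical value for these polyethersulfone membranes). Both are overridable
per call; no temperature–viscosity model is included.

```{r tpd}
pm <- purema_membranes()
pore_diameter_from_lp(207, pm[["PUREMA A"]])
```

### The STOP method

`lp_from_stop_method()` implements the dead-end filtration arithmetic:
$L_P = 60\,Q_F/(A \cdot TMP)$ with $Q_F$ in mL/min. The run duration is
metadata (it matters only when a collected volume rather than a rate was
recorded). The permeability ↔ radius algebra is exactly invertible;
`lp_from_pore_radius()` is the inverse and the round trip is tested to a
relative error of $10^{-12}$ across the full physical parameter range.

## SPM pore measurement

The imaging pipeline mirrors how an operator measures pores on a topography,
made deterministic and reproducible:

1. **Flattening** (`flatten_topography()`): least-squares plane removal
   (sample tilt), optionally followed by per-scan-line median alignment,
   then median re-centring to height 0. Both steps are linear or per-row
   constant shifts, so pit depths relative to their surround are unchanged.
2. **Segmentation** (`segment_pores()`): pores are connected components
   (4-connectivity) of pixels deeper than $-k \cdot \mathrm{MAD}$ of the
   flattened heights, $k = 3$ by default. MAD is used instead of the
   standard deviation because the pores themselves are in the tail they are
   being detected against. Components under `min_area_px` (default 4) are
   dropped; components touching the scan border are kept but flagged and
   excluded from distributions by default, because the border censors their
   axes.
3. **Line analysis** (`measure_pore()`): the major axis is the maximum Feret
   (caliper) diameter of the component and the minor axis the minimum Feret
   width — the extremal line lengths an operator could draw across the pore.
   Both are computed on the convex hull of pixel *corners* (the ImageJ
   convention; corner support makes a one-pixel-wide region one pixel wide,
   not zero). The equivalent diameter is the ellipse-area-equivalent
   $\sqrt{major \times minor}$; the area is pixel count × pixel area; the
   depth is the deepest height in the component.
4. **Distributions** (`build_distribution()`): fixed-width histograms
   starting at 0 — 5 nm bins for axis metrics, 100 nm² for area by default —
   with mean and sample standard deviation ($n-1$; reported as 0 with a flag
   when only one pore exists) for all four metrics.

Numerical conventions fixed for reproducibility: row 1 is the top scan line
with x increasing along columns; pixel size is scan size divided by the
pixel count; heights are relative; grids are plain-text matrices with a JSON
metadata sidecar, and all writers emit full double precision so round trips
are bit-exact.

## The synthetic generator

`generate_surface()` emulates what a dynamic-force-microscopy scan of a
clean polyethersulfone lumen surface looks like statistically: elliptical
nm-scale pores (axes lognormal, medians 27 and 15 nm by default, matching
the wide right-skewed axis distributions of high-permeability membranes) at
uniform orientations, placed without overlap on a rough surface, at field
sizes of 2000/500/200 nm. Ground truth (centres, axes, orientation, depth)
is returned with the surface, and everything is deterministic given the
spec's mandatory seed.

Choices that deserve justification:

* **Roughness is pixel-scale.** The background is a Gaussian field whose
  default correlation length (2 nm) is below the pixel size at the study's
  scan scales, i.e. effectively white — the signature of instrument noise.
  This is a modelling decision, not an accident: a robust
  $-k\cdot\mathrm{MAD}$ threshold is only a sensible detector when the
  background has little spatial correlation, since a field correlated over
  several pixels produces connected sub-threshold excursions that are
  indistinguishable from small pores by depth alone. Coarser real structure
  (the polymer-particle texture) is modelled separately as positive
  spherical-cap bumps (`particle_texture`), which raise the robust scale
  estimate but cannot mimic pits.
* **Pit profile.** Pores are flat-bottomed elliptical pits (default depth
  20 nm, deep relative to 1 nm RMS roughness, as for through-pores profiled
  by a sharp tip) with a cosine taper over one pixel of *true* distance to
  the rim. The taper suppresses aliasing in the caliper measurement; making
  its width a true distance rather than a fraction of the normalised
  elliptical coordinate keeps the detected contour within half a pixel of
  the rim for eccentric pores as well.
* **Fouling transform.** `apply_fouling()` occludes an exactly-counted,
  seeded and *nested* subset of pores (so detected counts are monotone in
  the coverage fraction at fixed seed), filling each to within
  `layer_thickness_nm` (default 1 nm) of the local surface level estimated
  from an annulus around the pore. Optional whole-field Gaussian smoothing
  is available but defaults to 0: smoothing correlates the background and
  lowers the MAD threshold, which reintroduces exactly the false detections
  discussed above and obscures the occlusion signal being studied.

**What passing recovery tests does and does not show.** The generator
reproduces the geometry and amplitude structure of real scans, not their
physics: no tip-sample convolution (real tips widen pores and round rims),
no scan-line artefacts or drift, no partially-resolved sub-surface pores,
and no adsorption kinetics. Recovery of ground truth (precision and recall
≥ 0.9, major-axis bias within 10% on seeded 512² fields with 15 pores)
validates the measurement pipeline's geometry; it does not certify accuracy
on instrument data, where tip convolution is typically the dominant bias.

## The fouling comparison

`fouling_report()` assembles, per membrane: permeability summaries per
condition (before, after high load, after low load), retention ratios, the
TPD diameter for each condition, paired t-tests, and the albumin sieving
coefficient $SC = 2 C_F / (C_{B,in} + C_{B,out})$ (the arithmetic-mean
blood-side convention standard for hemoconcentrators). Because the TPD
diameter is proportional to $\sqrt{L_P}$, diameter ratios track permeability
retention exactly; this identity is tested rather than assumed. Published
datasets often report only mean ± sd, so the report accepts either replicate
vectors (t-tests computed, zero-variance differences rejected as degenerate)
or summary means (t-tests skipped with a notice) — recomputing a published
p-value requires the raw replicates.

## Problem sizes and tolerances

Validation runs use 512² grids at 2000 nm scan size with 15 pores for
pipeline recovery (a realistic pore density for a high-permeability
membrane at that field size), 128–256² grids for I/O and fouling unit
tests, 1000-point random sweeps for the algebra round trip, and a
0.2 nm tolerance against published TPD diameters (the printed transport
inputs carry 2–3 significant figures, which is exactly a ±0.1–0.2 nm
uncertainty band at these diameters). Algebraic identities are asserted at
$10^{-12}$ relative; geometric measurements at 1–1.5 px.

## Known limitations

* The TPD model's homogeneous-wall assumption biases its diameter upward
  relative to skin-surface SPM measurements on asymmetric membranes; the two
  routes should agree in magnitude, not digit-for-digit.
* Feret axes on 3–4 px pores are quantisation-limited; below about 3 px
  radius the 10% bias bound is not meaningful.
* The segmentation rule is depth-only; it cannot separate touching pores
  (no watershed), and merged neighbours report as one larger pore.
* Sieving coefficients are treated as dimensionless ratios; assay units and
  protein-specific adsorption corrections are out of scope.
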