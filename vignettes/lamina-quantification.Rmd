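---
title: "Quantifying 3D nuclear lamina shape: models, parameters and validation"
author: "LaminaShape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D nuclear lamina shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The nuclear lamina — the lamin A/B meshwork lining the inner nuclear
membrane — changes shape when cultured cells senesce, when myoblasts come
from aged donors, when lamin genes carry disease mutations, and when cells
enter apoptosis. Fresh cells show a smooth, elliptical shell; senescent
cells show wrinkling and coherent bright patches with lamin redistributed
into the nucleoplasm; apoptotic cells show strong folding. LaminaShape
turns confocal Z-stacks of single nuclei into three per-cell descriptors of
that shape and classifies labeled cell populations from them.

# The three descriptors

Given a closed triangulated lamina surface with per-vertex intensity
samples:

* **intensity** — the mean of the per-vertex intensities divided by the
  mean raw intensity over the whole filled nucleus (shell plus interior).
  Division by the whole-nucleus mean makes the descriptor invariant to
  laser power and expression level, and makes it *decrease* when lamin
  moves from the shell into intranuclear structures — the behaviour that
  distinguishes senescent cells. Dimensionless.
* **skewness** — the sample skewness, in the biased moment form
  $g_1 = m_3 / m_2^{3/2}$, of the normalized per-vertex intensities.
  The biased form is the simplest convention and differs negligibly from
  bias-corrected variants at the per-cell vertex counts used here
  (thousands). Invariant under positive affine transforms of the values.
* **curvature** — the area-weighted mean of $|K|$ (absolute Gaussian
  curvature) over the surface, multiplied by $R_{eq}^2$ where
  $R_{eq} = (3V/4\pi)^{1/3}$ comes from the enclosed volume. The
  normalization makes the descriptor dimensionless and invariant to
  uniform spatial rescaling and anchors a perfect sphere at exactly 1;
  wrinkling and folding push it above 1.

Scale invariance of the curvature descriptor is what lets the simulator
work with compact (scaled-down) nuclei without changing any descriptor
distribution.

# Pipeline and design choices

## Resampling

Confocal stacks are anisotropic (axial spacing ~122 nm against lateral
40–60 nm in the acquisition regime this package targets).
`resampleIsotropic()` interpolates each axis with a natural cubic spline to
the smallest input spacing, so the better-sampled lateral axes are never
degraded. Spline interpolation is linear in the data, so each axis is
resampled with a precomputed interpolation matrix; values are clipped at
zero because intensities are physical counts. Resampling is exact on
constants and idempotent at a fixed target.

## Segmentation

`segmentLamina()` runs: Gaussian smoothing (default sigma 100 nm) → global
Otsu threshold (absolute override available) → largest 6-connected
component → morphological closing → cavity filling → surface extraction.
Failure is reported, with a reason, when nothing survives thresholding,
when the component touches the stack border, when the filled volume is
below `minVolume`, or when the surface cannot be completely traced — such
cells are meant to be excluded from population statistics, and
`segmentationSuccessRate()` reports the retained fraction.

Two deliberate choices:

* **Ray-cast surface extraction.** The closed mesh is built by casting
  rays from the mask centroid along geodesic-sphere directions (a
  subdivided icosahedron, default 2562 vertices) and placing a vertex at
  the outermost boundary crossing of the filled mask, refined to the
  half-amplitude crossing of the raw intensity edge for sub-voxel
  accuracy. This yields a guaranteed closed, consistently oriented,
  genus-0 2-manifold with a controllable vertex budget — properties a
  voxel-walking isosurface extractor only delivers after repair — and a
  ray with no crossing is exactly the "contour not completely found"
  failure mode. The cost is that strongly non-star-shaped folds are traced
  by their outermost crossing; nuclei are star-shaped to a good
  approximation, and the simulator's surfaces are star-shaped by
  construction.
* **Vertex intensity as an inward radial peak.** The mask boundary can sit
  a fraction of a voxel outside the shell, where intensity is already
  falling; sampling exactly at the vertex would make the intensity
  descriptor depend on that offset. Each vertex therefore carries the
  maximum raw intensity along a 300 nm inward radial probe
  (`intensityProbeDepth`) — the lamina's peak brightness at that surface
  point.

`minVolume` defaults to 10 µm³. This floor rejects debris while admitting
the compact simulated nuclei (~20–40 µm³) used throughout validation; for
real hMSC nuclei (hundreds of µm³) a higher floor is reasonable and the
parameter is exposed everywhere.

## Curvature estimation

Per-vertex Gaussian curvature comes from a local quadric fit: neighbours
within three mean edge lengths are projected onto the tangent plane
(normal = area-weighted incident face normals) and
$z = \frac12(ax^2 + 2bxy + cy^2) + dx + ey$ is fit by least squares,
giving $K = (ac - b^2)/(1 + d^2 + e^2)^2$. Neighbourhoods with fewer than
6 points raise an error (the fit would be under-determined). Vertex areas
are one third of incident face areas. The estimator is validated against
closed forms (sphere: $K = 1/R^2$; ellipsoid:
$K = 1/(a^2b^2c^2(x^2/a^4 + y^2/b^4 + z^2/c^4)^2)$) and against the
Gauss–Bonnet identity $\int K\,dA = 4\pi$ on closed genus-0 meshes — see
`tests/testthat/test-features.R` and `scripts/acceptance.R`, which compute
these errors.

## Classification

`fitLinear()` implements the Fisher pairwise linear discriminant with
pooled within-class covariance: $w \propto S_w^{-1}(\mu_1 - \mu_2)$, offset
at the midpoint of the projected class means, ridge term
$10^{-6}\,\mathrm{tr}(S_w)$ against near-singularity. Multiclass decisions
use pairwise voting; ties are broken by the smallest Mahalanobis distance
to a tied class mean (for midpoint offsets this voting is equivalent to
taking the largest equal-prior discriminant score, which the
leave-one-out loop exploits for speed; the equivalence is asserted in the
test suite).

Features are z-scored before fitting (default on, switchable) so the
intensity scale cannot dominate; standardization is refit inside every
leave-one-out fold to avoid information leakage. Whether the original
method standardized is not documented, hence the switch, and both paths
are tested.

`loocvError()` reports the leave-one-out error — each of the N cells
classified by a discriminant trained on the other N − 1 — with the
binomial standard deviation $\sqrt{e(1-e)/N}$, the convention that
reproduces the published error ± SD pairs this package anchors itself to
(6.1% → ±2.9% and 13% → ±4.1% at N = 68). All cells are kept; no outlier
removal. Significance comes from `permutationP()`: labels are permuted
across cells (default 999 permutations; the heavier validation runs use
199), the LOO error recomputed, and the add-one estimate
$p = (1 + \#\{e_{perm} \le e_{obs}\})/(1 + B)$ reported. A binomial test
against chance (`chanceBinomialP()`) is available as a secondary report.
`fractionInClassRegion()` answers questions like "what fraction of a
senescent cohort falls in the apoptotic decision region";
`populationTrendReport()` gives per-population feature means ± SD and the
centroid trend plot.

## FRAP

`normalizeTrace()` applies double normalization,
$$I(t) = \frac{roi(t)-bg}{ref(t)-bg} \cdot
          \frac{\overline{ref_{pre}}-bg}{\overline{roi_{pre}}-bg},$$
so background and any fading shared by bleach and reference regions cancel
exactly, and rescales so the pre-bleach mean is exactly 1.
`fitRecovery()` fits $I(t) = I_0 + A(1 - e^{-t/\tau})$ to the post-bleach
frames. A single exponential is the minimal model that yields both
reported quantities: $T_{1/2} = \tau\ln 2$ and the immobile fraction
$1 - (plateau - I_{bleach})/(1 - I_{bleach})$. For fixed $\tau$ the model
is linear in $(I_0, A)$, so the fit profiles the residual sum of squares
over $\log\tau$ with a 1-D minimizer and solves the linear part exactly —
derivative-free, no starting values, deterministic. A model-free
half-time (first crossing of the midpoint between bleach depth and the
late plateau, the last 30 frames) is attached as a cross-check.
`compareGroups()` applies the equal-variance two-sample Student t-test
(Welch by flag) to half-times and immobile fractions. `simulateFrap()`
reproduces the acquisition geometry: 10 pre-bleach and 300 post-bleach
frames at 0.555 s.

# The synthetic nucleus simulator

Real acquisitions of this kind are not publicly deposited, so validation
rests on simulated nuclei with analytic ground truth.

A cell is a star-shaped radial surface
$r(u) = r_{ell}(u)\,(1 + w(u) + b(u))$ around an ellipsoid $r_{ell}$:

* **wrinkles** $w$: a random real spherical-harmonic field with equal
  expected power per degree over degrees 2..`wrinkleDegreeMax`, normalized
  to unit RMS and scaled by `wrinkleAmplitude`. Band-limited fields give
  smooth, controllable roughness with a known length scale.
* **blebs** $b$: Gaussian radial bumps (height 0.15 of local radius,
  width 0.3 rad) at random directions — local protrusions of the kind
  apoptotic and mutant nuclei show.
* **hotspots**: contiguous spherical-cap patches (not salt-and-pepper
  noise) covering `hotspotFraction` of the shell at `hotspotGain` times
  the shell intensity, mirroring the spatially coherent bright regions
  seen in senescent lamina.

Ground truth carries the exact radial function and its Gaussian curvature:
the closed form for unperturbed ellipsoids, otherwise central finite
differences of the parametric surface in a per-direction tangent frame
(step $10^{-3}$ rad; agreement with the ellipsoid closed form is asserted
to 0.01%). Surfaces whose sampled relief would self-intersect (relief
below 0.1) are rejected at generation.

`rasterizeNucleus()` paints shell voxels (within `shellThickness` of the
surface, measured radially) at the lamina intensity, the interior at the
nucleoplasm intensity (ratio `laminaToNucleoplasmRatio`), exterior zero.
The radial function is tabulated on a 257×513 polar grid and bilinearly
interpolated per voxel — the surface is band-limited, so the table is
accurate to about a nanometre while keeping rasterization fast.
`applyMicroscope()` then applies anisotropic Gaussian blur (default sigma
250 nm axial / 120 nm lateral, the elongated confocal point-spread
shape), a Poisson photon draw (`photonScale` counts per intensity unit),
Gaussian read noise, and a constant background. All randomness flows
through explicit seeds; identical seeds give identical stacks.

**Templates.** `phenotypeTemplates()` fixes the three study conditions:

| parameter | fresh | senescent | apoptotic |
|---|---|---|---|
| semi-axes (nm) | 2000/1700/1400 | 1900/1700/1450 | 1800/1650/1500 |
| wrinkle amplitude | 0.01 | 0.08 | 0.16 |
| wrinkle degrees | ≤6 | ≤8 | ≤10 |
| blebs | 0 | 0 | 4 |
| hotspot fraction / gain | 0 / 1 | 0.2 / 2 | 0.1 / 1.5 |
| shell/nucleoplasm ratio | 4.5 | 2.5 | 2.8 |
| shell thickness (nm) | 250 | 250 | 250 |

The geometry is deliberately scaled down (~20 µm³ nuclei on ~50 nm grids
of roughly 100–150 voxels per axis) so a full cohort simulates in minutes;
all three descriptors are scale-invariant, so this changes compute, not
biology. The senescent template encodes the published *direction* of
change — lamin redistribution lowers the shell/nucleoplasm contrast
(2.5 vs 4.5), hotspots raise skewness, moderate wrinkling raises
curvature; the original study gives no quantitative shell geometry, so
these are the package's own choices, fixed here once. Per-cell parameters
are jittered log-normally (relative SD `jitter`, default 0.05) around the
template.

**What the simulator does not emulate:** chromatin texture and
intranuclear lamin bodies (their effect enters only through the intensity
normalization), realistic confocal PSF side lobes, depth-dependent
attenuation, multi-nucleus fields, fixation artifacts. Passing the
simulation-based checks therefore demonstrates the pipeline's internal
correctness and sensitivity to shape/intensity redistribution of the kind
described — not performance on any particular real acquisition.

# Numerical choices and degenerate inputs

* Isotropy means spacings equal within 0.1%; all stack geometry is
  voxel-centred and 0-based.
* Otsu runs on 256 levels of the smoothed volume; thresholds are
  reproducible for identical input.
* A perfectly constant normalized-intensity distribution (only possible
  on noiseless synthetic shells) is recorded as skewness 0 by
  `computeFeatures()`; the standalone `featureSkewness()` raises an error
  on zero variance, as an explicit contract.
* The FRAP profile fit searches $\log\tau$ over $[10^{-4}, 10^{3}]$ times
  the trace span with tolerance $10^{-10}$; a flat post-bleach trace gives
  mobile fraction 0 and an uninformative $\tau$; a trace already at 1
  gives immobile fraction 0.
* Mesh orientation is fixed by the sign of the divergence-theorem volume;
  Euler characteristic 2 is asserted for every successful mesh.

# Validation problem sizes

The shipped checks use: 10242-vertex ground-truth meshes for the
curvature oracles; a simulated cohort of 25 fresh + 33 senescent-labeled
(2 of them drawn from the apoptotic template as planted contamination) +
25 apoptotic cells for the population-level checks; N = 200 points for
the Bayes-error calibration of the LOO estimator; 50 null replicates for
the permutation-test size; and 20 noisy traces for FRAP recovery. These
sizes were chosen so the entire validation runs comfortably on a laptop
while keeping every binomial/stochastic tolerance meaningful.

# Limitations

* Absolute descriptor values depend on conventions (normalization
  constants, probe depth, mesh resolution) that differ from the original
  implementation's unpublished internals by monotone per-feature
  transforms; cross-study comparisons should therefore use consistent
  settings, and classification results (which are invariant to such
  monotone rescalings in practice) rather than raw feature values.
* Ray-cast extraction underestimates the area and curvature of deeply
  re-entrant folds (traced at their outermost crossing).
* The FRAP module fits a single-component recovery; diffusion-coupled or
  multi-component kinetics are out of scope.
* Touching nuclei are not separated; one stack is assumed to contain one
  nucleus.
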