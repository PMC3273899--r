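# LaminaShape

Quantification and classification of 3D nuclear lamina shape from confocal
Z-stacks, with a FRAP recovery-analysis module and a synthetic-nucleus
simulator for end-to-end validation.

## The problem

The shape of the nuclear lamina — the lamin A/B meshwork lining the inner
nuclear membrane — changes when cultured cells senesce, in myoblasts from
aged donors, in cells carrying lamin-gene mutations, and in apoptosis:
smooth elliptical shells become wrinkled, locally folded, and show lamin
redistributed into the nucleoplasm. LaminaShape makes those changes
quantitative. It is aimed at cell biologists and imaging scientists who
have per-nucleus confocal stacks (or want to validate such a pipeline on
simulated data) and need an objective, per-cell readout of lamina shape
and a statistically controlled population classification.

## The method

For each nucleus the package:

1. resamples the anisotropic stack to an isotropic grid (natural cubic
   splines, `resampleIsotropic`),
2. segments the lamina as a closed triangulated surface (smoothing → Otsu
   threshold → largest 3D component → closing → cavity fill → ray-cast
   surface extraction with sub-voxel refinement, `segmentLamina`); cells
   whose contour cannot be completely traced are excluded, with a reason,
3. computes three dimensionless descriptors (`computeFeatures`):
   * **intensity** — mean lamina intensity normalized by the whole-nucleus
     mean,
   * **skewness** — g1 = m3 / m2^(3/2) of the normalized intensity
     distribution,
   * **curvature** — area-weighted mean |K| (Gaussian curvature from local
     quadric fits) times R_eq², equal to 1 for a perfect sphere,
4. classifies labeled populations with a pairwise Fisher linear
   discriminant, w ∝ Sw⁻¹(μ₁ − μ₂) with midpoint offsets, evaluated by
   leave-one-out cross-validation; the error carries the binomial
   standard deviation sqrt(e(1−e)/N) and a label-permutation p-value
   (`loocvError`, `permutationP`).

The FRAP module double-normalizes bleach-region time series and fits
I(t) = I₀ + A(1 − e^(−t/τ)), reporting T/2 = τ ln 2 and the immobile
fraction, with equal-variance t-tests between region groups
(`normalizeTrace`, `fitRecovery`, `compareGroups`).

Because no raw acquisitions of this kind are publicly deposited, the
package ships a simulator (`phenotypeTemplates`, `makeSurface`,
`rasterizeNucleus`, `applyMicroscope`, `simulatePopulation`) that builds
GFP-lamina-like shells — ellipsoids with spherical-harmonic wrinkles,
blebs, and hotspot patches, imaged with anisotropic blur and shot noise —
with analytic ground truth for every downstream stage. See the methods
vignette (`vignettes/lamina-quantification.Rmd`) for models, parameters
and design rationale.

## Worked example

```r
library(LaminaShape)

# simulate a small two-population experiment and quantify it
cells <- simulatePopulation(phenotypeTemplates()[c("fresh", "senescent")],
                            nPerLabel = 10, seed = 11)
feats <- lapply(cells, function(cl)
    computeFeatures(cl$stack, cellId = cl$cellId, label = cl$label))
tab <- featureTable(feats)
aggregate(tab[c("intensity", "skewness", "curvature")],
          list(tab$label), mean)
#>     Group.1 intensity  skewness curvature
#> 1     fresh  1.491434 0.4683151  1.168213
#> 2 senescent  1.339933 1.2481484  2.128305

ds <- populationDataset(tab)
res <- loocvError(ds)
res@errorRate; res@errorSD
#> [1] 0
#> [1] 0
```

The senescent template redistributes lamin into the nucleoplasm and adds
hotspots and wrinkling, so its mean normalized intensity falls below the
fresh population while skewness and curvature rise — the published
direction of change — and the two simulated populations separate with
zero leave-one-out error at these settings. On a sphere the curvature
descriptor is 1 by construction; wrinkled senescent-like shells here sit
around 2.

A YAML-driven end-to-end run (simulate → segment → features → classify,
with per-cell logs and exclusion reasons) is available as
`runPipeline("config.yaml")`, and `inst/scripts/lamina-cli.R` exposes
`simulate` / `segment` / `features` / `classify` / `frap` / `run`
subcommands for shell use.

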