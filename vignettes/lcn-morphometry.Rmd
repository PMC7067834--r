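---
title: "Quantifying the lacuno-canalicular network: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lacuno-canalicular network: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnmorph)
```

## The problem

Osteocytes live in ellipsoidal cavities (lacunae, ~17 × 9 × 5 µm in human
cortical bone) connected by sub-micron channels (canaliculi, 200–500 nm
diameter). Quantifying this lacuno-canalicular network (LCN) from 3D
gray-level volumes requires segmenting two pore populations three orders of
magnitude apart in volume, inside the same image, and the measured
canalicular parameters depend strongly on the voxel size: a 120 nm voxel
cannot resolve a 300 nm channel the way a 30 nm voxel can. `lcnmorph`
implements the full measurement chain — segmentation, dual-resolution
registration, morphometry, and paired statistics — together with a phantom
generator that provides exact ground truth, so every stage is validated
without access to beamline data.

All volumes follow one convention: arrays indexed `[x, y, z]` (1-based, as
natural in R), isotropic voxel size in nm, voxel centres at
`(i − 1/2)·h` µm, pores darker than matrix, crops specified by a 0-based
origin voxel plus a size.

## Segmentation of lacunae

The lacunar chain is median filter → hysteresis threshold → size split →
labeling.

* **Median radius.** The filter's job is to erase structures of canalicular
  calibre so that the subsequent thresholding cannot connect lacunae through
  canaliculi. A kernel must span the structure it should remove, so the
  default radius scales with voxel size as `max(1, ceiling(150 nm / h))` —
  radius 1 at 120 nm and above, radius 3 at 60 nm, radius 5 at 30 nm.
  Lacunae, tens of voxels across at any of these sizes, pass through with
  their interiors untouched.
* **Hysteresis orientation.** The two thresholds follow the dark-object
  convention: voxels `≤ t_seed` are high-confidence pore seeds, and the mask
  keeps every voxel `≤ t_keep` that is 26-connected to a seed through voxels
  `≤ t_keep`. `hysteresis_segment(v, t, t)` degenerates to plain
  thresholding, and raising `t_keep` can only grow the mask — both are
  tested properties. Default thresholds are the 0.2 % and 2 % gray
  percentiles of the filtered volume; real acquisitions vary in contrast, so
  these are configuration, not constants.
* **Haversian canals** are separated purely by component volume
  (default cutoff 2000 µm³ — an order of magnitude above a large lacuna,
  orders below a vascular canal) and excluded from bone volume:
  `BV = VOI − canals`. Labels are assigned in decreasing volume order with
  raster-scan tie-break, making outputs reproducible.
* **Connectivity** is 26-neighbour everywhere for pore objects, the choice
  that best preserves thin diagonal structures.

## Segmentation of canaliculi

* **Vesselness.** A Frangi-form response computed from the eigenvalues
  `|λ1| ≤ |λ2| ≤ |λ3|` of the Gaussian-smoothed Hessian, γ-normalized by
  σ², with the plate discriminant `Ra = |λ2|/|λ3|`, blobness
  `Rb = |λ1|/√|λ2 λ3|` and strength `S`; sensitivities default to
  α = β = 0.5 and `c` = half the per-scale maximum strength (data-driven).
  The volume is inverted internally so dark channels become bright ridges;
  voxels failing the bright-ridge sign test (λ2 or λ3 > 0) are zeroed, as
  are voxels whose strength is at numerical-noise level (relative floor
  1e-8 of the gray range) so homogeneous regions respond exactly 0.
  Smoothing is FFT-based with edge-replicated padding of 3σ. Scales default
  to 100/150/250 nm — the physiological canalicular radius range — clipped
  to resolvable values (σ ≥ h/2). On an ideal 150 nm-radius tube the
  response peaks within one grid step of the radius (tested); fixing `c`
  rather than the data-driven default is needed to observe that peak, since
  the adaptive `c` self-normalizes the maximum.
* **Initialization** thresholds the vesselness map at the Kapur
  maximum-entropy cut (256 bins, ties to the lowest cut).
* **Variational region growing.** The functional is a concrete two-region
  instantiation: gray-level data term with region means plus a linear
  vesselness prior, `E(Ω) = αΣ_in(I−μ_in)² + αΣ_out(I−μ_out)² − βΣ_in V`,
  no curvature term. Sweeps visit both sides of the 6-neighbour boundary
  and flip every voxel whose individual flip lowers `E` at the current
  means; because the data term is separable given the means, a sweep of
  such flips followed by re-estimating the means strictly decreases `E`, so
  convergence is guaranteed and the energy trace is asserted non-increasing
  in the tests. With defaults α = 1, β = 0.5 this fills intermediate-gray
  gaps in tubes (the reconnection behaviour the stage exists for) without
  inflating noise: on a phantom with 2.5-voxel tubes and 5 % noise, Dice
  overlap with ground truth rises from ~0.67 (initialization) to ~0.95
  after growing. An empty initialization is returned unchanged — a
  documented degenerate case.
* Canaliculi are kept disjoint from lacunae (lacunar voxels are excluded),
  so the two porosities add exactly to the LCN porosity.

## Registration

The two acquisitions of one site differ by a pure translation at a known 4×
scale factor, so registration reduces to phase correlation: block-mean
downsample the fine volume (the mean, rather than decimation, was chosen for
its noise averaging; the choice only has to be consistent), zero-pad it at
the origin corner to the coarse grid, and take the argmax of the inverse
transform of the unit-normalized cross-power spectrum. Corner-origin padding
makes the peak index directly the crop origin; indices above half the grid
are circular and are reduced modulo the grid before cropping. Offsets are
integer coarse voxels — no sub-voxel fit, matching a workflow that crops
whole voxels. The spectrum normalization uses a machine-epsilon-scaled
magnitude floor; it makes the correlation invariant to affine gray rescaling
up to the DC bin (whose sign follows the means). Recovery is integer-exact
on noise-free phantom pairs across random offsets including beyond-half-grid
ones, and remains exact at Gaussian noise of 20 % of the pore/matrix
contrast provided the scene carries realistic structure density; with only a
handful of weak features the whitened spectrum is noise-dominated and the
peak can move — scene richness, not the estimator, is the limiting factor.

## Morphometry

* **Voronoi cells** are influence zones of lacuna *objects*: each voxel
  joins the lacuna with the smallest exact Euclidean distance to any of its
  voxels (per-label distance transforms; ties to the lowest label). Object
  distance, not centroid distance, is the reading of "local environment"
  appropriate for extended, elongated lacunae. Cells partition the domain,
  so ΣCell.V equals the VOI volume exactly in voxel counts.
* **Ellipsoid fits** use the second-order moment matrix with the
  solid-ellipsoid relation `L_i = 2√(5 λ_i)` and a `h²/12` within-voxel
  correction; degenerate (coplanar) voxel sets are rejected by a rank test
  before that correction is added. Over 50 random ellipsoids with axes
  4–25 µm digitized at 60 nm the median axis-length error is below 0.01 %, and
  fits are rotation-invariant to digitization tolerance.
* **Surface area** is a 13-direction Crofton estimator: boundary crossings
  counted along the 3 axis, 6 face-diagonal and 4 body-diagonal lattice
  directions, combined with isotropic quadrature weights,
  `S = 4 h² Σ_k c_k T_k / |v_k|`. A digitized 5 µm-radius sphere reads
  within 0.2 % of 4πr² (naive face counting would be ~50 % high).
* **SMI** is `6 V S′ / S²` with `S′` the surface-area derivative under
  dilation. Estimating `S′` needed care: a half-voxel dilation adds no
  voxels at all, a single finite difference against `S(0)` is biased
  because discrete dilations carry a constant effective-radius offset that
  the undilated surface lacks, and a sparse three-point rule amplifies the
  ~0.1-voxel wiggle of individual dilation radii. The estimator therefore
  dilates with the exact Euclidean distance transform at a ladder of radii
  (0.5–4 steps of 2 voxels, quarter-step spacing), fits the Steiner
  polynomial — `S(r)` is exactly quadratic for convex bodies — by least
  squares, and takes its derivative at zero. Digitized reference solids at
  120 nm then read 3.93 (sphere, ideal 4), 3.06 (cylinder, ideal 3) and
  0.23 (plate, ideal 0); the plate's residual is the genuine edge
  contribution of a finite 30 × 30 × 0.36 µm slab plus digitization, not
  estimator bias.
* **Ca.N(r)** counts 26-connected patches of the canaliculi mask
  intersected with a one-voxel-thick *analytic* shell: the fitted ellipsoid
  dilated by adding `r ± thickness/2` to each semi-axis. Patch counting
  equals crossing counting for tubes transversal to the shell. On phantoms
  with spherical lacunae (where shell distance equals arc length) straight
  radial tubes return the constructed count at all seven default distances
  (1.2–12 µm) and bifurcating tubes double past the branch; the analytic
  shell also reproduces, component for component, the brute-force
  morphological dilation of the voxel lacuna that it replaces. Counts are
  attributed to a lacuna globally (any canal voxel on its shell), not
  restricted to its Voronoi cell; a configuration flag could restrict this,
  but global attribution is the natural reading of "crossing the bounding
  surface". Ca.N is always computed on the fitted ellipsoid, also for
  non-ellipsoidal lacunae — an approximation inherited from the analytic
  dilation, noted here once.
* **Lc.S** is computed on the segmented object as-is, canalicular-junction
  protuberances included; smoothing before measuring is deliberately left
  out of the default path.

## Paired resolution statistics

Per parameter, the fine/coarse comparison reports the mean of per-sample
relative differences (`mean(100·(f−c)/f)` — averaging per-sample ratios,
not differencing means), a decision-rule test (Kolmogorov–Smirnov normality
on each group with estimated moments — a Lilliefors-style usage, so the
normality p-values are approximate — plus an F-test of variance
homogeneity; all p > 0.05 selects the paired t, anything else the Wilcoxon
signed rank), and Spearman R² with OLS slope (coarse on fine) and a Fisher
r-to-z p-value; "good correlation" flags R² > 0.5 with p < 0.05, and 0.05
is the significance level throughout. The branch taken and the reason are
returned with every result. Degenerate inputs are explicit: identical
groups report p = 1 flagged, an exactly constant nonzero shift reports a
diverging t with p = 0 flagged.

## The phantom generator

Scenes are continuous-domain: ellipsoidal lacunae placed by rejection
sampling (bounding-sphere non-overlap), capsule canaliculi growing radially
from the lacunar surface with optional bifurcations at prescribed arc
lengths (two children tilted ±25° about a random perpendicular axis), and
gray levels assigned at rasterization with 3³-supersampled partial-volume
fractions in a boundary band, Gaussian noise added last, plus optional
salt-and-pepper impulses to exercise the median filter. Defaults are the
realistic operating point: lacunar axes 17.2 × 9.4 × 4.8 µm (anisotropy
close to 4:2:1), ~7 lacunae in a 61.44 µm cubic field (≈3 × 10⁴ mm⁻³), 80
primary canaliculi per lacuna of 300 nm diameter, matrix/pore contrast 1
with σ = 0.1 noise. Validation scenes scale these down and say so.

What the phantoms emulate: dark-pore/bright-matrix contrast, partial-volume
loss of sub-voxel channels (the mechanism behind resolution bias),
co-located two-resolution acquisitions with integer offsets, branching.
What they do not: phase-contrast fringes, detector blur, ring artifacts,
curved or anastomosing canaliculi, spatially correlated noise. Passing
tests therefore demonstrate correctness of the measurement chain, not
robustness to every beamline artifact; tortuosity and branch statistics of
real canaliculi are unknown free parameters of the generator, and no claim
about real bone follows from their settings.

## Validation sizes and costs

The test suite and the acceptance script run entirely on generated
phantoms, sized so the whole chain stays comfortable on a single CPU:
registration trials use 64³ coarse grids with 64³ fine rasters (15.36 µm
scenes at 60/240 nm); the moment-fit study digitizes 50 ellipsoids at
60 nm; counting phantoms use 34 µm scenes at 240 nm (142³); and the
dual-resolution pipeline comparison runs a 23.04 µm scene with a 192³ fine
raster at 60 nm against its 96³ coarse raster at 240 nm — the same 4×
voxel-size ratio as a 30 vs 120 nm protocol, with 0.3 µm tubes that are
well-resolved at the fine and sub-voxel at the coarse size. These sizes are
the package's validation choices; all stages accept larger volumes, with
memory bounded by a small multiple of one volume for ≤512³ grids.

## Known limitations

Touching lacunae are not split (no watershed); lacuna orientation relative
to anatomical axes is not computed; no rotation or scale registration (the
dual-resolution protocol guarantees pure translation); no network/graph
topology of the LCN; canalicular diameters are not estimated per channel.
TIFF I/O is 32-bit float restricted to [0, 1] grays — MHD/raw is the
lossless container.
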