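# lcnmorph

Segmentation, registration and 3D morphometry of the bone
**lacuno-canalicular network (LCN)** — the pore system of osteocyte lacunae
(ellipsoidal cavities of roughly 17 × 9 × 5 µm) and canaliculi (channels of
200–500 nm diameter) embedded in mineralized bone matrix. The package is
aimed at researchers quantifying the LCN in 3D gray-level volumes from
high-resolution X-ray (nano-)CT, where pores appear darker than the matrix,
and at methodologists studying how the voxel size of an acquisition biases
those measurements.

## What it computes

**Segmentation.** Lacunae: 3D median filter → dual-threshold hysteresis
segmentation of dark pores → removal of Haversian-scale canals by
connected-component size → volume-ordered labeling. Canaliculi: multiscale
Hessian vesselness (Frangi-type; eigenvalues `|λ1| ≤ |λ2| ≤ |λ3|` of the
Gaussian-scale Hessian combined through plate/blob/strength terms) →
maximum-entropy (Kapur) thresholding of the vesselness map → variational
region growing minimizing

    E(Ω) = α Σ_{x∈Ω} (I(x) − μ_in)² + α Σ_{x∉Ω} (I(x) − μ_out)² − β Σ_{x∈Ω} V(x)

(two-region gray-level data term plus vesselness prior, which fills gaps and
reconnects tubes broken by noise) → small-component removal.

**Registration.** A fine-voxel acquisition is located inside a coarse one of
the same site by FFT phase correlation of the block-mean-downsampled,
zero-padded fine volume against the coarse volume,
`p = F⁻¹[ conj(F₂) F₁ / |conj(F₂) F₁| ]`; the argmax of `p` is the
integer-voxel crop origin of the site-matched VOI.

**Morphometry.** Per-lacuna Voronoi tessellation (exact Euclidean distance
to the lacuna *object*), ellipsoid fits from second-order moments
(`L_i = 2√(5 λ_i)`), Crofton 13-direction surface areas, structure model
index from the surface-area derivative under dilation, and the standard
parameter tables: Lc.N, Lc.TV, BV, Lc.TV/BV, Lc.N/BV, Lc.V, Cell.V,
Lc.V/Cell.V, Lc.S, Lc.L1–L3, anisotropy ratios, Lc.SMI; Ca.TV, LCN.TV and
their porosities, Ca.V per Voronoi cell, and the ramification profile
Ca.N(r): the number of canaliculi crossing an *analytically* dilated
ellipsoidal shell (semi-axes `L_i/2 + r`) at distances r = 1.2 … 12 µm from
the lacunar surface.

**Resolution comparison.** Paired fine/coarse statistics per parameter: mean
relative difference, a Kolmogorov–Smirnov + F-test decision rule choosing
paired t-test or Wilcoxon signed rank, and Spearman R² with OLS slope and
Fisher r-to-z p-values.

**Phantoms.** A synthetic scene generator (non-overlapping ellipsoidal
lacunae, capsule canaliculi with optional bifurcations, partial-volume
rasterization at any voxel size, Gaussian/speckle noise, co-located
fine/coarse pairs with known offsets) provides ground truth for every stage;
all tests run on phantoms generated in code.

## Worked example

```r
library(lcnmorph)

# a small synthetic tissue: 2 lacunae, 12 canaliculi each, 11.52 um domain
cfg <- phantom_config(domain_um = rep(11.52, 3), n_lacunae = 2,
                      lacuna_axes_um = c(3.5, 2, 1.4),
                      lacuna_axes_sd_um = c(0.2, 0.15, 0.1),
                      n_canaliculi = 12, canaliculi_radius_um = 0.15,
                      canaliculi_length_um = 4, noise_sigma = 0.05)
scene <- build_scene(cfg, seed = 11)
vol <- rasterize_scene(scene, voxel_size_nm = 60)    # 192^3 voxels

run <- lcn_config(t_seed = 0.25, t_keep = 0.5,
                  min_lacuna_volume_um3 = 1, max_lacuna_volume_um3 = 1e5,
                  min_component_voxels = 27, r_grid_um = c(1.2, 2.4))
q <- quantify_volume(vol, run)
q$lacunae$summary[c("Lc.N", "Lc.TV/BV", "Lc.L1", "Lc.L2", "Lc.L3")]
#>  Lc.N Lc.TV/BV    Lc.L1   Lc.L2    Lc.L3
#>     2 0.562682 3.153505 1.97109 1.339508
q$canaliculi$ca_n
#>  r_um Ca.N Ca.N/Lc.S
#>   1.2 12.5 0.8667620
#>   2.4 12.0 0.8351938
```

Both lacunae are found; the recovered mean axis lengths track the generated
3.5 × 2 × 1.4 µm ellipsoids (hysteresis segmentation at these thresholds
keeps the high-confidence core, so lengths read slightly short of the
generated envelope); Lc.TV/BV is the segmented lacunar pore fraction of the
VOI in percent; and essentially all 12 canaliculi per lacuna are counted
crossing the shells at 1.2 and 2.4 µm (the 12.5 at r = 1.2 µm is one
near-surface noise patch on one lacuna's shell). For a
dual-resolution comparison, `raster_pair()` + `quantify_pair()` register the
two volumes, crop the matched VOI and quantify both; `compare_tables()`
builds the per-parameter paired report.

A thin command-line driver with `phantom`, `register`, `quantify`, `compare`
and `run-all` subcommands is installed at `inst/cli/lcnmorph`.

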