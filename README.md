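# lacunaCT

Osteocyte lacunar morphometry and relative mass-density analysis for
synchrotron phase-contrast micro-CT of cortical bone — built for
researchers who quantify bone at the cellular scale (osteocyte lacunae,
vascular canals, matrix mineralization) from propagation-based
phase-contrast scans, and for anyone who needs a fully synthetic,
ground-truthed testbed for such pipelines.

Cortical bone imaged at 350 nm isotropic voxels shows osteocyte lacunae
(~50–1000 µm³ cavities housing osteocytes), vascular canals, and a
spatially heterogeneous mineralized matrix. The package implements the
complete analysis chain used to compare such microstructure across
anatomical sites (tibia, femur, jaw) and pathology (bisphosphonate-related
osteonecrosis of the jaw, BRONJ):

1. **Simulation / acquisition** — parallel-beam radiographs of a
   (δ, β)-valued volume with angular-spectrum Fresnel propagation
   (in-line phase contrast) at E = 16.874 keV, D = 282 mm, δ/β = 199,
   1201 projections / 360°;
2. **Phase retrieval** — Paganin's single-distance method: per
   projection, the Fourier filter
   `1 / (1 + λD(δ/β)|k|²/4π)` applied to I/I₀ followed by `−log`;
3. **Reconstruction** — slice-wise ramp-filtered back projection;
4. **Segmentation** — multi-class Otsu thresholds, sample-support
   masking, 3D 26-connected labelling, the inclusive [50, 1000] µm³
   lacuna gate, 3 equal VOIs along the core with border-lacuna removal;
5. **Morphometry** — per VOI: N.Lc, Lc.V_med, Lc.V_var, Lc.TV/BV,
   N.Lc/BV, Lc.Dist₅₀ (median Euclidean distance of bone to the nearest
   lacuna), and canal metrics Ca.V/BV, Ca.S/BV, Ca.S/Ca.V on a
   5×-coarsened pore mask cleaned of objects < 1600 voxels (8575 µm³);
6. **Density** — the unit-area relative mass-density distribution (rDMD)
   within bone and its five BMDD-style descriptors (mean, peak, FWHM, and
   the P = 0.005 low/high percentiles);
7. **Statistics** — Jarque–Bera normality screening, one-way ANOVA with
   Bonferroni post hoc pairwise tests at α = 0.05, and percent contrasts
   of group means.

Raw scans of this kind are not publicly deposited, so the package ships a
seeded phantom generator (`site_phantom_spec()` / `generate_phantom()`)
producing bone cores with known per-lacuna ground truth; every stage is
tested against phantoms and independent brute-force oracles. All
densities are relative (arbitrary units): the phase-retrieval scaling is
uncalibrated by construction.

## Worked example

```r
library(lacunaCT)

sp  <- site_phantom_spec("jaw_control", grid_shape = c(192L, 192L, 192L),
                         seed = 42)
ph  <- generate_phantom(sp)          # volume + ground truth
seg <- segment_volume(ph$volume)     # Otsu, labels, gate, VOIs
cat("thresholds (a.u.):", round(seg$thresholds, 1), "\n")
voi_morphometry(seg, ph$volume$voxel_size)
```

prints the Otsu thresholds separating air | glue | bone and the per-VOI
metric table:

```
thresholds (a.u.): 50.5 469.3
  voi N.Lc Lc.V_med_um3 Lc.Dist50_um Lc.TV_BV_pct N.Lc_BV_1000mm3 Ca.V_BV_pct
1   1    1       204.77        21.54         0.34           16.79        7.48
2   2    2       290.76        16.00         0.98           33.63        7.50
3   3    0           NA           NA         0.00            0.00        6.86
```

Three lacunae survive the size gate and border removal in this small
(67 µm)³ core; their median volumes sit in the expected jaw range, the
lacunar number densities bracket the generation target of 27 × 10³ mm⁻³,
and the canal occupies ~7% of bone volume as configured. The density
descriptors of the same sample:

```r
dd <- compute_rdmd(ph$volume, seg$bone_mask)
rdmd_descriptors(dd)
#> rDMD: mean 1187, peak 1173, FWHM 111, low 1070, high 1330 a.u.; bimodal: TRUE
```

The bimodal flag reflects the two-mode (osteonal vs interstitial) matrix
field of the phantom.

The numbered scripts under `analysis/` run the same chain as a cohort
study: `01_simulate_phantoms.R` (four groups × three samples),
`02_reconstruction_demo.R` (acquisition → retrieval → FBP round trip),
`03_segment_morphometry.R` (per-VOI table), `04_group_statistics.R`
(ANOVA + Bonferroni report and density contrasts), writing their tables
under `results/`.

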