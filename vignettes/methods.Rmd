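---
title: "Methods: synthetic phase-contrast µCT analysis of cortical bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phase-contrast µCT analysis of cortical bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lacunaCT)
```

# Scope

`lacunaCT` re-implements, end to end, a 3D analysis of cortical bone imaged
by synchrotron in-line phase-contrast micro-tomography at 350 nm isotropic
voxels: osteocyte lacunar morphometry, vascular-canal morphometry, and
descriptors of the relative mass-density distribution (rDMD) inside the
mineralized matrix, compared across anatomical-site / pathology groups
(tibia, femur, healthy jaw, bisphosphonate-related osteonecrotic jaw).
Because no per-sample scan data are publicly available for this kind of
study, the package is built around a synthetic phantom generator with exact
ground truth; every downstream stage is validated against phantoms and
against independent brute-force oracles.

# The imaging model

## Acquisition

A parallel monochromatic beam (energy $E$ = 16.874 keV, wavelength
$\lambda = hc/E \approx 0.0735$ nm) traverses the object, described by its
complex refractive index $n = 1 - \delta + i\beta$. After free-space
propagation over the sample–detector distance $D$ = 282 mm, the recorded
flat-corrected intensity contains edge-enhancing interference fringes
(propagation-based phase contrast). The simulator computes, per projection
angle, the line integrals of $\delta$ and $\beta$, forms the complex
transmittance, and propagates it with the angular-spectrum Fresnel
propagator using the paraxial transfer function
$H(f) = \exp(-i\pi\lambda D f^2)$ on a field zero-padded to twice the
detector with vacuum fill (this avoids wrap-around fringes; the choice is
internal to the simulator and pinned by a test against the closed-form
Fresnel edge solution).

The beamline that motivates the defaults used a focused (cone) beam; the
simulator deliberately uses parallel geometry, consistent with treating
voxels as isotropic 350 nm throughout the analysis. This is a documented
simplification — magnification effects are not modelled.

## Phase retrieval

Paganin's single-distance method assumes a homogeneous object
($\delta/\beta$ fixed; 199 for cortical bone at this energy) and retrieves
the projected thickness by a Fourier-domain low-pass filter applied to each
flat-corrected radiograph,

$$ T(x,y) \;\propto\; -\ln\, \mathcal{F}^{-1}\!\left[
   \frac{\mathcal{F}[I/I_0]}{1 + \frac{\lambda D (\delta/\beta)}{4\pi}|k|^2}
   \right], $$

with $|k| = 2\pi f$ the angular spatial frequency. Several equivalent
parameterizations circulate; the package fixes exactly this convention in
one place (`paganin_filter_value()`) and the tests pin it: the filter is 1
at DC and strictly below 1 elsewhere (a contraction).

At the full 282 mm distance and 350 nm pixels the near-field condition is
violated — the original acquisition had the same property, which is one
reason the reconstructed densities are only *relative*. The package
therefore validates retrieval quantitatively in near-field simulated
regimes (e.g. 30 mm), where the retrieved projected thickness of a
homogeneous ellipsoid matches analytic chord lengths within 3% RMS, and
makes no attempt to reproduce far-field bias.

## Reconstruction

Standard slice-by-slice filtered back projection with a band-limited ramp
(Ram–Lak) filter, zero-padded to the next power of two above twice the
detector width. Angles must be evenly spaced; a 360° set is handled by the
uniform weight $\pi/N$ over all views, which halves the contribution of
conjugate rays — tests confirm 180° and 360° reconstructions agree to
better than 1% RMS. Reconstructed values are in arbitrary relative units:
no absolute mass-density calibration exists anywhere in the package.

# The phantom generator

The generator renders what the analysis assumes about real scans, with
exact ground truth:

* **Geometry** — a cylindrical core (the drilled ~0.5 mm bone core) along
  the z (sample-length) axis, surrounded by air at −100 a.u.; a "glue"
  region at ~200 a.u. pooled at the bottom of the field of view outside
  the core, reproducing the three-population histogram (air / glue / bone)
  on which the 3-class Otsu threshold operates.
* **Matrix density** — columnar nearest-seed patches in the transverse
  plane, each assigned one of the configured density modes (default two
  modes ~80 a.u. apart, emulating osteonal vs interstitial tissue), plus
  per-mode Gaussian noise. A two-mode spec provably yields a bimodal
  histogram (tested).
* **Lacunae** — triaxial ellipsoids with uniformly random orientation.
  The field's literature gives no calibrated lacunar shape statistics, so
  the aspect ratios (default 1 : 0.7 : 0.4, a flattened prolate shape) are
  a free parameter and orientation is not a measured output. Volumes are
  drawn i.i.d. from a configurable distribution; site profiles use
  near-normal distributions for tibia (median 194 µm³) and femur (224 µm³)
  and a right-tailed mixture for jaw groups (10% of mass uniform on
  400–1000 µm³, main Gaussian component positioned so the mixture median
  hits the target, 277 µm³ for healthy jaw, 269 µm³ for BRONJ-like).
  Samples are confined to [20, 1500] µm³ so the 50/1000 µm³ segmentation
  gate is exercised from both sides. Placement is rejection sampling with
  exact voxel-level non-overlap (candidate inflated by one voxel so
  lacunae never touch) and a retry cap of 100× the requested count;
  lacunar porosity below ~1% keeps rejection cheap at realistic densities,
  and an overcrowded spec fails with a clear error.
* **Canals** — vertical cylinders spanning the core. The canal radius is
  derived from the site's target vascular porosity
  ($r = R\sqrt{t/(n(100+t))}$ for $n$ canals at porosity $t$% of BV),
  which keeps Ca.V/BV on target at any grid size.
* **Lacuna count** — derived from the site's target lacunar number density
  (38k, 20k, 27k, 23k per mm³ for tibia/femur/jaw-control/jaw-BRONJ) times
  the expected bone volume of the core.
* **Pore interiors** are set to the air level plus matrix-like noise, as
  pores image at near-air intensity.

Identical spec + seed gives bit-identical volumes (tested). Ground truth
includes the per-lacuna table (analytic $\tfrac{4}{3}\pi abc$ and voxelized
volumes, within 15% of each other for semi-axes ≳ 5 voxels), a per-lacuna
label volume, canal and matrix masks, and the noiseless density field.

What the phantoms do **not** emulate: the canalicular network (below
resolution at 350 nm), necrotic-tissue regions, ring or motion artifacts,
beam-hardening-like effects, spatially correlated noise, and the
far-field phase-retrieval bias of the real acquisition. Passing tests
therefore demonstrate correctness of the *analysis* under its stated
assumptions, not robustness of the acquisition model to real-scan
artifacts.

# Segmentation

1. **Thresholds** — multi-class Otsu on the volume histogram (256 bins),
   maximizing between-class variance by exhaustive search (pinned to a
   brute-force oracle). Default 3 classes (air/soft, intermediate
   glue-like, mineralized); the bone/pore split is the highest threshold.
2. **Support** — the analysis needs exterior air excluded from the pore
   domain, and the field's protocols rarely say how; the package computes
   the sample support as a morphological closing of the bone mask (ball,
   radius 10 voxels) followed by slice-wise hole filling transverse to the
   core axis. The closing alone cannot fill cavities whose inscribed ball
   exceeds its radius (~3.5 µm) — i.e. most lacunae and any canal — which
   is why the hole-filling step exists: interior cavities of any size
   belong to the support, while exterior air, which is border-connected in
   every transverse slice, never does.
3. **Labelling** — 3D connected components, default 26-connectivity
   (configurable 6/18/26; pinned to a flood-fill oracle either way).
4. **Lacuna gate** — object volume = voxel count × (0.35 µm)³; objects in
   [50, 1000] µm³ inclusive are lacunae ("smaller than 50 µm³ or larger
   than 1000 µm³" are strict exclusions, so equality retains); everything
   else feeds the canal analysis.
5. **VOIs** — 3 contiguous slabs along the core axis, sizes differing by
   at most one slice, remainder slices to the first slab(s)
   (deterministic tie-break).
6. **Border removal** — any lacuna with a voxel on an outer volume face or
   on a slice adjacent to a VOI interface may be truncated and is removed
   entirely; a lacuna spanning an interface is thereby removed from both
   VOIs. The gate is applied before VOI splitting and border removal,
   matching the order of the protocol's description (the original text
   does not resolve this ordering; the choice is fixed and tested).

# Morphometry

Per VOI: lacuna count N.Lc; median Lc.V_med and sample variance Lc.V_var
(n−1 denominator, reported in 1000 µm⁶) of lacunar volumes; lacunar
porosity Lc.TV/BV (%); lacunar number density N.Lc/BV (reported in
1000 mm⁻³); and Lc.Dist50, the median over bone voxels of the exact
Euclidean distance to the nearest lacunar voxel (µm) — the distance within
which half the mineralized tissue lies from the closest lacunar surface.
BV is the mineralized tissue excluding all pores.

The canal chain coarsens the full-sample pore mask by 5× (strict-majority
rule per 5³ block — the protocol says only "coarsening"; majority preserves
the expected volume fraction, and an any-voxel rule is available), removes
coarse objects below 1600 voxels (= 8575 µm³; boundary inclusive, 1600
survives), and computes Ca.V by voxel counting and Ca.S as the count of
pore voxels within one voxel Euclidean distance of the pore boundary
(pore-side convention; a bone-side flag exists because the original
wording is ambiguous) times the coarse face area. Running the clean at
sample level rather than per VOI is deliberate: at desk-scale fields of
view a canal crossing a VOI boundary would otherwise be fragmented below
the absolute 8575 µm³ threshold and vanish. Small non-lacunar pores do
enter the canal pipeline and are then removed by the cleaning, matching a
reading of "the segmented volumes" as the full pore mask.

# Density descriptors

The rDMD is the histogram of reconstructed intensities restricted to BV,
normalized to unit area. Default 256 bins spanning the 0.05th–99.95th
percentile range of the masked intensities: the range must contain the
0.5th/99.5th percentile descriptors in its interior, which a narrower
[1st, 99.9th] window cannot (values outside the range are clamped into the
end bins; their mass at this width is ≤ 0.1%). Descriptors: mean; peak
(centre of the maximal bin; ties return the lowest-intensity tied bin and
raise a flag); low and high at P = 0.005 and 1 − P by linear interpolation
of the cumulative curve; and FWHM between the outermost crossings of half
the global maximum. For bimodal distributions FWHM spans both modes — it
is computed exactly as defined, and a bimodality flag (more than one local
maximum after 5-bin smoothing) is reported rather than any alternative
width, since a whole-distribution FWHM is of debatable value for bimodal
data. Tolerances in the tests are stated in bin widths, making the binning
choice itself testable; descriptors are stable under bin doubling within
one bin width.

# Statistics

Per-group Jarque–Bera normality screening
($JB = \frac{n}{6}(S^2 + \frac{(K-3)^2}{4})$ with 1/n central moments,
p from $\chi^2_2$), one-way fixed-effects ANOVA across groups, and all
pairwise two-sided t tests with Bonferroni adjustment over the number of
pairs, significance at α = 0.05. Pairwise tests pool the variance across
all groups (the classical post hoc convention); a Welch variant is a flag.
Per-VOI values are treated as independent observations, mirroring the
ROI-level accounting of the original analysis — VOIs within a donor are in
truth correlated, and this limitation is inherited knowingly. Both
groupings (all four groups; site-only or BRONJ-vs-control subsets) can be
run by subsetting the input table; the package does not privilege either.
The chain's type-I error under a global null is verified to lie in
[0.03, 0.07] over 1000 replicates, and two-group power is checked against
a noncentral-F oracle.

Percent contrasts between group means are reported to one decimal:
with lacunar densities (in 1000 mm⁻³) of 27 for healthy jaw, 23 for
BRONJ and 20 for femur, the BRONJ group is 14.8% below the healthy jaw
and 15.0% above the femur.

# Numerical choices and problem sizes

* Energy→wavelength uses $hc$ = 1.23984 keV·nm.
* The EDT is the exact separable lower-envelope (Felzenszwalb–Huttenlocher)
  transform; connected components use an iterative BFS — both in C++.
* Morphological closing pads the volume with background before dilating so
  grid-face clipping cannot create spurious support.
* FBP interpolation is linear in the detector coordinate; projections are
  sampled at one-voxel ray steps with bilinear interpolation.
* Phantom studies in the tests and the reproduction script run at 96³–256³
  voxel grids with 1–2 replicates per condition — large enough that each
  256³ jaw-like core carries a realistic ~10–15 lacunae and a canal that
  survives the 8575 µm³ cleaning, while a full four-group cohort remains
  a desk-scale computation. At these counts the *realized* median lacunar
  volume of any single phantom fluctuates by more than 5% around the
  generator target, so parameter-recovery checks compare measured values
  against the phantom's realized ground truth (interior, in-gate lacunae),
  not against the nominal target; the nominal lacunar number density is
  still realized within 5% because the count is derived from the core's
  expected bone volume.
* Degenerate inputs fail loudly: empty bone mask, empty lacuna mask for
  spacing, zero-variance samples for JB/ANOVA, histograms with fewer
  populated bins than Otsu classes, non-positive intensities in retrieval.

# Known limitations

* Parallel-beam, noise-free-detector optics; no cone-beam magnification,
  ring artifacts, or photon statistics.
* Paganin retrieval is validated only in the near field; the package
  reproduces the method, not the far-field bias of the original data.
* Canal metrics at desk-scale fields of view are dominated by one or few
  canals; Ca.S/Ca.V is resolution-limited by the 5× coarsening, and the
  fields of view are far below a representative volume for the vascular
  network (as in the original study).
* Group statistics on synthetic cohorts inherit the VOI-independence
  assumption discussed above.
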