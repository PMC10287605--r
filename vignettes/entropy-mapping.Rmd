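---
title: "Local entropy mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local entropy mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemap)
```

## The model

Texture entropy condenses the disorder of an intensity distribution into a
single number; `lemap` instead computes it *locally*, producing a parametric
map that can be read like any other medical image. For a volume `V` with
integer intensities (Hounsfield units for CT), the map at voxel `x` is

$$H(x) = -\sum_i P_i(x)\, \ln P_i(x),$$

where `P_i(x)` is the relative frequency of intensity symbol `i` among the
`k^3` voxels of the cubic neighborhood centered on `x`. Symbols are
`floor(value / bin_width)`; with the default `bin_width = 1` every integer
HU value is its own symbol, which is the natural choice for CT where the
quantization already exists in the data. `H` is measured in nats (natural
logarithm) and obeys `0 <= H <= ln(k^3)`: 0 for a constant neighborhood,
the maximum when all `k^3` values are distinct. With `k = 5` the bound is
`ln 125 ≈ 4.83`, and realistic noisy tissue sits near saturation (~3.5–4
nats), because 125 samples of a ±10 HU distribution rarely repeat values.

The pipeline is: entropy map → Gaussian smoothing → (optional)
normalization. Each stage is a separate flag-tracked operation, and the
statistics layer can consume any stage. The default stage for statistics is
the smoothed, unnormalized map: smoothing suppresses the voxel-level jitter
of the raw map, while normalization rescales all values by a common factor
and therefore changes units rather than structure; whether to report
statistics in absolute nats or liver-relative units is a study-level choice
the package leaves open rather than hard-codes.

### Assumptions

* Intensities are (near-)integer valued, so symbol formation by flooring is
  faithful. For float data a user-chosen `bin_width` takes that role.
* The kernel is defined in voxels, not millimetres; anisotropic spacing is
  carried as metadata but not compensated. With strongly anisotropic
  reconstructions the effective neighborhood is anisotropic too.
* No tissue masking: kernels in air or at tissue interfaces are processed
  like any other, so interface voxels legitimately show high entropy.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `k` | 5 | voxels | kernel side; the 5×5×5 kernel is the trade-off between spatial resolution and noise smoothing (see the sweep below) |
| `bin_width` | 1 | HU | intensity units per symbol |
| `padding` | reflect | — | border rule; `exclude-border` marks the (k−1)/2 shell missing instead |
| `sigma` | 1 | voxels | Gaussian smoothing SD |
| `z_cutoff` | 1 | liver SD | hyper/hypo threshold around the liver mean |
| `rim_width` | 3 | voxels | Euclidean boundary-shell thickness for pattern rules |
| `n_bins` | 64 | — | bins of the global (whole-VOI) entropy |

**Log base.** Natural log throughout the map; the global VOI entropy
exposes base e or 2. **Normalization** divides by the liver mean (making
the liver reference exactly 1); a subtraction variant exists behind
`method = "subtract"` for users who prefer additive offsets. Division is
the default because entropy magnitudes scale multiplicatively with symbol
richness, and a ratio yields a unit-free "times the parenchyma" reading.

### Numerical choices

* The optimized C++ map accumulates `-p ln p` over symbols in ascending
  order with extended precision, making it *bit-identical* to a per-voxel
  R evaluation of `kernel_entropy()` — the oracle-equivalence tests assert
  `identical()`, not approximate equality.
* Reflect padding mirrors including the edge voxel, so corner kernels see
  plausible tissue rather than zeros.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7). Variance and SD use the population (1/N) convention:
  a VOI is the complete population of its voxels, and this makes
  `rms² = mean² + variance` an exact identity.
* Crossing counts are defined on the in-VOI voxel sequence in canonical
  array scan order (first axis fastest): `n_mean_crossings` counts strict
  sign changes about the VOI mean and `n_zero_crossings` the same on the
  mean-centered sequence. A histogram has no time axis, so *some* sequence
  convention is required; this one is deterministic, and it makes the two
  counts equal by construction — consistent with them always coinciding in
  practice when computed from histogram software.
* Smoothing uses a separable discrete Gaussian truncated at 4σ, with
  missing-border voxels excluded from the support (weights renormalized),
  so `exclude-border` maps do not bleed `NA` into the interior.
* Mann–Whitney U is evaluated exactly when the combined sample size is at
  most 20 with no ties, otherwise by normal approximation with tie and
  continuity correction. P-values are reported uncorrected per statistic
  (a Benjamini–Hochberg option exists behind `adjust = "BH"`).
* Ties in the modal-class computation of the pattern rules break by the
  fixed order hypo < iso < hyper, so classification is deterministic.

## The pattern classifier

Voxels inside the tumor VOI are classed **hyper**/**iso**/**hypo** relative
to the liver reference: hyper above `mean + z·SD`, hypo below
`mean − z·SD`. The lesion label then follows fixed rules on three
fractions, each read volumetrically with a 75% threshold:

1. hyper fraction ≥ 0.75 and modal class ≥ 0.75 of the VOI →
   **homogeneous**;
2. otherwise, boundary-shell hyper coverage ≥ 0.75 → **peripheral_rim**
   when the core is ≥ 75% homogeneous and iso/hypo (subtype *complete*
   at coverage ≥ 0.999, else *incomplete*), **mixed** when the core is
   inhomogeneous;
3. otherwise **inhomogeneous**.

Homogeneity is checked before rim coverage so that a uniformly
hyper-entropic lesion — whose shell is trivially all-hyper — is not
mislabeled as a rim. An empty core (lesion thinner than the shell) is
flagged and treated as a homogeneous iso core, so classification proceeds
rim-only.

**Why a Euclidean shell of 3 voxels.** The shell is the residue of erosion
by a Euclidean ball, computed with an exact distance transform. Iterated
box erosion (Chebyshev distance) reaches `rim_width·√3` deep along
diagonals of a spherical lesion, diluting the rim measurement with core
voxels. The width default of 3 follows from signal geometry: a thin
anatomical rim of 1–2 tissue voxels appears in the map widened by part of
the kernel radius, i.e. as a band roughly 3 voxels deep; a much wider shell
again dilutes the rim, a 1-voxel shell misses most of the band. Both
`z_cutoff` and `rim_width` are exposed, and the per-lesion report always
carries the three fractions so a reader can audit any label.

## What the phantoms emulate — and what they do not

`generate_phantom()` builds a 64³, 1 mm-isotropic volume: liver background
of i.i.d. Gaussian HU (100 ± 10), one spherical lesion (radius 14 voxels,
60 HU — a hypodense metastasis-like target; radii below 5 voxels are
refused as too few voxels for stable statistics), two bright vessel
cylinders (+60 HU), and integer rounding throughout. Local entropy is
induced through local intensity variance: with integer symbols, a high-SD
region (35 HU) presents many distinct values per kernel and reads hyper;
a quiet region (5 HU) reads hypo relative to the 10-HU liver.

Two mechanisms keep the prescribed ground truth true *in the map*, not just
in the texture layout:

* **Partial-volume edge ramp** (`edge_ramp = 6` voxels): the mean HU
  crosses the lesion boundary on a linear ramp, emulating scanner
  point-spread blur. A hard 40-HU step would itself read as a
  hyper-entropic ring on *every* lesion — including the patterns defined by
  not having one — because a step inside a kernel is indistinguishable from
  texture.
* **Texture-margin erosion** (`texture_margin = 2` voxels): the entropy
  kernel dilates any textured region by its radius, so scattered blobs are
  laid down as the erosion of the target region; the realized hyper
  fraction of the map then tracks `scatter_fraction` (default 0.5) instead
  of overshooting it.

Pattern recipes: *homogeneous* = high-SD texture throughout;
*inhomogeneous* = smoothed-noise blobs covering ~50% of the lesion;
*peripheral rim* = high-SD shell of thickness 2 over a quiet core, with an
azimuthal gap over 15% of the circumference for the incomplete variant;
*mixed* = rim plus blobs in the core. The two-group cohort generator
shifts the heterogeneous-texture SD between groups (default 35 vs 15 HU)
as a stand-in for a response-associated texture effect.

The phantoms deliberately omit: anatomically shaped livers and lesions,
spatially correlated noise, beam hardening and other scanner physics,
respiratory motion, and contrast-phase variability. Passing the phantom
tests therefore demonstrates that the *computational chain* — map,
statistics, thresholds, geometry — behaves as specified under controlled
signal; it does not validate clinical discrimination on real CT, where
effect sizes, noise correlation and segmentation error differ.

## Kernel-size sweep

`run_sweep()` re-runs the pipeline over kernel sizes (default 3, 5, 7) on
regenerated cohorts and reports per-k wall time, a working-set proxy,
group-separation p-value of the tumor map-mean, and pattern-recovery
accuracy, as mean ± SD over repetitions (SD flagged undefined for a single
repetition). Wall time and memory are reported but never asserted — they
are hardware facts, not correctness claims. The grade-like discrimination
panel is emulated as binary-group separation on synthetic cohorts and is
labeled as such.

## Problem sizes used in the test suite

The shipped tests and the acceptance script run at sizes chosen to exercise
every code path at full 64³ study scale where the claim concerns the study
conditions (pattern recovery over 20 seeds × 5 patterns; the k ∈ {3,5,7}
sweep), and at reduced scale where the claim is statistical machinery only:
oracle equivalence on 16³ volumes (where exact brute force is cheap), the
type-I calibration on synthetic statistic vectors (n = 20/20, 200
repetitions), and the power study on 28³ phantom cohorts (SD 35 vs 15,
n = 10/10, 50 repetitions) — the texture effect, not the grid, carries that
result.

## Known limitations

* The global VOI entropy uses equal-width binning over the in-VOI range; it
  is an approximation of, not a replica of, values from external radiomics
  software whose binning conventions differ.
* No DICOM/RT-STRUCT input, no resampling between mismatched grids: volumes
  and masks must share one lattice (NIfTI only).
* Whether published histogram statistics of entropy maps are computed on
  raw, smoothed or normalized maps is often unstated; the package exposes
  all three stages rather than guessing, with `smoothed` as the documented
  default.
* Hyper-entropic signal extending beyond the tumor contour is visible in
  fusion renders but not quantified; no overshoot metric is defined.
* Vessel-related entropy is not removed or modeled beyond the phantom's
  qualitative bright cylinders.
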