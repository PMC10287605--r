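# lemap — local entropy maps for volumetric CT

`lemap` turns a CT volume into a voxel-wise **local entropy map**: a 3D
image in which every voxel holds the first-order Shannon entropy of its
surrounding k×k×k neighborhood. Radiomic entropy is usually reported as a
single number per lesion; mapping it voxel-by-voxel makes intra-tumoral
heterogeneity *visible* and lets its spatial distribution be quantified and
classified. The package is aimed at image-analysis researchers working on
lesion characterization (the motivating case is colorectal liver
metastases on portal-phase CT), and ships a seeded digital-phantom
generator so the entire workflow runs and is tested without any patient
data.

## Method

For a volume with integer-valued intensities (HU), a cubic kernel of side
`k` (default 5) slides with a one-voxel stride. Within each kernel the
entropy

&nbsp;&nbsp;&nbsp;&nbsp;H = −Σᵢ P(i) · ln P(i)

is computed, where P(i) is the probability of occurrence of intensity
symbol *i* among the k³ voxels (symbols are `floor(value / bin_width)`,
default bin width 1). H is stored at the kernel center, giving a map in
nats bounded by ln(k³). The map is then smoothed with a Gaussian filter
(σ = 1 voxel) and, optionally, normalized by the mean entropy of a
liver-parenchyma reference region ("virtual liver biopsy"), after which the
liver mean is exactly 1.

On top of the map the package provides:

* **VOI histogram statistics** — the 11 first-order descriptors of the
  in-VOI value distribution (mean, median, SD, variance, RMS, 5th/25th/
  75th/95th percentiles, numbers of zero and mean crossings), for entropy
  maps and for the parallel raw-HU workflow, plus a binned global entropy.
* **Pattern classification** — voxels are classed hyper-/iso-/hypo-entropic
  against the liver reference (mean ± z·SD), and each lesion receives one
  of four deterministic patterns: *homogeneous*, *inhomogeneous*,
  *peripheral rim* (complete/incomplete) or *mixed*, using 75% volumetric
  thresholds on the lesion, its Euclidean boundary shell, and its core.
* **Group comparison** — z-scored statistics compared across two cohorts
  with two-sided Mann–Whitney U tests (exact for small samples).
* **Phantoms, sweep, rendering** — seeded CT-like phantoms with prescribed
  ground-truth patterns, a kernel-size sensitivity harness, and colormapped
  slice/fusion PNG rendering.

## Worked example

```r
library(lemap)

ph  <- generate_phantom(phantom_spec(pattern = "peripheral_rim_complete",
                                     seed = 42))
map <- local_entropy_map(ph$ct, kernel_config(k = 5))
map <- smooth_map(map, sigma = 1)
map
#> <lem_entropy_map> shape 64x64x64, spacing (1, 1, 1) mm, origin (0, 0, 0) mm
#>   kernel k=5 bin_width=1 padding=reflect
#>   smoothed: TRUE (sigma=1); normalized: FALSE
#>   value range: [2.774, 4.06] nats

extract_histogram_stats(map, ph$tumor)
#> <lem_stats> source: smoothed (11462 voxels)
#>      mean   median   std_dev  variance      rms       p5      p25      p75
#>  3.491236 3.597816 0.4261223 0.1815802 3.517145 2.873047 3.009031 3.917231
#>       p95 n_zero_crossings n_mean_crossings
#>  3.985613              736              736

classify_lesion(map, ph$tumor, ph$liver)
#> <lem_pattern> peripheral_rim (incomplete rim)
#>   rim coverage 0.997 | core homogeneity 0.886 (hypo) | hyper fraction 0.525
```

The phantom embeds a 14-voxel-radius lesion whose outer 2-voxel shell
carries heterogeneous texture (SD 35 HU) over a quiet core (SD 5 HU) in
liver background (100 ± 10 HU). The map mean of ~3.5 nats reflects
near-saturated symbol diversity of integer HU under a 125-voxel kernel; the
crossing counts are equal by construction (both count scan-order sign
changes about the VOI mean). The classifier reads the lesion as a
peripheral rim: 99.7% of the boundary shell is hyper-entropic and the core
is 89% homogeneously hypo-entropic relative to the liver reference.

A YAML-driven pipeline (`run_pipeline()`) and a CLI
(`inst/cli/lemap.R` with `run`, `phantom`, `compute`, `stats`, `classify`,
`render`, `sweep` subcommands) wire the same steps end to end and write a
reproducibility manifest beside every artifact.

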