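# run expr with a private RNG stream seeded by `seed`; the caller's RNG
# state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic CT phantom
#'
#' Defines a CT-like volume: liver background of Gaussian HU noise, one
#' embedded spherical lesion carrying a prescribed ground-truth entropy
#' pattern, tubular vessels, and the companion Tumor-VOI and Liver-VOI
#' masks. Local entropy is induced through local intensity variance: with
#' integer-rounded HU, a high-SD region presents more distinct symbols per
#' kernel, which provably raises first-order entropy.
#'
#' Defaults emulate a portal-phase liver CT at desk scale: 64^3 grid, 1 mm
#' isotropic voxels, liver 100 +/- 10 HU, lesion of radius 14 voxels at
#' 60 HU (hypodense metastasis), heterogeneous texture SD 35 HU, quiet
#' texture SD 5 HU, rim thickness 2 voxels, two bright vessels.
#'
#' @param shape grid dimensions (length 3).
#' @param spacing voxel size in mm.
#' @param liver_hu_mean,liver_hu_sd background liver HU distribution.
#' @param lesion_center lesion center in voxel coordinates (default left of
#'   grid center, leaving room for the liver reference VOI).
#' @param lesion_radius lesion radius in voxels (>= 5; smaller lesions carry
#'   too few voxels for stable statistics).
#' @param pattern ground-truth pattern, one of `"homogeneous"`,
#'   `"inhomogeneous"`, `"peripheral_rim_complete"`,
#'   `"peripheral_rim_incomplete"`, `"mixed"`.
#' @param lesion_hu_mean lesion mean HU.
#' @param hu_sd_high texture SD (HU) of hyper-entropic regions.
#' @param hu_sd_low texture SD (HU) of iso/hypo-entropic regions.
#' @param rim_thickness rim shell thickness in voxels for rim patterns.
#' @param edge_ramp width in voxels of the linear partial-volume ramp of the
#'   mean HU across the lesion boundary, emulating the scanner point-spread
#'   blur; a hard step edge would itself read as a spurious hyper-entropic
#'   ring on every lesion.
#' @param scatter_fraction target hyper fraction of scattered (blob) texture
#'   in inhomogeneous/mixed cores.
#' @param texture_margin voxels by which scattered texture blobs are eroded
#'   before use, compensating the dilation of textured regions by the
#'   entropy-kernel radius (default 2, the radius of the default 5x5x5
#'   kernel) so the realized hyper fraction of the map tracks
#'   `scatter_fraction`.
#' @param gap_fraction angular fraction of the rim left quiet for the
#'   incomplete-rim pattern.
#' @param vessel_count,vessel_radius,vessel_contrast straight bright
#'   cylinders along the z axis.
#' @param liver_voi_center,liver_voi_radius spherical Liver-VOI ("virtual
#'   liver biopsy") placed away from lesion and vessels.
#' @param seed integer seed; the phantom is fully reproducible from it.
#' @return A `lem_phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         liver_hu_mean = 100, liver_hu_sd = 10,
                         lesion_center = NULL, lesion_radius = 14,
                         pattern = c("peripheral_rim_complete",
                                     "peripheral_rim_incomplete",
                                     "homogeneous", "inhomogeneous", "mixed"),
                         lesion_hu_mean = 60,
                         hu_sd_high = 35, hu_sd_low = 5,
                         rim_thickness = 2, scatter_fraction = 0.5,
                         gap_fraction = 0.15,
                         edge_ramp = 6, texture_margin = 2,
                         vessel_count = 2, vessel_radius = 1.5,
                         vessel_contrast = 60,
                         liver_voi_center = NULL, liver_voi_radius = 7,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be 3 dims >= 8")
  if (lesion_radius < 5) stop("lesion_radius must be >= 5 voxels")
  if (is.null(lesion_center)) lesion_center <- c(shape[1] * 0.38,
                                                 shape[2] * 0.38,
                                                 shape[3] / 2)
  if (is.null(liver_voi_center)) liver_voi_center <- c(shape[1] * 0.78,
                                                       shape[2] * 0.78,
                                                       shape[3] / 2)
  if (any(lesion_center - lesion_radius < 1) ||
      any(lesion_center + lesion_radius > shape))
    stop("lesion not contained in grid")
  if (gap_fraction < 0 || gap_fraction >= 1) stop("gap_fraction must be in [0,1)")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 pattern = pattern, lesion_hu_mean = lesion_hu_mean,
                 hu_sd_high = hu_sd_high, hu_sd_low = hu_sd_low,
                 rim_thickness = rim_thickness, edge_ramp = edge_ramp,
                 texture_margin = texture_margin,
                 scatter_fraction = scatter_fraction,
                 gap_fraction = gap_fraction,
                 vessel_count = vessel_count, vessel_radius = vessel_radius,
                 vessel_contrast = vessel_contrast,
                 liver_voi_center = liver_voi_center,
                 liver_voi_radius = liver_voi_radius,
                 seed = as.integer(seed)),
            class = "lem_phantom_spec")
}

# voxel-coordinate grids and Euclidean distance from a point (voxel units)
dist_from <- function(shape, center) {
  gx <- (seq_len(shape[1]) - center[1])^2
  gy <- (seq_len(shape[2]) - center[2])^2
  gz <- (seq_len(shape[3]) - center[3])^2
  sqrt(outer(outer(gx, gy, `+`), gz, `+`))
}

# smooth blob indicator inside a mask: Gaussian-filtered white noise,
# thresholded so about `fraction` of the mask is TRUE. `margin` erodes the
# blobs by that many voxels: the entropy kernel dilates any textured region
# by its radius, so laying the texture down as the erosion of the target
# region makes the realized map pattern match the prescribed fraction.
blob_field <- function(shape, mask, fraction, blob_sigma = 3, margin = 0) {
  noise <- array(stats::rnorm(prod(shape)), shape)
  w <- gaussian_kernel_1d(blob_sigma, truncate = 3)
  for (ax in 1:3) noise <- convolve_axis_na(noise, w, ax)
  thr <- stats::quantile(noise[mask], probs = 1 - fraction, type = 7)
  blobs <- noise >= thr & mask
  if (margin > 0 && any(blobs)) blobs <- blobs & euclidean_depth(blobs) > margin
  blobs
}

#' Generate a synthetic CT phantom
#'
#' Builds the CT volume, Tumor-VOI and Liver-VOI of a [phantom_spec()]:
#' Gaussian liver background, a spherical lesion whose local intensity SD is
#' laid out so that the local entropy map shows the requested ground-truth
#' pattern (high-SD texture exactly where the pattern demands hyper-entropy),
#' bright vessel cylinders, and integer-rounded HU throughout. Bit-identical
#' volumes are produced for identical spec + seed.
#'
#' @param spec a [phantom_spec()].
#' @return A `lem_phantom`: list with `ct` ([lem_volume()]), `tumor` and
#'   `liver` ([lem_mask()]s), `truth` (pattern label), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "lem_phantom_spec"))
  with_seed(spec$seed, {
    sh <- spec$shape
    d_les <- dist_from(sh, spec$lesion_center)
    lesion <- d_les <= spec$lesion_radius
    shell <- lesion & d_les > (spec$lesion_radius - spec$rim_thickness)
    core <- lesion & !shell

    # mean HU: linear partial-volume ramp across the boundary (scanner blur)
    w <- max(spec$edge_ramp, 1e-6)
    frac_inside <- pmin(1, pmax(0, (spec$lesion_radius + w / 2 - d_les) / w))
    mu <- spec$liver_hu_mean +
      (spec$lesion_hu_mean - spec$liver_hu_mean) * frac_inside
    sdv <- array(spec$liver_hu_sd, sh)

    hot <- switch(spec$pattern,
      homogeneous = lesion,
      inhomogeneous = blob_field(sh, lesion, spec$scatter_fraction,
                                 margin = spec$texture_margin),
      peripheral_rim_complete = shell,
      peripheral_rim_incomplete = {
        phi <- atan2(
          rep(seq_len(sh[2]) - spec$lesion_center[2], each = sh[1]),
          rep(seq_len(sh[1]) - spec$lesion_center[1], times = sh[2]))
        gap2d <- array(rep(phi, times = sh[3]), sh) <
          (-pi + 2 * pi * spec$gap_fraction)
        shell & !gap2d
      },
      mixed = shell | blob_field(sh, core, spec$scatter_fraction,
                                 margin = spec$texture_margin))
    sdv[lesion] <- spec$hu_sd_low
    sdv[hot] <- spec$hu_sd_high

    ct <- round(mu + sdv * array(stats::rnorm(prod(sh)), sh))

    # vessels: straight bright cylinders along z, away from lesion and VOI
    if (spec$vessel_count > 0) {
      cx <- sh[1] * c(0.80, 0.20, 0.50, 0.15)
      cy <- sh[2] * c(0.22, 0.80, 0.10, 0.50)
      for (i in seq_len(min(spec$vessel_count, 4L))) {
        r2d <- sqrt(outer((seq_len(sh[1]) - cx[i])^2,
                          (seq_len(sh[2]) - cy[i])^2, `+`))
        lum2d <- r2d <= spec$vessel_radius
        lumen <- array(rep(lum2d, times = sh[3]), sh)
        ct[lumen] <- round(spec$liver_hu_mean + spec$vessel_contrast +
                             3 * stats::rnorm(sum(lumen)))
      }
    }

    liver_voi <- dist_from(sh, spec$liver_voi_center) <= spec$liver_voi_radius
    if (any(liver_voi & lesion))
      stop("liver VOI overlaps the lesion; move liver_voi_center")

    structure(list(
      ct = lem_volume(ct, spec$spacing,
                      meta = list(descrip = sprintf("phantom %s seed=%d",
                                                    spec$pattern, spec$seed))),
      tumor = lem_mask(lesion, spec$spacing),
      liver = lem_mask(liver_voi, spec$spacing),
      truth = sub("^peripheral_rim_(in)?complete$", "peripheral_rim",
                  spec$pattern),
      truth_subtype = if (grepl("^peripheral_rim", spec$pattern))
        sub("^peripheral_rim_", "", spec$pattern) else "none",
      spec = spec), class = "lem_phantom")
  })
}

#' @export
print.lem_phantom <- function(x, ...) {
  cat(sprintf("<lem_phantom> pattern %s (seed %d), grid %s\n",
              x$spec$pattern, x$spec$seed,
              paste(x$spec$shape, collapse = "x")))
  cat(sprintf("  lesion: %d voxels (radius %g); liver VOI: %d voxels\n",
              sum(x$tumor$data), x$spec$lesion_radius, sum(x$liver$data)))
  invisible(x)
}

#' Generate a two-group phantom cohort
#'
#' Builds two labeled groups of lesions ("responder" vs "non-responder"
#' stand-ins) whose hyper-region texture SD differs by `effect` HU:
#' group A keeps `base_spec$hu_sd_high`, group B uses
#' `base_spec$hu_sd_high - effect`. Each group contains `n_per_pattern`
#' phantoms of each of the five pattern variants, with per-phantom seeds
#' derived deterministically from `seed`.
#'
#' @param n_per_pattern phantoms per pattern per group (>= 1).
#' @param base_spec template [phantom_spec()].
#' @param effect HU shift in texture SD between the groups.
#' @param seed cohort seed.
#' @return A `lem_cohort`: list of `lem_phantom`s plus `labels`
#'   (`"A"`/`"B"`), and the generating parameters.
#' @export
generate_cohort <- function(n_per_pattern = 2L, base_spec = phantom_spec(),
                            effect = 20, seed = 1L) {
  n_per_pattern <- as.integer(n_per_pattern)
  if (n_per_pattern < 1L) stop("n_per_pattern must be >= 1")
  patterns <- c("homogeneous", "inhomogeneous", "peripheral_rim_complete",
                "peripheral_rim_incomplete", "mixed")
  sd_by_group <- c(A = base_spec$hu_sd_high, B = base_spec$hu_sd_high - effect)
  if (any(sd_by_group <= 0)) stop("effect leaves a non-positive texture SD")
  n_total <- 2L * length(patterns) * n_per_pattern
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  phantoms <- vector("list", n_total); labels <- character(n_total)
  i <- 0L
  for (g in names(sd_by_group)) for (p in patterns)
    for (j in seq_len(n_per_pattern)) {
      i <- i + 1L
      sp <- base_spec
      sp$pattern <- p
      sp$hu_sd_high <- sd_by_group[[g]]
      sp$seed <- seeds[i]
      phantoms[[i]] <- generate_phantom(sp)
      labels[i] <- g
    }
  structure(list(phantoms = phantoms, labels = labels,
                 n_per_pattern = n_per_pattern, effect = effect,
                 base_spec = base_spec, seed = as.integer(seed)),
            class = "lem_cohort")
}

#' @export
print.lem_cohort <- function(x, ...) {
  cat(sprintf("<lem_cohort> %d phantoms (%d per pattern per group), effect %g HU, seed %d\n",
              length(x$phantoms), x$n_per_pattern, x$effect, x$seed))
  print(table(x$labels))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes `ct.nii.gz`, `tumor.nii.gz`, `liver.nii.gz` and a `phantom.json`
#' sidecar (spec + ground-truth label) into `dir`.
#'
#' @param ph a `lem_phantom`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "lem_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(ph$ct, file.path(dir, "ct.nii.gz"))
  write_volume(ph$tumor, file.path(dir, "tumor.nii.gz"))
  write_volume(ph$liver, file.path(dir, "liver.nii.gz"))
  side <- file.path(dir, "phantom.json")
  jsonlite::write_json(c(unclass(ph$spec),
                         list(truth = ph$truth,
                              truth_subtype = ph$truth_subtype)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
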