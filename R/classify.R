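# exact Euclidean depth of each foreground voxel: distance (voxels) to the
# nearest background voxel; outside the grid counts as background
euclidean_depth <- function(m) {
  d <- dim(m)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  dt <- sqrt(array(edt_sq_cpp(as.logical(padded), as.integer(d + 2L)),
                   d + 2L))
  dt[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

#' Split a tumor mask into a boundary rim shell and a core
#'
#' The rim shell is the set of tumor voxels within `rim_width` voxels
#' (Euclidean distance) of the tumor boundary — the residue of morphological
#' erosion by a Euclidean ball of radius `rim_width`, computed with an exact
#' distance transform. Shell and core are disjoint and together cover the
#' tumor exactly; voxels outside the volume count as background, so the
#' volume face is a boundary too.
#'
#' @param tumor a non-empty [lem_mask()].
#' @param rim_width shell thickness in voxels (>= 1).
#' @return List with `rim` and `core` masks and a `core_empty` flag (a tumor
#'   so small that erosion empties it is flagged; classification then
#'   proceeds rim-only).
#' @export
split_rim_core <- function(tumor, rim_width = 1L) {
  stopifnot(inherits(tumor, "lem_mask"))
  rim_width <- as.integer(rim_width)
  if (is.na(rim_width) || rim_width < 1L) stop("rim_width must be >= 1")
  if (!any(tumor$data)) stop("empty VOI: tumor mask has no voxel")
  depth <- euclidean_depth(tumor$data)
  core <- tumor$data & depth > rim_width
  rim <- tumor$data & !core
  list(rim = lem_mask(rim, tumor$spacing, tumor$origin),
       core = lem_mask(core, tumor$spacing, tumor$origin),
       core_empty = !any(core))
}

#' Classify tumor voxels as hyper-, iso- or hypo-entropic
#'
#' Each tumor voxel is classed relative to the liver-parenchyma reference
#' remote from the tumor: hyper if its map value exceeds
#' `liver_mean + z_cutoff * liver_SD`, hypo if below
#' `liver_mean - z_cutoff * liver_SD`, iso otherwise. The liver SD uses the
#' population (1/N) convention, consistent with the VOI statistics.
#'
#' @param m a `lem_entropy_map`.
#' @param tumor,liver non-empty, disjoint [lem_mask()]s on the map grid.
#' @param z_cutoff threshold in liver SD units (default 1).
#' @return A `lem_class_field`: categorical grid (`"hyper"`/`"iso"`/`"hypo"`,
#'   `NA` outside the tumor) plus the thresholds used.
#' @export
classify_voxels <- function(m, tumor, liver, z_cutoff = 1) {
  stopifnot(inherits(m, "lem_entropy_map"),
            inherits(tumor, "lem_mask"), inherits(liver, "lem_mask"))
  check_same_grid(m, tumor); check_same_grid(m, liver)
  if (!any(tumor$data)) stop("empty VOI: tumor")
  if (!any(liver$data)) stop("empty VOI: liver")
  if (any(tumor$data & liver$data))
    stop("tumor and liver masks must be disjoint")
  if (!is.finite(z_cutoff) || z_cutoff < 0) stop("z_cutoff must be >= 0")
  lv <- m$data[liver$data]
  lv <- lv[!is.na(lv)]
  lmean <- mean(lv)
  lsd <- sqrt(mean((lv - lmean)^2))
  if (lsd == 0)
    stop("liver reference SD is zero: hyper/hypo thresholds undefined")
  lo <- lmean - z_cutoff * lsd
  hi <- lmean + z_cutoff * lsd
  cls <- array(NA_character_, dim(m$data))
  tv <- m$data[tumor$data]
  cls[tumor$data] <- ifelse(is.na(tv), NA_character_,
                            ifelse(tv > hi, "hyper",
                                   ifelse(tv < lo, "hypo", "iso")))
  structure(list(classes = cls, tumor = tumor,
                 thresholds = c(liver_mean = lmean, liver_sd = lsd,
                                z_cutoff = z_cutoff, lower = lo, upper = hi),
                 spacing = m$spacing, origin = m$origin),
            class = "lem_class_field")
}

#' @export
print.lem_class_field <- function(x, ...) {
  cat("<lem_class_field>\n  thresholds:",
      sprintf("liver mean %.4g, SD %.4g, z-cutoff %.3g\n",
              x$thresholds["liver_mean"], x$thresholds["liver_sd"],
              x$thresholds["z_cutoff"]))
  print(table(x$classes[x$tumor$data], useNA = "ifany"))
  invisible(x)
}

modal_fraction <- function(cls) {
  # (modal class, its fraction) of a character vector; ties broken by the
  # fixed order hypo < iso < hyper for determinism
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0L) return(list(class = NA_character_, fraction = NA_real_))
  lev <- c("hypo", "iso", "hyper")
  cnt <- vapply(lev, function(l) sum(cls == l), 0L)
  i <- which.max(cnt)
  list(class = lev[i], fraction = unname(cnt[i]) / length(cls))
}

#' Assign one of the four intra-tumoral entropy patterns
#'
#' Operationalizes the four qualitative entropy-distribution patterns —
#' homogeneous, inhomogeneous, peripheral rim (complete/incomplete) and
#' mixed — as deterministic decision rules over the voxel class field, using
#' the printed 75% thresholds read volumetrically:
#'
#' 1. `hyper_surface_fraction >= 0.75` and the modal class covering >= 75%
#'    of the whole VOI: **homogeneous** (uniformly hyper-entropic lesion).
#' 2. Otherwise, if the boundary shell is hyper-entropic over >= 75% of its
#'    extent (`rim_coverage_fraction >= 0.75`): **peripheral_rim** when the
#'    core is homogeneous (modal class >= 75% of the core) and iso/hypo —
#'    subtype `complete` when coverage >= 0.999, else `incomplete`; **mixed**
#'    when the core is inhomogeneous (modal fraction < 0.75).
#' 3. Otherwise **inhomogeneous** (scattered hyper and iso/hypo components,
#'    hyper < 75%, no rim).
#'
#' An empty core (lesion thinner than the rim) is treated as a
#' homogeneous iso core. All three fractions are always reported with the
#' label.
#'
#' @param field a `lem_class_field` from [classify_voxels()].
#' @param rim_width boundary shell thickness in voxels for
#'   [split_rim_core()]. The default 3 matches the map-space width of a thin
#'   anatomical rim: the entropy kernel spreads an interface signal by part
#'   of its radius, so a rim of 1-2 tissue voxels appears in the map as a
#'   band of roughly 3 voxels (Euclidean depth). A much wider shell dilutes
#'   the rim with core voxels; a 1-voxel shell misses most of the band.
#' @return A `lem_pattern`: `label`, `rim_subtype`, the three fractions,
#'   core modal class and the thresholds used.
#' @export
classify_pattern <- function(field, rim_width = 3L) {
  stopifnot(inherits(field, "lem_class_field"))
  tumor <- field$tumor
  parts <- split_rim_core(tumor, rim_width)
  all_cls <- field$classes[tumor$data]
  rim_cls <- field$classes[parts$rim$data]
  hyper_frac <- mean(all_cls == "hyper", na.rm = TRUE)
  whole_modal <- modal_fraction(all_cls)
  rim_cov <- mean(rim_cls == "hyper", na.rm = TRUE)
  if (parts$core_empty) {
    core_modal <- list(class = "iso", fraction = 1)
  } else {
    core_modal <- modal_fraction(field$classes[parts$core$data])
  }
  label <- NULL; subtype <- "none"
  if (hyper_frac >= 0.75 && whole_modal$fraction >= 0.75) {
    label <- "homogeneous"
  } else if (rim_cov >= 0.75) {
    if (core_modal$fraction >= 0.75 && core_modal$class %in% c("iso", "hypo")) {
      label <- "peripheral_rim"
      subtype <- if (rim_cov >= 0.999) "complete" else "incomplete"
    } else if (core_modal$fraction < 0.75) {
      label <- "mixed"
      subtype <- if (rim_cov >= 0.999) "complete" else "incomplete"
    }
  }
  if (is.null(label)) label <- "inhomogeneous"
  structure(list(label = label, rim_subtype = subtype,
                 rim_coverage_fraction = rim_cov,
                 core_homogeneity_fraction = core_modal$fraction,
                 core_modal_class = core_modal$class,
                 hyper_surface_fraction = hyper_frac,
                 core_empty = parts$core_empty,
                 rim_width = as.integer(rim_width),
                 thresholds = field$thresholds),
            class = "lem_pattern")
}

#' Pattern labels emitted by the classifier
#' @return Character vector of the four possible labels.
#' @export
pattern_labels <- function() {
  c("homogeneous", "inhomogeneous", "peripheral_rim", "mixed")
}

#' End-to-end lesion pattern classification
#'
#' Convenience wrapper: [classify_voxels()] then [classify_pattern()].
#'
#' @inheritParams classify_voxels
#' @inheritParams classify_pattern
#' @return A `lem_pattern`.
#' @export
classify_lesion <- function(m, tumor, liver, z_cutoff = 1, rim_width = 3L) {
  classify_pattern(classify_voxels(m, tumor, liver, z_cutoff), rim_width)
}

#' @export
print.lem_pattern <- function(x, ...) {
  cat(sprintf("<lem_pattern> %s%s\n", x$label,
              if (x$rim_subtype != "none") paste0(" (", x$rim_subtype, " rim)")
              else ""))
  cat(sprintf("  rim coverage %.3f | core homogeneity %.3f (%s) | hyper fraction %.3f\n",
              x$rim_coverage_fraction, x$core_homogeneity_fraction,
              x$core_modal_class, x$hyper_surface_fraction))
  invisible(x)
}

#' @export
as.data.frame.lem_pattern <- function(x, ...) {
  data.frame(label = x$label, rim_subtype = x$rim_subtype,
             rim_coverage_fraction = x$rim_coverage_fraction,
             core_homogeneity_fraction = x$core_homogeneity_fraction,
             core_modal_class = x$core_modal_class,
             hyper_surface_fraction = x$hyper_surface_fraction,
             liver_mean = unname(x$thresholds["liver_mean"]),
             liver_sd = unname(x$thresholds["liver_sd"]),
             z_cutoff = unname(x$thresholds["z_cutoff"]),
             rim_width = x$rim_width,
             stringsAsFactors = FALSE)
}
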