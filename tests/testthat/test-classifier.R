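# build a class field from an explicit per-voxel class array, bypassing the
# thresholding stage (tests of classify_pattern's decision rules construct
# their ground truth directly)
field_from_classes <- function(cls, tumor) {
  structure(list(classes = cls, tumor = tumor,
                 thresholds = c(liver_mean = 1, liver_sd = 0.1, z_cutoff = 1,
                                lower = 0.9, upper = 1.1),
                 spacing = tumor$spacing, origin = tumor$origin),
            class = "lem_class_field")
}

ball_mask <- function(n, r, center = rep((n + 1) / 2, 3)) {
  d <- lemap:::dist_from(c(n, n, n), center)
  lem_mask(d <= r)
}

test_that("voxel classification is direct threshold arithmetic", {
  # liver mean 0.75, SD 0.05, z-cutoff 1
  d <- array(0.75, c(12, 12, 12))
  liv <- array(FALSE, dim(d)); liv[1:4, , ] <- TRUE
  # balanced +/- 0.05: liver mean exactly 0.75, population SD exactly 0.05
  d[liv] <- 0.75 + 0.05 * rep(c(-1, 1), length.out = sum(liv))
  tum <- array(FALSE, dim(d)); tum[8:10, 8:10, 8:10] <- TRUE
  d[8, 8, 8] <- 0.91; d[9, 9, 9] <- 0.72; d[10, 10, 10] <- 0.69
  fld <- classify_voxels(map_with_data(d), lem_mask(tum), lem_mask(liv),
                         z_cutoff = 1)
  expect_equal(unname(fld$thresholds["liver_mean"]), 0.75)
  expect_equal(unname(fld$thresholds["liver_sd"]), 0.05)
  expect_identical(fld$classes[8, 8, 8], "hyper")
  expect_identical(fld$classes[9, 9, 9], "iso")
  expect_identical(fld$classes[10, 10, 10], "hypo")
  expect_true(all(is.na(fld$classes[!tum])))
})

test_that("degenerate thresholds behave as documented", {
  d <- array(1, c(8, 8, 8))
  liv <- array(FALSE, dim(d)); liv[1:3, , ] <- TRUE
  tum <- array(FALSE, dim(d)); tum[6:7, 6:7, 6:7] <- TRUE
  # constant liver: SD 0 -> thresholds undefined
  expect_error(classify_voxels(map_with_data(d), lem_mask(tum), lem_mask(liv)),
               "SD is zero")
  # map equal to liver mean everywhere -> all iso
  d2 <- d; d2[liv] <- 1 + 0.1 * rep(c(-1, 1), length.out = sum(liv))
  fld <- classify_voxels(map_with_data(d2), lem_mask(tum), lem_mask(liv))
  expect_true(all(fld$classes[tum] == "iso"))
  # z_cutoff 0: iso only at exact equality
  fld0 <- classify_voxels(map_with_data(d2), lem_mask(tum), lem_mask(liv),
                          z_cutoff = 0)
  expect_true(all(fld0$classes[tum] == "iso"))  # exactly equal to the mean
  d3 <- d2; d3[tum][1:4] <- 1 + 1e-9
  fld3 <- classify_voxels(map_with_data(d3), lem_mask(tum), lem_mask(liv),
                          z_cutoff = 0)
  expect_identical(sum(fld3$classes[tum] == "hyper"), 4L)
  # overlapping masks are rejected
  expect_error(classify_voxels(map_with_data(d2), lem_mask(liv),
                               lem_mask(liv)), "disjoint")
})

test_that("rim/core split counts match explicit construction", {
  cube <- lem_mask(array(TRUE, c(9, 9, 9)))
  p <- split_rim_core(cube, 1)
  expect_identical(sum(p$rim$data), 386L)   # 9^3 - 7^3
  expect_identical(sum(p$core$data), 343L)
  expect_false(p$core_empty)
  # rim wider than the radius: core empty, shell == tumor
  small <- ball_mask(9, 3)
  p2 <- split_rim_core(small, 5)
  expect_true(p2$core_empty)
  expect_identical(p2$rim$data, small$data)
})

test_that("shell and core partition the tumor for random blob masks", {
  set.seed(55)
  for (i in 1:50) {
    base <- array(stats::rnorm(12^3), c(12, 12, 12))
    w <- lemap:::gaussian_kernel_1d(2, truncate = 2)
    for (ax in 1:3) base <- lemap:::convolve_axis_na(base, w, ax)
    mask <- base > stats::quantile(base, 0.8)
    if (!any(mask)) next
    p <- split_rim_core(lem_mask(mask), sample(1:3, 1))
    expect_false(any(p$rim$data & p$core$data))
    expect_identical(p$rim$data | p$core$data, mask)
  }
})

test_that("constructed class fields receive their designed labels", {
  n <- 26
  tum <- ball_mask(n, 10)
  rw <- 2L   # thin shell so the rim never dominates the lesion volume
  parts <- split_rim_core(tum, rw)

  all_hyper <- array(NA_character_, c(n, n, n))
  all_hyper[tum$data] <- "hyper"
  r1 <- classify_pattern(field_from_classes(all_hyper, tum), rw)
  expect_identical(r1$label, "homogeneous")
  expect_equal(r1$hyper_surface_fraction, 1)
  expect_identical(r1$rim_subtype, "none")

  # complete hyper shell over an iso core
  shell_iso <- array(NA_character_, c(n, n, n))
  shell_iso[parts$rim$data] <- "hyper"
  shell_iso[parts$core$data] <- "iso"
  r2 <- classify_pattern(field_from_classes(shell_iso, tum), rw)
  expect_identical(r2$label, "peripheral_rim")
  expect_identical(r2$rim_subtype, "complete")
  expect_equal(r2$rim_coverage_fraction, 1)
  expect_equal(r2$core_homogeneity_fraction, 1)

  # 85% shell coverage -> incomplete rim
  shell_gap <- shell_iso
  rim_idx <- which(parts$rim$data)
  set.seed(3)
  shell_gap[sample(rim_idx, round(0.15 * length(rim_idx)))] <- "iso"
  r3 <- classify_pattern(field_from_classes(shell_gap, tum), rw)
  expect_identical(r3$label, "peripheral_rim")
  expect_identical(r3$rim_subtype, "incomplete")
  expect_lt(r3$rim_coverage_fraction, 0.999)
  expect_gte(r3$rim_coverage_fraction, 0.75)

  # scattered 50% hyper, no shell enrichment -> inhomogeneous
  set.seed(9)
  scattered <- array(NA_character_, c(n, n, n))
  scattered[tum$data] <- sample(c("hyper", "hypo"), sum(tum$data), TRUE)
  r4 <- classify_pattern(field_from_classes(scattered, tum), rw)
  expect_identical(r4$label, "inhomogeneous")
  expect_lt(r4$rim_coverage_fraction, 0.75)
  expect_identical(r4$rim_subtype, "none")

  # complete rim over a scattered (40% hyper) core -> mixed
  mixed <- shell_iso
  core_idx <- which(parts$core$data)
  set.seed(10)
  mixed[core_idx] <- sample(c("hyper", "hypo"), length(core_idx), TRUE,
                            prob = c(0.4, 0.6))
  r5 <- classify_pattern(field_from_classes(mixed, tum), rw)
  expect_identical(r5$label, "mixed")
  expect_identical(r5$rim_subtype, "complete")
})

test_that("label set is exactly the four patterns and output deterministic", {
  expect_identical(pattern_labels(),
                   c("homogeneous", "inhomogeneous", "peripheral_rim",
                     "mixed"))
  ph <- generate_phantom(small_phantom_spec("mixed", seed = 5))
  m <- smooth_map(local_entropy_map(ph$ct), 1)
  r1 <- classify_lesion(m, ph$tumor, ph$liver)
  r2 <- classify_lesion(m, ph$tumor, ph$liver)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(r1$label %in% pattern_labels())
})

test_that("raising scattered hyper load never passes through a rim label", {
  tum <- ball_mask(20, 7)
  n_t <- sum(tum$data)
  seen <- character(0)
  set.seed(17)
  ord <- sample(which(tum$data))  # fixed scatter order, no shell enrichment
  for (f in seq(0, 1, by = 0.1)) {
    cls <- array(NA_character_, c(20, 20, 20))
    cls[tum$data] <- "hypo"
    k <- round(f * n_t)
    if (k > 0) cls[ord[seq_len(k)]] <- "hyper"
    r <- classify_pattern(field_from_classes(cls, tum), 3)
    seen <- c(seen, r$label)
  }
  expect_false(any(seen %in% c("peripheral_rim", "mixed")))
  # all-hypo start: no hyper component, hence inhomogeneous by the rules
  expect_identical(seen[1], "inhomogeneous")
  expect_identical(seen[length(seen)], "homogeneous")
})
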