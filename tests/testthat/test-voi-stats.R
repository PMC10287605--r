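test_that("the extraction returns exactly the 11 named statistics", {
  v <- random_volume(10, seed = 4)
  voi <- array(FALSE, c(10, 10, 10)); voi[3:7, 3:7, 3:7] <- TRUE
  st <- extract_histogram_stats(local_entropy_map(v), lem_mask(voi))
  stat_fields <- setdiff(names(st),
                         c("voi_voxel_count", "n_dropped", "source_stage"))
  expect_length(stat_fields, 11L)
  expect_setequal(stat_fields,
                  c("mean", "median", "std_dev", "variance", "rms",
                    "p5", "p25", "p75", "p95",
                    "n_zero_crossings", "n_mean_crossings"))
  expect_identical(st$voi_voxel_count, 125L)
})

test_that("a constant VOI collapses every statistic", {
  v <- lem_volume(array(-100, c(8, 8, 8)))
  voi <- lem_mask(array(TRUE, c(8, 8, 8)))
  st <- hounsfield_stats(v, voi)
  expect_equal(st$mean, -100)
  expect_equal(st$median, -100)
  expect_equal(st$p5, -100); expect_equal(st$p95, -100)
  expect_equal(st$std_dev, 0); expect_equal(st$variance, 0)
  expect_equal(st$rms, 100)   # rms of a negative constant is its magnitude
  expect_identical(st$n_mean_crossings, 0L)
  expect_identical(st$n_zero_crossings, 0L)
})

test_that("crossing counts follow the canonical scan order", {
  # column (2,0,2,0): mean 1, signs (+,-,+,-) => 3 crossings of both kinds
  d <- array(1, c(4, 3, 3))
  d[, 1, 1] <- c(2, 0, 2, 0)
  voi <- array(FALSE, c(4, 3, 3)); voi[, 1, 1] <- TRUE
  st <- hounsfield_stats(lem_volume(d), lem_mask(voi))
  expect_equal(st$mean, 1)
  expect_identical(st$n_mean_crossings, 3L)
  expect_identical(st$n_zero_crossings, 3L)
})

test_that("statistic identities hold over many random VOIs", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(5:400, 1)
    vals <- switch(i %% 3 + 1,
                   rnorm(n, sample(-100:100, 1), runif(1, 0.1, 50)),
                   sample(-50:50, n, replace = TRUE),
                   rexp(n, 0.1) - 5)
    st <- lemap:::stats_from_values(vals)
    expect_true(st$p5 <= st$p25 && st$p25 <= st$median &&
                  st$median <= st$p75 && st$p75 <= st$p95)
    expect_equal(st$variance, st$std_dev^2, tolerance = 1e-9)
    expect_gte(st$rms, abs(st$mean) - 1e-12)
    # population-variance convention: rms^2 = mean^2 + variance
    expect_equal(st$rms^2, st$mean^2 + st$variance, tolerance = 1e-9)
    expect_identical(st$n_zero_crossings, st$n_mean_crossings)
  }
})

test_that("statistics other than crossings are multiset functions", {
  set.seed(12)
  vals <- rnorm(200)
  s1 <- lemap:::stats_from_values(vals)
  s2 <- lemap:::stats_from_values(rev(vals))
  for (f in c("mean", "median", "std_dev", "variance", "rms",
              "p5", "p25", "p75", "p95"))
    expect_equal(s1[[f]], s2[[f]])
})

test_that("global entropy follows the binned histogram formula", {
  cube <- lem_mask(array(TRUE, c(4, 4, 4)))
  expect_identical(global_entropy(lem_volume(array(7, c(4, 4, 4))), cube), 0)
  # 64 voxels uniformly filling 4 bins -> log(4)
  v <- lem_volume(array(rep(c(0, 1, 2, 3), each = 16), c(4, 4, 4)))
  expect_equal(global_entropy(v, cube, n_bins = 4), log(4))
  expect_equal(global_entropy(v, cube, n_bins = 4, log_base = "2"), 2)
  # 32/16/16 split across three bins
  v3 <- lem_volume(array(c(rep(0, 32), rep(1, 16), rep(2, 16)), c(4, 4, 4)))
  h <- global_entropy(v3, cube, n_bins = 3)
  expect_equal(h, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(h, 1.0397, tolerance = 1e-4)
  expect_error(global_entropy(v3, cube, n_bins = 1), "n_bins")
})

test_that("phantom tumor HU statistics recover the generator parameters", {
  ph <- generate_phantom(phantom_spec(pattern = "homogeneous", seed = 77,
                                      lesion_hu_mean = 60, hu_sd_high = 10))
  st <- hounsfield_stats(ph$ct, ph$tumor)
  expect_gt(st$voi_voxel_count, 1000L)
  # the partial-volume ramp pulls the boundary band toward liver HU, so the
  # whole-VOI mean sits a few HU above the lesion mean; the interior is clean
  expect_lt(abs(st$mean - 60), 8)
  core <- split_rim_core(ph$tumor, 4)$core
  stc <- hounsfield_stats(ph$ct, core)
  expect_lt(abs(stc$mean - 60), 1.5)
  expect_lt(abs(stc$std_dev - 10), 1.5)
})

test_that("group comparison separates and ranks as the U statistic dictates", {
  mk <- function(x) lemap:::stats_from_values(rep(x, 5))
  subjects <- lapply(c(1, 2, 3, 10, 11, 12), mk)
  cmp <- compare_groups(subjects, c("A", "A", "A", "B", "B", "B"))
  row <- cmp[cmp$statistic == "mean", ]
  expect_equal(row$U, 0)
  expect_equal(row$p_value, 2 / choose(6, 3))  # exact enumeration, n=3,3
  expect_match(row$direction, "B > A")
  # constant-across-subjects statistics are flagged, not errors
  expect_true(all(cmp$degenerate[cmp$statistic %in%
                                   c("std_dev", "variance")]))
  expect_true(all(is.na(cmp$p_value[cmp$degenerate])))
})

test_that("z-scoring leaves the rank-test p-values unchanged", {
  set.seed(31)
  subjects <- lapply(1:12, function(i) lemap:::stats_from_values(rnorm(50, i)))
  labels <- rep(c("A", "B"), each = 6)
  cmp <- compare_groups(subjects, labels)
  for (s in c("mean", "median", "rms", "p95")) {
    raw <- vapply(subjects, function(st) st[[s]], 0)
    ref <- stats::wilcox.test(raw[labels == "A"], raw[labels == "B"],
                              exact = TRUE)$p.value
    expect_equal(cmp$p_value[cmp$statistic == s], ref)
  }
})

test_that("group comparison validates its inputs", {
  mk <- function(x) lemap:::stats_from_values(rep(x, 5))
  expect_error(compare_groups(lapply(1:3, mk), c("A", "A", "B")),
               "at least 2")
  expect_error(compare_groups(lapply(1:4, mk), c("A", "A", "A", "A")),
               "two groups")
  cmp <- compare_groups(lapply(c(1, 2, 9, 10), mk), c("A", "A", "B", "B"),
                        adjust = "BH")
  expect_true("p_adjusted" %in% names(cmp))
})
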