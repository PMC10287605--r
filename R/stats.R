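# In-VOI voxel values in canonical scan order: the R array storage order
# (first axis fastest), which is the fixed raster the crossing counts refer
# to. Missing (NA) voxels from exclude-border maps are dropped with a count.
voi_values <- function(x, voi) {
  check_same_grid(x, voi)
  if (!any(voi$data)) stop("empty VOI")
  v <- x$data[voi$data]
  n_na <- sum(is.na(v))
  if (n_na > 0L)
    message(n_na, " VOI voxel(s) fall in the missing border region; dropped")
  list(values = v[!is.na(v)], dropped = n_na)
}

# crossings of `values` about `level`: consecutive pairs strictly straddling it
count_crossings <- function(values, level) {
  c0 <- values - level
  if (length(c0) < 2L) return(0L)
  a <- c0[-length(c0)]; b <- c0[-1L]
  sum((a < 0 & b > 0) | (a > 0 & b < 0))
}

stats_from_values <- function(v, source_stage = "raw", dropped = 0L) {
  n <- length(v)
  if (n == 0L) stop("empty VOI")
  mu <- mean(v)
  va <- mean((v - mu)^2)  # population (1/N) convention: the VOI is its own population
  q <- unname(stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7))
  nmc <- count_crossings(v, mu)
  structure(list(
    mean = mu,
    median = q[3],
    std_dev = sqrt(va),
    variance = va,
    rms = sqrt(mean(v^2)),
    p5 = q[1], p25 = q[2], p75 = q[4], p95 = q[5],
    n_zero_crossings = count_crossings(v - mu, 0),  # equals n_mean_crossings by construction
    n_mean_crossings = nmc,
    voi_voxel_count = n,
    n_dropped = dropped,
    source_stage = source_stage
  ), class = "lem_stats")
}

#' The 11 first-order histogram statistics of names used throughout
#' @keywords internal
#' @noRd
stat_names <- function() {
  c("mean", "median", "std_dev", "variance", "rms",
    "p5", "p25", "p75", "p95", "n_zero_crossings", "n_mean_crossings")
}

#' Extract histogram statistics of a map inside a VOI
#'
#' Computes the 11 first-order descriptive statistics of the voxel values
#' inside the VOI: mean, median, standard deviation, variance, root mean
#' square (RMS), the 5th/25th/75th/95th percentiles, and the numbers of zero
#' and mean crossings.
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7). Variance and standard deviation use the population
#' (1/N) convention, under which `rms^2 == mean^2 + variance` exactly.
#' Crossing counts are taken on the in-VOI voxel sequence in the canonical
#' array scan order: `n_mean_crossings` counts consecutive pairs strictly
#' straddling the VOI mean, and `n_zero_crossings` counts sign changes of the
#' mean-centered sequence about zero — the two are equal by construction,
#' which this definition makes explicit rather than accidental.
#'
#' @param m a `lem_entropy_map` or [lem_volume()].
#' @param voi a non-empty [lem_mask()] on the same grid (e.g. the Tumor-VOI).
#' @return A `lem_stats` object: the 11 statistics plus `voi_voxel_count`,
#'   `n_dropped` and `source_stage` metadata.
#' @export
extract_histogram_stats <- function(m, voi) {
  vv <- voi_values(m, voi)
  stage <- if (inherits(m, "lem_entropy_map")) map_stage(m) else "raw_hu"
  stats_from_values(vv$values, source_stage = stage, dropped = vv$dropped)
}

#' Histogram statistics of the Hounsfield units inside a VOI
#'
#' The parallel workflow on the raw CT: identical machinery to
#' [extract_histogram_stats()], applied to the HU values of the input volume.
#'
#' @param ct a CT [lem_volume()] in HU.
#' @param voi a non-empty [lem_mask()].
#' @return A `lem_stats` object with `source_stage = "raw_hu"`.
#' @export
hounsfield_stats <- function(ct, voi) {
  vv <- voi_values(ct, voi)
  stats_from_values(vv$values, source_stage = "raw_hu", dropped = vv$dropped)
}

#' Global first-order entropy of a VOI
#'
#' Shannon entropy of the in-VOI intensity histogram, discretized into
#' `n_bins` equal-width bins spanning the in-VOI min-max range. This is an
#' equal-width-binned first-order entropy — an approximation of, not a
#' replica of, values produced by external radiomics software, whose binning
#' is not reproduced here.
#'
#' @param v a [lem_volume()] or `lem_entropy_map`.
#' @param voi a non-empty [lem_mask()].
#' @param n_bins number of histogram bins (>= 2).
#' @param log_base `"e"` (nats) or `"2"` (bits).
#' @return Scalar entropy; 0 for a constant region.
#' @export
global_entropy <- function(v, voi, n_bins = 64L, log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2")
  vals <- voi_values(v, voi)$values
  rng <- range(vals)
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(pmin(findInterval(vals, br, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  p <- cnt[cnt > 0] / length(vals)
  h <- -sum(p * log(p))
  if (log_base == "2") h / log(2) else h
}

#' @export
print.lem_stats <- function(x, ...) {
  cat("<lem_stats> source:", x$source_stage,
      sprintf("(%d voxels)\n", x$voi_voxel_count))
  df <- as.data.frame(x)
  print(df[, stat_names()], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.lem_stats <- function(x, ...) {
  data.frame(x[c(stat_names(), "voi_voxel_count", "n_dropped",
                 "source_stage")],
             stringsAsFactors = FALSE)
}

#' Compare two subject groups on each histogram statistic
#'
#' For each of the 11 statistics, values are z-score standardized across all
#' subjects, then the two groups are compared with a two-sided Mann-Whitney U
#' test (exact distribution when the combined sample size is at most 20 and
#' there are no ties; normal approximation with tie and continuity correction
#' otherwise). Raw per-statistic p-values are reported against the 0.05
#' significance threshold; Benjamini-Hochberg adjustment is available via
#' `adjust = "BH"`.
#'
#' A statistic that is identical across all subjects leaves the test
#' undefined; the row is flagged `degenerate` with `NA` p-value rather than
#' failing.
#'
#' @param stats_by_subject list of `lem_stats`, one per subject.
#' @param labels binary group labels (length matching the list); e.g.
#'   responders vs non-responders.
#' @param adjust `"none"` (default, matching uncorrected per-variable
#'   p-values) or `"BH"`.
#' @return A `lem_comparison`: data frame with one row per statistic —
#'   standardized group medians, U statistic, p-value, direction and
#'   significance at 0.05.
#' @export
compare_groups <- function(stats_by_subject, labels, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two groups")
  if (length(stats_by_subject) != length(labels))
    stop("one label per subject is required")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("each group needs at least 2 subjects; got ",
         paste(tab, collapse = " and "))
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  rows <- lapply(stat_names(), function(s) {
    x <- vapply(stats_by_subject, function(st) as.numeric(st[[s]]), 0)
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx == 0) {
      return(data.frame(statistic = s, median_g1 = NA_real_,
                        median_g2 = NA_real_, U = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    z <- (x - mean(x)) / sdx
    z1 <- z[labels == g1]; z2 <- z[labels == g2]
    exact <- (length(z1) + length(z2)) <= 20L && !anyDuplicated(z)
    wt <- suppressWarnings(
      stats::wilcox.test(z1, z2, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    data.frame(statistic = s,
               median_g1 = stats::median(z1), median_g2 = stats::median(z2),
               U = unname(wt$statistic), p_value = wt$p.value,
               direction = if (stats::median(z2) > stats::median(z1))
                 paste(g2, ">", g1) else paste(g1, ">", g2),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) &
    (if (adjust == "BH") out$p_adjusted else out$p_value) < 0.05
  attr(out, "groups") <- c(g1, g2)
  attr(out, "n_per_group") <- as.integer(tab)
  class(out) <- c("lem_comparison", class(out))
  out
}

#' @export
print.lem_comparison <- function(x, ...) {
  g <- attr(x, "groups"); n <- attr(x, "n_per_group")
  cat(sprintf("<lem_comparison> %s (n=%d) vs %s (n=%d), Mann-Whitney U, alpha=0.05\n",
              g[1], n[1], g[2], n[2]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
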