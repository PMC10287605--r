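#' Kernel configuration for local entropy
#'
#' @param k odd kernel side length in voxels, >= 3. The default 5 gives the
#'   5x5x5 neighborhood used throughout the pipeline as the trade-off between
#'   spatial resolution and noise smoothing.
#' @param bin_width intensity units per symbol bin; symbols are formed by
#'   flooring `value / bin_width`. Default 1, i.e. integer HU values act as
#'   distinct symbols.
#' @param padding `"reflect"` (mirror padding; map keeps the full volume
#'   shape) or `"exclude-border"` (the (k-1)/2-voxel border shell is marked
#'   missing).
#' @return A `lem_kernel` config list.
#' @export
kernel_config <- function(k = 5L, bin_width = 1,
                          padding = c("reflect", "exclude-border")) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L)
    stop("kernel side k must be an odd integer >= 3")
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  padding <- match.arg(padding)
  structure(list(k = k, bin_width = bin_width, padding = padding),
            class = "lem_kernel")
}

#' Shannon entropy of a multiset of intensities
#'
#' First-order entropy in nats: `-sum_i P(i) ln P(i)` where `P(i)` is the
#' probability of occurrence of symbol `i` among the values, and symbols are
#' formed by flooring `value / bin_width`. Always in `[0, ln(length(values))]`.
#'
#' @param values non-empty numeric vector of finite intensities.
#' @param bin_width intensity units per symbol bin (> 0).
#' @return Entropy in nats (scalar).
#' @examples
#' kernel_entropy(rep(40, 125))            # 0: a single symbol
#' kernel_entropy(1:125)                   # log(125): all distinct
#' kernel_entropy(c(rep(40, 100), rep(60, 25)))  # two-symbol split
#' @export
kernel_entropy <- function(values, bin_width = 1) {
  if (length(values) == 0L) stop("empty input: entropy needs at least one value")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  sym <- floor(as.vector(values) / bin_width)
  cnt <- tabulate(match(sym, sort(unique(sym))))  # counts in ascending symbol order
  p <- cnt / length(values)
  -sum(p * log(p))
}

# symmetric (mirror, edge-including) padding indices for one axis
reflect_index <- function(i, n) {
  # maps any integer index onto 1..n by reflection about the array edges
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j)
}

pad_reflect <- function(a, r) {
  d <- dim(a)
  ix <- reflect_index(seq.int(1L - r, d[1] + r), d[1])
  iy <- reflect_index(seq.int(1L - r, d[2] + r), d[2])
  iz <- reflect_index(seq.int(1L - r, d[3] + r), d[3])
  a[ix, iy, iz, drop = FALSE]
}

#' Compute the voxel-wise local entropy map
#'
#' Slides a cubic k x k x k kernel over the volume with a one-voxel stride;
#' each output voxel holds the Shannon entropy (nats, [kernel_entropy()]) of
#' its neighborhood, saved as the local entropy of the central voxel. The
#' output has the same shape as the input; with `"reflect"` padding every
#' voxel is defined, with `"exclude-border"` the border shell is `NA`.
#'
#' @param v a [lem_volume()].
#' @param cfg a [kernel_config()].
#' @return A `lem_entropy_map` (subclass of `lem_volume`) with the kernel
#'   config and stage flags attached.
#' @export
local_entropy_map <- function(v, cfg = kernel_config()) {
  stopifnot(inherits(v, "lem_volume"), inherits(cfg, "lem_kernel"))
  d <- dim(v$data)
  r <- (cfg$k - 1L) %/% 2L
  if (cfg$padding == "exclude-border" && any(d < cfg$k))
    stop("volume (", paste(d, collapse = "x"),
         ") smaller than kernel k=", cfg$k, " with exclude-border padding")
  sym <- array(as.integer(floor(v$data / cfg$bin_width)), dim = d)
  if (cfg$padding == "reflect") {
    padded <- pad_reflect(sym, r)
    ent <- local_entropy_cpp(as.integer(padded), as.integer(d), cfg$k, TRUE)
  } else {
    ent <- local_entropy_cpp(as.integer(sym), as.integer(d), cfg$k, FALSE)
  }
  m <- lem_volume(array(ent, dim = d), spacing = v$spacing, origin = v$origin,
                  meta = v$meta)
  m$kernel <- cfg
  m$smoothed <- FALSE
  m$sigma <- NA_real_
  m$normalized <- FALSE
  m$reference_mean <- NA_real_
  m$meta$descrip <- sprintf("local entropy map k=%d bin=%g pad=%s",
                            cfg$k, cfg$bin_width, cfg$padding)
  class(m) <- c("lem_entropy_map", class(m))
  m
}

# NA-aware separable 1D convolution along one axis, reflect boundary;
# missing voxels are excluded from the filter support (weights renormalized).
convolve_axis_na <- function(a, w, axis) {
  d <- dim(a)
  r <- (length(w) - 1L) %/% 2L
  num <- array(0, d); den <- array(0, d)
  ok <- !is.na(a)
  a0 <- ifelse(ok, a, 0)
  for (o in seq.int(-r, r)) {
    idx <- reflect_index(seq_len(d[axis]) + o, d[axis])
    sl <- switch(axis,
                 `1` = list(idx, TRUE, TRUE),
                 `2` = list(TRUE, idx, TRUE),
                 `3` = list(TRUE, TRUE, idx))
    av <- do.call(`[`, c(list(a0), sl, list(drop = FALSE)))
    kv <- do.call(`[`, c(list(ok * 1), sl, list(drop = FALSE)))
    wt <- w[o + r + 1L]
    num <- num + wt * av
    den <- den + wt * kv
  }
  out <- num / den
  out[!ok] <- NA_real_
  out
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  w <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian-smooth an entropy map
#'
#' Separable 3D Gaussian filter (kernel truncated at 4 sigma, reflect
#' boundary). Missing border voxels from `exclude-border` padding are left
#' missing and excluded from the filter support of their neighbors.
#'
#' @param m an unsmoothed `lem_entropy_map`.
#' @param sigma Gaussian standard deviation in voxels (> 0); default 1.
#' @return The smoothed map with its `smoothed` flag set.
#' @export
smooth_map <- function(m, sigma = 1) {
  stopifnot(inherits(m, "lem_entropy_map"))
  if (isTRUE(m$smoothed)) stop("map is already smoothed")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  w <- gaussian_kernel_1d(sigma)
  a <- m$data
  for (ax in 1:3) a <- convolve_axis_na(a, w, ax)
  m$data <- a
  m$smoothed <- TRUE
  m$sigma <- sigma
  m$meta$descrip <- paste0(m$meta$descrip, sprintf(" smooth=%g", sigma))
  m
}

#' Normalize an entropy map to the liver-parenchyma reference
#'
#' Divides every voxel by the mean map value inside the liver mask (the
#' "virtual liver biopsy" reference), so the liver mean becomes exactly 1.
#' `method = "subtract"` instead subtracts the reference mean (liver mean
#' becomes 0).
#'
#' @param m a `lem_entropy_map`.
#' @param liver a non-empty [lem_mask()] on the same grid.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return The normalized map with the reference mean recorded.
#' @export
normalize_map <- function(m, liver, method = c("divide", "subtract")) {
  stopifnot(inherits(m, "lem_entropy_map"), inherits(liver, "lem_mask"))
  method <- match.arg(method)
  check_same_grid(m, liver)
  vals <- m$data[liver$data]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("empty VOI: liver mask has no valid voxel")
  ref <- mean(vals)
  if (method == "divide" && abs(ref) < 1e-12)
    stop("normalization undefined: liver reference mean is zero ",
         "(constant liver region)")
  m$data <- if (method == "divide") m$data / ref else m$data - ref
  m$normalized <- TRUE
  m$reference_mean <- ref
  m$meta$descrip <- paste0(m$meta$descrip,
                           sprintf(" norm=%s ref=%.6g", method, ref))
  m
}

#' @export
print.lem_entropy_map <- function(x, ...) {
  cat("<lem_entropy_map> ", fmt_grid(grid_of(x)), "\n", sep = "")
  cat(sprintf("  kernel k=%d bin_width=%g padding=%s\n",
              x$kernel$k, x$kernel$bin_width, x$kernel$padding))
  cat(sprintf("  smoothed: %s%s; normalized: %s%s\n",
              x$smoothed, if (isTRUE(x$smoothed))
                sprintf(" (sigma=%g)", x$sigma) else "",
              x$normalized, if (isTRUE(x$normalized))
                sprintf(" (reference mean %.4g)", x$reference_mean) else ""))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  value range: [%.4g, %.4g] nats\n", rng[1], rng[2]))
  invisible(x)
}

#' Coerce a volume to an entropy map
#'
#' Re-attaches entropy-map metadata to a volume, e.g. after reading a map
#' back from NIfTI (the file stores only the description string). The stage
#' flags must be supplied by the caller.
#'
#' @param v a [lem_volume()] holding entropy values in nats.
#' @param kernel the [kernel_config()] the map was computed with.
#' @param smoothed,sigma,normalized,reference_mean stage flags to record.
#' @return A `lem_entropy_map`.
#' @export
as_entropy_map <- function(v, kernel = kernel_config(), smoothed = FALSE,
                           sigma = NA_real_, normalized = FALSE,
                           reference_mean = NA_real_) {
  stopifnot(inherits(v, "lem_volume"))
  v$kernel <- kernel
  v$smoothed <- smoothed
  v$sigma <- sigma
  v$normalized <- normalized
  v$reference_mean <- reference_mean
  if (!inherits(v, "lem_entropy_map"))
    class(v) <- c("lem_entropy_map", class(v))
  v
}

#' Map stage label
#'
#' @param m a `lem_entropy_map`.
#' @return `"raw"`, `"smoothed"` or `"normalized"`.
#' @export
map_stage <- function(m) {
  if (isTRUE(m$normalized)) "normalized"
  else if (isTRUE(m$smoothed)) "smoothed"
  else "raw"
}
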