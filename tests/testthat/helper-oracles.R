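# Independent brute-force oracles shared across tests. These deliberately
# avoid the package's padding and entropy code paths: padding is done by
# explicit index reflection and entropy is either recomputed from the
# printed formula or delegated to kernel_entropy where the contract under
# test is the map assembly, not the formula.

# mirror (edge-including) reflection of indices onto 1..n
reflect_idx <- function(i, n) {
  p <- 2 * n
  j <- (i - 1) %% p
  ifelse(j < n, j + 1, p - j)
}

# plain-formula entropy: -sum P(i) ln P(i) over integer-floored symbols
entropy_formula <- function(values, bin_width = 1) {
  p <- as.vector(table(floor(as.vector(values) / bin_width))) / length(values)
  -sum(p * log(p))
}

# per-voxel brute-force local entropy map with reflect padding
brute_force_map <- function(data, k, bin_width = 1, fun = kernel_entropy) {
  d <- dim(data)
  r <- (k - 1) / 2
  out <- array(NA_real_, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    nb <- data[reflect_idx((x - r):(x + r), d[1]),
               reflect_idx((y - r):(y + r), d[2]),
               reflect_idx((z - r):(z + r), d[3])]
    out[x, y, z] <- fun(nb, bin_width)
  }
  out
}

random_volume <- function(n = 16, symbols = 0:9, seed = 1) {
  set.seed(seed)
  lem_volume(array(sample(symbols, n^3, replace = TRUE), c(n, n, n)))
}

# a small, fast phantom spec for tests that only need the mechanics
small_phantom_spec <- function(pattern, seed,
                               lesion_radius = 8, shape = c(40, 40, 40)) {
  phantom_spec(shape = shape, lesion_radius = lesion_radius,
               pattern = pattern, seed = seed)
}

# build an entropy-map object around given data (for tests that need to
# inject known values into the smoothing/normalization stages)
map_with_data <- function(data, spacing = c(1, 1, 1)) {
  m <- local_entropy_map(lem_volume(array(0, dim(data)), spacing),
                         kernel_config(k = 3))
  m$data <- data
  m
}
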