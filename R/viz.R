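# map scalar values to palette colors; returns [h, w, 3] array in [0,1]
colorize <- function(slice2d, palette, value_range, n_colors = 256L) {
  cols <- grDevices::hcl.colors(n_colors, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  lo <- value_range[1]; hi <- value_range[2]
  f <- if (hi > lo) (slice2d - lo) / (hi - lo) else array(0, dim(slice2d))
  idx <- pmin(pmax(floor(f * n_colors) + 1L, 1L), n_colors)
  idx[is.na(slice2d)] <- NA_integer_
  out <- array(0, c(dim(slice2d), 3L))
  for (ch in 1:3) {
    v <- rgbm[ch, idx]
    v[is.na(idx)] <- 0  # missing voxels render black
    out[, , ch] <- v
  }
  out
}

extract_slice <- function(data, axis = c("axial", "coronal", "sagittal"),
                          index) {
  axis <- match.arg(axis)
  d <- dim(data)
  ax <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  if (index < 1L || index > d[ax])
    stop("slice index ", index, " out of range 1..", d[ax], " on ", axis,
         " axis")
  switch(axis,
         sagittal = data[index, , ],
         coronal = data[, index, ],
         axial = data[, , index])
}

make_colorbar <- function(palette, height, width = 16L, n_colors = 256L) {
  ramp <- matrix(rev(seq(0, 1, length.out = height)), nrow = height,
                 ncol = width)
  colorize(ramp, palette, c(0, 1), n_colors)
}

#' Render one slice of an entropy map
#'
#' Encodes the entropy values of an axial/coronal/sagittal slice with a
#' dedicated color palette and attaches a color bar. Passing a fixed
#' `value_range` makes renders comparable across slices and subjects; with
#' the default `NULL` the slice's own finite min-max is used, so the extreme
#' voxels map exactly to the palette endpoints.
#'
#' @param m a `lem_entropy_map` (or any [lem_volume()]).
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param index 1-based slice index along that axis.
#' @param palette a `grDevices::hcl.colors` palette name; the default
#'   `"viridis"` is perceptually uniform and sequential.
#' @param value_range optional `c(lo, hi)` shared across renders.
#' @return A `lem_raster`: `image` (`[h, w, 3]` RGB in `[0,1]`), `colorbar`,
#'   and the palette/range metadata. Write with [save_raster_png()].
#' @export
render_slice <- function(m, axis = c("axial", "coronal", "sagittal"),
                         index, palette = "viridis", value_range = NULL) {
  axis <- match.arg(axis)
  sl <- extract_slice(m$data, axis, index)
  if (is.null(value_range)) {
    value_range <- range(sl, na.rm = TRUE, finite = TRUE)
    if (!all(is.finite(value_range))) value_range <- c(0, 1)
  }
  img <- colorize(sl, palette, value_range)
  structure(list(image = img,
                 colorbar = make_colorbar(palette, dim(img)[1]),
                 palette = palette, value_range = value_range,
                 axis = axis, index = index),
            class = "lem_raster")
}

#' Render a CT slice with an entropy-map fusion overlay
#'
#' Grayscale CT (windowed to `window` HU) alpha-blended with the colorized
#' entropy map, the way PET-CT is read in fusion mode. `alpha = 0`
#' reproduces the plain CT render exactly; `alpha = 1` reproduces the
#' [render_slice()] colors over the CT extent.
#'
#' @param ct the CT [lem_volume()].
#' @param m the `lem_entropy_map` on the same grid.
#' @param axis,index,palette,value_range as in [render_slice()].
#' @param alpha overlay opacity in `[0, 1]`.
#' @param window CT display window `c(lo, hi)` in HU.
#' @return A `lem_raster`.
#' @export
render_fusion <- function(ct, m, axis = c("axial", "coronal", "sagittal"),
                          index, alpha = 0.5, palette = "viridis",
                          value_range = NULL, window = c(-150, 250)) {
  axis <- match.arg(axis)
  check_same_grid(ct, m)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  ctsl <- extract_slice(ct$data, axis, index)
  g <- pmin(pmax((ctsl - window[1]) / (window[2] - window[1]), 0), 1)
  gray <- array(rep(g, 3L), c(dim(g), 3L))
  overlay <- render_slice(m, axis, index, palette, value_range)
  img <- (1 - alpha) * gray + alpha * overlay$image
  structure(list(image = img, colorbar = overlay$colorbar,
                 palette = palette, value_range = overlay$value_range,
                 axis = axis, index = index, alpha = alpha, window = window),
            class = "lem_raster")
}

#' Write a raster (with its color bar) to PNG
#'
#' @param x a `lem_raster`.
#' @param path output `.png` path.
#' @return Invisibly, `path`.
#' @export
save_raster_png <- function(x, path) {
  stopifnot(inherits(x, "lem_raster"))
  h <- dim(x$image)[1]
  sep <- array(1, c(h, 2L, 3L))  # white separator column
  full <- array(0, c(h, dim(x$image)[2] + 2L + dim(x$colorbar)[2], 3L))
  full[, seq_len(dim(x$image)[2]), ] <- x$image
  full[, dim(x$image)[2] + 1:2, ] <- sep
  full[, (dim(x$image)[2] + 3L):dim(full)[2], ] <- x$colorbar
  png::writePNG(full, path)
  invisible(path)
}

#' @export
print.lem_raster <- function(x, ...) {
  cat(sprintf("<lem_raster> %s slice %d, %dx%d px, palette %s, range [%.4g, %.4g]\n",
              x$axis, x$index, dim(x$image)[1], dim(x$image)[2], x$palette,
              x$value_range[1], x$value_range[2]))
  invisible(x)
}
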