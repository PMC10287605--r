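#' Construct a volume
#'
#' A `lem_volume` is the package's in-memory representation of a 3D scalar
#' image: a numeric array plus voxel spacing and physical origin in mm, and a
#' free-form metadata list. CT inputs carry Hounsfield units (HU); entropy
#' maps carry nats.
#'
#' Voxels are addressed 0-based conceptually but stored as a plain R array
#' (1-based indexing); the canonical axis order is the NIfTI storage order
#' (i, j, k) = (fastest, middle, slowest varying), which R arrays preserve.
#' All kernel and rim geometry downstream is defined in this voxel space.
#'
#' @param data 3D numeric array; no NaN/Inf.
#' @param spacing length-3 positive numeric, voxel size per axis in mm.
#' @param origin length-3 numeric, physical offset per axis in mm.
#' @param meta named list of provenance entries.
#' @return An object of class `lem_volume`.
#' @export
lem_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all three volume dimensions must be >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), meta = meta),
            class = "lem_volume")
}

#' Construct a mask
#'
#' A `lem_mask` is a boolean 3D grid on the same lattice as a companion
#' volume, used as a volume of interest (VOI): Tumor-VOI or Liver-VOI.
#'
#' @param data 3D logical (or coercible) array; nonzero means inside.
#' @param spacing,origin as in [lem_volume()].
#' @return An object of class `lem_mask`.
#' @export
lem_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  m <- array(as.logical(data) & !is.na(data), dim = dim(data))
  structure(list(data = m, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "lem_mask")
}

grid_of <- function(x) list(shape = dim(x$data), spacing = x$spacing,
                            origin = x$origin)

fmt_grid <- function(g) {
  sprintf("shape %s, spacing (%s) mm, origin (%s) mm",
          paste(g$shape, collapse = "x"),
          paste(format(g$spacing, trim = TRUE), collapse = ", "),
          paste(format(g$origin, trim = TRUE), collapse = ", "))
}

#' Check that two objects share a voxel grid
#'
#' Shapes must match exactly; spacing and origin to within `tol` mm.
#'
#' @param a,b `lem_volume`/`lem_mask` objects.
#' @param tol tolerance in mm on spacing and origin.
#' @return Invisibly `TRUE`; stops with a message naming both grids otherwise.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  ga <- grid_of(a); gb <- grid_of(b)
  ok <- identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) <= tol) &&
    all(abs(ga$origin - gb$origin) <= tol)
  if (!ok)
    stop("grid mismatch: [", fmt_grid(ga), "] vs [", fmt_grid(gb), "]")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file (`.nii`/`.nii.gz`), applies the stored
#' slope/intercept scaling, squeezes a singleton fourth axis, and returns the
#' data in the file's storage order (the package's canonical orientation).
#'
#' @param path path to a NIfTI file.
#' @return A [lem_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 3D payload (or 4D with singleton fourth axis), got ",
         paste(d, collapse = "x"), " in ", path)
  }
  if (any(!is.finite(img2)))
    stop("volume contains NaN/Inf voxels: ", path)
  hdr <- RNifti::niftiHeader(img)
  lem_volume(img2,
             spacing = abs(hdr$pixdim[2:4]),
             origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z),
             meta = list(path = path, descrip = hdr$descrip))
}

#' Read a NIfTI mask against a reference grid
#'
#' Nonzero voxels become `TRUE`. The file must live on the same grid as
#' `reference` (shape exact; spacing/origin within 1e-4 mm) and contain at
#' least one nonzero voxel.
#'
#' @param path path to a NIfTI file.
#' @param reference the companion [lem_volume()].
#' @return A [lem_mask()].
#' @export
read_mask <- function(path, reference) {
  v <- read_volume(path)
  m <- lem_mask(v$data != 0, spacing = v$spacing, origin = v$origin)
  check_same_grid(m, reference)
  if (!any(m$data)) stop("empty VOI: mask has no nonzero voxel: ", path)
  m
}

#' Write a volume (or mask) to NIfTI
#'
#' Writes a NIfTI-1 file whose round-trip through [read_volume()] recovers
#' data, spacing and origin at the stored precision. If `v$meta$descrip` is
#' set (e.g. entropy-map provenance: kernel size, smoothing sigma), it is
#' stored in the header description field (truncated to 79 bytes by the
#' format).
#'
#' @param v a [lem_volume()] or [lem_mask()].
#' @param path output path (`.nii` or `.nii.gz`); its directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  dat <- if (inherits(v, "lem_mask")) array(as.numeric(v$data), dim(v$data))
         else v$data
  descrip <- if (!is.null(v$meta$descrip)) v$meta$descrip else ""
  hdr <- list(pixdim = c(1, v$spacing, 0, 0, 0, 0),
              qoffset_x = v$origin[1], qoffset_y = v$origin[2],
              qoffset_z = v$origin[3], qform_code = 1L,
              descrip = descrip)
  img <- RNifti::asNifti(dat, hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @export
print.lem_volume <- function(x, ...) {
  cat("<lem_volume> ", fmt_grid(grid_of(x)), "\n", sep = "")
  cat("  intensity range: [", format(min(x$data, na.rm = TRUE)), ", ",
      format(max(x$data, na.rm = TRUE)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.lem_mask <- function(x, ...) {
  cat("<lem_mask> ", fmt_grid(grid_of(x)),
      sprintf("; %d voxels inside\n", sum(x$data)), sep = "")
  invisible(x)
}
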