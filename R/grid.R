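#' Volume grid geometry
#'
#' A `volume_grid` records the shape of a 3D voxel grid together with its
#' voxel dimensions and an origin offset, and is carried alongside every
#' volume, mask and time series in the package so that objects can be checked
#' for geometric compatibility. All per-voxel vectors in the package use
#' R's native 1-based, column-major flat indices over this grid.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric of length 1 or 3, voxel edge lengths in mm.
#' @param origin_offset_mm numeric of length 3, world offset of voxel (1,1,1).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = 2, origin_offset_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be positive", call. = FALSE)
  origin_offset_mm <- as.numeric(origin_offset_mm)
  if (length(origin_offset_mm) != 3L)
    stop("`origin_offset_mm` must have length 3", call. = FALSE)
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_offset_mm = origin_offset_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm, tolerance = 1e-6))
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

#' Convert between voxel (i,j,k) coordinates and flat indices
#'
#' Flat indices are R's native 1-based column-major indices into an array of
#' dimension `grid$shape`.
#'
#' @param grid a [volume_grid()].
#' @param ijk integer matrix with 3 columns of 1-based voxel coordinates.
#' @param flat integer vector of flat voxel indices.
#' @return `voxel_to_flat()` returns flat indices; `flat_to_voxel()` an
#'   n x 3 integer matrix.
#' @export
voxel_to_flat <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  if (any(ijk < 1L) || any(t(ijk) > grid$shape))
    stop("voxel coordinates outside grid bounds", call. = FALSE)
  d <- grid$shape
  ijk[, 1L] + d[1L] * (ijk[, 2L] - 1L) + d[1L] * d[2L] * (ijk[, 3L] - 1L)
}

#' @rdname voxel_to_flat
#' @export
flat_to_voxel <- function(grid, flat) {
  flat <- as.integer(flat)
  if (any(flat < 1L) || any(flat > n_voxels(grid)))
    stop("flat index outside grid", call. = FALSE)
  arrayInd(flat, .dim = grid$shape)
}

#' Binary mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param inside logical array of dimension `grid$shape` (or a logical vector
#'   of length `prod(shape)`), `TRUE` for in-mask voxels.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, inside) {
  if (!inherits(grid, "volume_grid")) stop("`grid` must be a volume_grid")
  inside <- array(as.logical(inside), dim = grid$shape)
  if (anyNA(inside)) stop("mask contains NA", call. = FALSE)
  structure(list(grid = grid, inside = inside), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, %d/%d voxels inside>\n",
              paste(x$grid$shape, collapse = "x"),
              sum(x$inside), length(x$inside)))
  invisible(x)
}

#' @rdname binary_mask
#' @param mask a `binary_mask`.
#' @return `mask_indices()` returns the sorted flat indices of in-mask voxels.
#' @export
mask_indices <- function(mask) which(mask$inside)

#' Integer-labeled volume (ROI atlas)
#'
#' @param grid a [volume_grid()].
#' @param labels integer array of dimension `grid$shape`; 0 is background.
#' @param names named character vector mapping label integers (as names) to
#'   region names, e.g. `c("1" = "MeA", "2" = "CoA")`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, labels, names) {
  labels <- array(as.integer(labels), dim = grid$shape)
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be nonnegative integers", call. = FALSE)
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("labels without names: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(grid = grid, labels = labels,
                 names = vapply(names, as.character, character(1))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s: %s>\n", paste(x$grid$shape, collapse = "x"),
              paste(sprintf("%s=%s", names(x$names), x$names), collapse = ", ")))
  invisible(x)
}
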