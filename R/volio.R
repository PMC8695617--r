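#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI file and returns the grid geometry together with the
#' voxel data as a plain array.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A list with elements `grid` (a [volume_grid()]) and `values`
#'   (a 3D or 4D array).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  dims <- dim(img)
  if (length(dims) < 3L || length(dims) > 4L)
    stop("expected a 3D or 4D volume, got ", length(dims), "D", call. = FALSE)
  pix <- RNifti::pixdim(img)
  grid <- volume_grid(dims[1:3], voxel_size_mm = abs(pix[1:3]))
  values <- array(as.numeric(img), dim = dims)
  list(grid = grid, values = values)
}

#' Write a NIfTI volume
#'
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a [volume_grid()] describing the first three dimensions.
#' @param values 3D array matching `grid$shape`, or 4D array whose first three
#'   dimensions match (the fourth being time).
#' @param tr_seconds repetition time stored in the header for 4D series.
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, grid, values, tr_seconds = NULL) {
  dims <- dim(values)
  if (is.null(dims) || length(dims) < 3L || length(dims) > 4L ||
      !identical(as.integer(dims[1:3]), grid$shape))
    stop("`values` must be a 3D/4D array on the grid ",
         paste(grid$shape, collapse = "x"), call. = FALSE)
  pix <- grid$voxel_size_mm
  if (length(dims) == 4L) pix <- c(pix, if (is.null(tr_seconds)) 1 else tr_seconds)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gray-matter mask from a tissue prior
#'
#' Thresholds a gray-matter prior/probability image: a voxel is inside the
#' mask when its prior value is greater than or equal to `threshold`
#' (voxels exactly at the threshold are kept).
#'
#' @param grid a [volume_grid()].
#' @param prior 3D numeric array of prior values on `grid`.
#' @param threshold inclusion threshold (default 100, the conventional value
#'   for template tissue priors scaled 0-255).
#' @return A [binary_mask()].
#' @export
make_gray_matter_mask <- function(grid, prior, threshold = 100) {
  if (length(dim(prior)) != 3L)
    stop("`prior` must be 3D, got ", length(dim(prior)), "D", call. = FALSE)
  if (!identical(as.integer(dim(prior)), grid$shape))
    stop("prior shape does not match grid", call. = FALSE)
  binary_mask(grid, prior >= threshold)
}

#' Morphological erosion of a binary mask
#'
#' One iteration removes every in-mask voxel that has at least one neighbor
#' outside the mask under the chosen connectivity; the volume boundary counts
#' as outside. The result is always a subset of the input.
#'
#' @param mask a [binary_mask()].
#' @param iterations number of erosion passes (>= 1).
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return The eroded [binary_mask()].
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = 6L) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("`iterations` must be a positive integer", call. = FALSE)
  offs <- neighbor_offsets(connectivity)
  inside <- mask$inside
  d <- dim(inside)
  for (i in seq_len(iterations)) {
    keep <- inside
    for (r in seq_len(nrow(offs))) {
      keep <- keep & shift_array(inside, offs[r, ], fill = FALSE)
    }
    inside <- keep
  }
  binary_mask(mask$grid, inside)
}

# Neighbor offsets for 6/18/26-connectivity (excluding the origin).
neighbor_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  g[keep, , drop = FALSE]
}

# Shift a 3D logical/numeric array by an integer offset, filling exposed
# planes with `fill`.
shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o) + o
      dst[[ax]] <- seq_len(d[ax] - o)
    } else {
      src[[ax]] <- seq_len(d[ax] + o)
      dst[[ax]] <- seq_len(d[ax] + o) - o
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Union of named atlas regions as a mask
#'
#' @param atlas a [label_volume()].
#' @param names character vector of region names to combine.
#' @return A [binary_mask()] covering the union of the named labels' voxels.
#' @export
combine_roi_masks <- function(atlas, names) {
  known <- atlas$names
  unknown <- setdiff(names, known)
  if (length(unknown))
    stop("unknown ROI name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(known, collapse = ", "), call. = FALSE)
  ids <- as.integer(base::names(known)[match(names, known)])
  binary_mask(atlas$grid, array(atlas$labels %in% ids, dim = atlas$grid$shape))
}

#' Write / read an atlas name table
#'
#' The name table is stored as a JSON object mapping label integers to region
#' names, alongside the label NIfTI.
#'
#' @param atlas a [label_volume()].
#' @param path_nii path for the label volume NIfTI.
#' @param path_json path for the JSON name table.
#' @return `read_atlas()` returns a [label_volume()].
#' @export
write_atlas <- function(atlas, path_nii, path_json) {
  write_volume(path_nii, atlas$grid, array(as.numeric(atlas$labels),
                                           dim = atlas$grid$shape))
  jsonlite::write_json(as.list(atlas$names), path_json, auto_unbox = TRUE)
  invisible(path_nii)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path_nii, path_json) {
  v <- read_volume(path_nii)
  nm <- unlist(jsonlite::read_json(path_json))
  label_volume(v$grid, round(v$values), nm)
}
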