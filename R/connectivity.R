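#' Fisher z transform and its inverse
#'
#' `fisher_z()` maps correlations to the variance-stabilized z scale
#' (`atanh`), clipping input to +/- 0.999999 first so that degenerate
#' identical-series correlations stay finite; `fisher_z_inverse()` is `tanh`.
#'
#' @param values numeric vector/matrix of correlations (forward) or z values
#'   (inverse).
#' @param clip clipping bound applied before `atanh`.
#' @return Transformed values, same shape.
#' @export
fisher_z <- function(values, clip = 0.999999) {
  atanh(pmin(pmax(values, -clip), clip))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(values) tanh(values)

#' Connectivity profiles container
#'
#' Seed-voxel by target-voxel matrix of correlations: each row is one seed
#' voxel's whole-brain connectivity profile, the feature vector used for
#' parcellation.
#'
#' @param seed_voxels,target_voxels sorted flat voxel indices (duplicate-free;
#'   targets exclude all seeds).
#' @param values numeric matrix, `length(seed_voxels)` x
#'   `length(target_voxels)`.
#' @param scale `"r"` (Pearson) or `"z"` (Fisher).
#' @param grid optional [volume_grid()] the indices refer to.
#' @return An object of class `connectivity_profiles`.
#' @export
connectivity_profiles <- function(seed_voxels, target_voxels, values,
                                  scale = c("r", "z"), grid = NULL) {
  scale <- match.arg(scale)
  seed_voxels <- as.integer(seed_voxels)
  target_voxels <- as.integer(target_voxels)
  if (anyDuplicated(seed_voxels) || anyDuplicated(target_voxels))
    stop("voxel lists must be duplicate-free", call. = FALSE)
  if (length(intersect(seed_voxels, target_voxels)))
    stop("target list must exclude every seed voxel", call. = FALSE)
  values <- as.matrix(values)
  if (!identical(dim(values), c(length(seed_voxels), length(target_voxels))))
    stop("`values` must be seeds x targets", call. = FALSE)
  if (scale == "r" && any(abs(values) > 1 + 1e-12, na.rm = TRUE))
    stop("r-scale values must lie in [-1, 1]", call. = FALSE)
  structure(list(seed_voxels = seed_voxels, target_voxels = target_voxels,
                 values = values, scale = scale, grid = grid),
            class = "connectivity_profiles")
}

#' @export
print.connectivity_profiles <- function(x, ...) {
  cat(sprintf("<connectivity_profiles %d seeds x %d targets, scale=%s>\n",
              length(x$seed_voxels), length(x$target_voxels), x$scale))
  invisible(x)
}

#' Voxelwise seed-to-brain connectivity profiles
#'
#' Computes, for every voxel in the seed mask, the Pearson correlation of its
#' time course with every voxel of the target mask outside the seed mask
#' ("every other voxel in the rest of the brain"). The whole seed mask is
#' excluded from the target space so every seed voxel has the same feature
#' dimensionality and no trivial self-similarity.
#'
#' @param series a [bold_series()].
#' @param seed_mask,target_mask [binary_mask()]s on the series grid.
#' @param exclude one of `"seed_mask"` (default: all seed voxels excluded
#'   from targets) or `"self"` (only each seed's own voxel is dropped —
#'   not supported for profile matrices; provided for API symmetry and
#'   validated).
#' @return A [connectivity_profiles()] on the r scale.
#' @export
voxelwise_profiles <- function(series, seed_mask, target_mask,
                               exclude = c("seed_mask", "self")) {
  exclude <- match.arg(exclude)
  if (exclude == "self")
    stop("per-seed self-exclusion changes the feature space per seed; ",
         "use exclude = \"seed_mask\"", call. = FALSE)
  stopifnot_same_grid(series$grid, seed_mask$grid, "series and seed mask")
  stopifnot_same_grid(series$grid, target_mask$grid, "series and target mask")
  seeds <- mask_indices(seed_mask)
  targets <- setdiff(mask_indices(target_mask), seeds)
  if (length(seeds) == 0L) stop("seed mask is empty", call. = FALSE)
  if (length(targets) == 0L)
    stop("target mask minus seed mask is empty", call. = FALSE)
  X <- series$data[, seeds, drop = FALSE]
  Y <- series$data[, targets, drop = FALSE]
  bad <- c(seeds[apply(X, 2L, stats::sd) == 0],
           targets[apply(Y, 2L, stats::sd) == 0])
  if (length(bad))
    stop("zero-variance voxel(s) at flat index: ",
         paste(utils::head(bad, 20L), collapse = ", "), call. = FALSE)
  r <- stats::cor(X, Y)
  connectivity_profiles(seeds, targets, r, scale = "r", grid = series$grid)
}

#' Group-average connectivity profiles
#'
#' Averages per-subject r-scale profiles on the Fisher z scale and transforms
#' the mean back to Pearson r: `tanh(mean(atanh(r)))` elementwise.
#'
#' @param profiles list of [connectivity_profiles()] (scale `"r"`) with
#'   identical seed and target voxel lists.
#' @return The group-level [connectivity_profiles()] (scale `"r"`).
#' @export
group_average_profiles <- function(profiles) {
  if (length(profiles) < 1L) stop("empty profile list", call. = FALSE)
  ref <- profiles[[1]]
  for (p in profiles) {
    if (p$scale != "r") stop("profiles must be on the r scale", call. = FALSE)
    if (!identical(p$seed_voxels, ref$seed_voxels) ||
        !identical(p$target_voxels, ref$target_voxels))
      stop("profiles have mismatched voxel lists", call. = FALSE)
  }
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (p in profiles) acc <- acc + fisher_z(p$values)
  connectivity_profiles(ref$seed_voxels, ref$target_voxels,
                        fisher_z_inverse(acc / length(profiles)),
                        scale = "r", grid = ref$grid)
}

#' ROI-seed whole-brain connectivity map
#'
#' Correlates the mean time course over an ROI with every brain voxel outside
#' the ROI and returns the Fisher-z map; ROI voxels are `NA`.
#'
#' @param series a [bold_series()].
#' @param roi nonempty [binary_mask()] (the seed region).
#' @param brain [binary_mask()] of analysis voxels (must contain the ROI).
#' @return 3D array of Fisher-z values, `NA` at ROI voxels and outside the
#'   brain mask.
#' @export
roi_seed_map <- function(series, roi, brain) {
  stopifnot_same_grid(series$grid, roi$grid, "series and roi")
  stopifnot_same_grid(series$grid, brain$grid, "series and brain mask")
  roi_idx <- mask_indices(roi)
  if (length(roi_idx) == 0L) stop("roi is empty", call. = FALSE)
  if (any(roi$inside & !brain$inside))
    stop("brain mask must contain the roi", call. = FALSE)
  seed_ts <- rowMeans(series$data[, roi_idx, drop = FALSE])
  if (stats::sd(seed_ts) == 0) stop("zero-variance seed time course", call. = FALSE)
  vox <- setdiff(mask_indices(brain), roi_idx)
  Y <- series$data[, vox, drop = FALSE]
  sds <- apply(Y, 2L, stats::sd)
  r <- rep(0, length(vox))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(seed_ts, Y[, ok, drop = FALSE]))
  out <- array(NA_real_, dim = series$grid$shape)
  out[vox] <- fisher_z(r)
  out
}

#' Persist / load connectivity profiles
#'
#' Profiles are stored as a plain-text matrix (TSV, seeds in rows) plus a JSON
#' sidecar recording the grid, voxel lists and scale.
#'
#' @param profiles a [connectivity_profiles()].
#' @param path_tsv,path_json output paths.
#' @return `read_profiles()` returns a [connectivity_profiles()].
#' @export
write_profiles <- function(profiles, path_tsv, path_json) {
  utils::write.table(profiles$values, path_tsv, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- list(seed_voxels = profiles$seed_voxels,
               target_voxels = profiles$target_voxels,
               scale = profiles$scale,
               grid = if (!is.null(profiles$grid))
                 list(shape = profiles$grid$shape,
                      voxel_size_mm = profiles$grid$voxel_size_mm))
  jsonlite::write_json(side, path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path_tsv, path_json) {
  side <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path_tsv, sep = "\t"))
  dimnames(vals) <- NULL
  grid <- if (!is.null(side$grid))
    volume_grid(side$grid$shape, side$grid$voxel_size_mm)
  connectivity_profiles(side$seed_voxels, side$target_voxels, vals,
                        scale = side$scale, grid = grid)
}
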