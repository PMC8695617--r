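#' One-sample group statistic map
#'
#' Per-voxel one-sample t statistic of the subjects' values (typically
#' Fisher-z connectivity maps) against zero: `mean / (sd / sqrt(n))`, with
#' the standard deviation floored at 1e-12 so identical values give a large
#' but finite statistic.
#'
#' @param maps list of per-subject 3D arrays on a common grid (NA allowed
#'   outside the mask), or a subjects x voxels matrix.
#' @param mask [binary_mask()] of analysis voxels.
#' @return 3D array of t values, `NA` outside the mask.
#' @export
group_onesample_stat <- function(maps, mask) {
  M <- maps_to_matrix(maps, mask)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  t <- colwise_tstat(M)
  out <- array(NA_real_, dim = mask$grid$shape)
  out[mask_indices(mask)] <- t
  out
}

# Vectorized one-sample t over columns, sd floored at 1e-12.
colwise_tstat <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  v <- (colSums(M * M) - n * mu^2) / (n - 1)
  sdv <- pmax(sqrt(pmax(v, 0)), 1e-12)
  mu / (sdv / sqrt(n))
}

# Coerce a list of 3D arrays (or a matrix) to subjects x in-mask voxels.
maps_to_matrix <- function(maps, mask) {
  idx <- mask_indices(mask)
  if (is.matrix(maps)) {
    if (ncol(maps) == length(idx)) return(maps)
    if (ncol(maps) == n_voxels(mask$grid)) return(maps[, idx, drop = FALSE])
    stop("matrix columns match neither mask nor grid", call. = FALSE)
  }
  M <- t(vapply(maps, function(a) {
    if (!identical(as.integer(dim(a)), mask$grid$shape))
      stop("map shape does not match mask grid", call. = FALSE)
    a[idx]
  }, numeric(length(idx))))
  if (anyNA(M)) stop("NA subject values inside the analysis mask", call. = FALSE)
  M
}

#' Threshold-free cluster enhancement
#'
#' Enhances a statistic map by integrating, over thresholds `h = dh, 2dh,
#' ...` up to the map maximum, the quantity `e(h, v)^E * h^H * dh`, where
#' `e(h, v)` is the voxel count of the connected component containing `v` in
#' the suprathreshold set `{map >= h}`. Negative values contribute nothing
#' (one-sided positive enhancement).
#'
#' @param stat_map 3D array (NA allowed outside the mask).
#' @param mask [binary_mask()]; defaults to all finite voxels.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step; `NULL` (default) uses `max(map)/n_steps`.
#' @param n_steps number of integration steps when `dh` is `NULL`
#'   (default 100).
#' @param connectivity 6 (default), 18 or 26.
#' @return 3D array of enhanced values (0 where the map is <= 0), `NA`
#'   outside the mask.
#' @export
tfce_transform <- function(stat_map, mask = NULL, E = 0.5, H = 2,
                           dh = NULL, n_steps = 100L, connectivity = 6L) {
  d <- dim(stat_map)
  if (length(d) != 3L) stop("`stat_map` must be 3D", call. = FALSE)
  if (is.null(mask)) {
    mask_arr <- is.finite(stat_map)
  } else {
    mask_arr <- mask$inside
    if (!identical(as.integer(dim(mask_arr)), as.integer(d)))
      stop("mask shape does not match map", call. = FALSE)
  }
  if (!is.null(dh) && dh <= 0) stop("`dh` must be positive", call. = FALSE)
  vals <- stat_map
  vals[!mask_arr] <- 0
  enh <- .tfce_cpp(as.numeric(vals), as.integer(d), as.logical(mask_arr),
                   E, H, if (is.null(dh)) -1 else dh, as.integer(n_steps),
                   as.integer(connectivity))
  out <- array(NA_real_, dim = d)
  out[mask_arr] <- enh[mask_arr]
  out
}

#' Sign-flip permutation FWE correction with max-TFCE
#'
#' Nonparametric one-sample group inference: the observed group t map is
#' TFCE-enhanced; each permutation multiplies every subject's map by an
#' independent random +/-1 (valid under a symmetric null), recomputes the
#' enhanced map and records its maximum over the mask. The FWE-corrected
#' p value of voxel v is `(1 + #[perm maxima >= enhanced(v)]) / (1 +
#' n_perms)`; the binary map thresholds it at `alpha`.
#'
#' @param maps list of per-subject 3D arrays (Fisher-z maps) or a subjects x
#'   voxels matrix.
#' @param mask [binary_mask()] of analysis voxels.
#' @param n_perms number of sign-flip permutations (>= 100).
#' @param alpha FWE level (default 0.05).
#' @param E,H,dh,n_steps,connectivity TFCE parameters, see
#'   [tfce_transform()].
#' @param seed RNG seed.
#' @return An object of class `group_stat_map`: list with `grid`, `mask`,
#'   `stat` (t map), `enhanced`, `p_corrected`, `binary` (logical 3D array),
#'   `perm_maxima`, `alpha`, `n_perms`, `seed`.
#' @export
signflip_fwe <- function(maps, mask, n_perms = 1000L, alpha = 0.05,
                         E = 0.5, H = 2, dh = NULL, n_steps = 100L,
                         connectivity = 6L, seed = 1L) {
  n_perms <- as.integer(n_perms)
  if (n_perms < 100L)
    stop("`n_perms` must be >= 100 for alpha-level resolution", call. = FALSE)
  M <- maps_to_matrix(maps, mask)
  n <- nrow(M)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  idx <- mask_indices(mask)
  d <- mask$grid$shape

  enhance <- function(tv) {
    vals <- numeric(prod(d)); vals[idx] <- tv
    .tfce_cpp(vals, as.integer(d), as.logical(mask$inside), E, H,
              if (is.null(dh)) -1 else dh, as.integer(n_steps),
              as.integer(connectivity))[idx]
  }

  t_obs <- colwise_tstat(M)
  enh_obs <- enhance(t_obs)

  set.seed(derive_seed(seed, "signflip"))
  signs <- matrix(sample(c(-1, 1), n_perms * n, replace = TRUE),
                  nrow = n_perms, byrow = TRUE)
  maxima <- as.numeric(.signflip_maxima_cpp(
    M, as.integer(d), as.logical(mask$inside), signs, E, H,
    if (is.null(dh)) -1 else dh, as.integer(n_steps),
    as.integer(connectivity)))
  # corrected p, monotone in the enhanced value
  pcor <- vapply(enh_obs, function(e) (1 + sum(maxima >= e)) / (1 + n_perms),
                 numeric(1))

  to_arr <- function(v, fill = NA_real_) {
    a <- array(fill, dim = d); a[idx] <- v; a
  }
  structure(list(grid = mask$grid, mask = mask,
                 stat = to_arr(t_obs), enhanced = to_arr(enh_obs),
                 p_corrected = to_arr(pcor),
                 binary = to_arr(pcor < alpha, fill = FALSE) & mask$inside,
                 perm_maxima = maxima, alpha = alpha,
                 n_perms = n_perms, seed = as.integer(seed)),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("<group_stat_map: %d/%d voxels FWE-significant at alpha=%g (%d perms)>\n",
              sum(x$binary), sum(x$mask$inside), x$alpha, x$n_perms))
  invisible(x)
}

#' Network category codes
#'
#' Integer codes of the 8-way partition of voxels by which subregion
#' networks they belong to.
#' @return Named integer vector of category codes.
#' @export
network_categories <- function() {
  c(NONE = 0L, MEA_ONLY = 1L, COA_ONLY = 2L, PAC_ONLY = 3L,
    MEA_COA = 4L, MEA_PAC = 5L, COA_PAC = 6L, ALL = 7L)
}

#' Partition voxels by subregion-network membership
#'
#' Given the three binarized subregion network maps, assigns each voxel to
#' exactly one of 8 mutually exclusive categories: none, one of three
#' unique-network categories, one of three pairwise-shared categories, or
#' all-shared.
#'
#' @param binary_mea,binary_coa,binary_pac logical 3D arrays on one grid
#'   (TRUE = significant connectivity with that subregion).
#' @param grid optional [volume_grid()] carried along.
#' @return An object of class `network_category_map`: list with `grid` and
#'   `category` (integer 3D array of [network_categories()] codes).
#' @export
assign_categories <- function(binary_mea, binary_coa, binary_pac, grid = NULL) {
  d <- dim(binary_mea)
  if (!identical(d, dim(binary_coa)) || !identical(d, dim(binary_pac)))
    stop(sprintf("grid mismatch among binary maps: %s / %s / %s",
                 paste(d, collapse = "x"),
                 paste(dim(binary_coa), collapse = "x"),
                 paste(dim(binary_pac), collapse = "x")), call. = FALSE)
  a <- binary_mea; b <- binary_coa; c <- binary_pac
  cat <- array(0L, dim = d)
  cat[a & !b & !c] <- 1L
  cat[!a & b & !c] <- 2L
  cat[!a & !b & c] <- 3L
  cat[a & b & !c] <- 4L
  cat[a & !b & c] <- 5L
  cat[!a & b & c] <- 6L
  cat[a & b & c] <- 7L
  structure(list(grid = grid, category = cat), class = "network_category_map")
}

#' Venn voxel counts of the three subregion networks
#'
#' @param category_map a [assign_categories()] result.
#' @return Named integer vector of voxel counts for the 7 non-empty
#'   categories (unique, pairwise-shared, all-shared); the counts sum to the
#'   size of the union of the three binary maps.
#' @export
venn_counts <- function(category_map) {
  codes <- network_categories()
  cnt <- vapply(codes[-1], function(k) sum(category_map$category == k),
                integer(1))
  cnt
}
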