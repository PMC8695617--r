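#' Phantom configuration
#'
#' Describes a synthetic multi-subject resting-state dataset with planted
#' subregion-network structure: each "subregion" (a small set of seed voxels,
#' standing in for an amygdala subdivision such as MeA, CoA or PAC) shares a
#' latent low-frequency time course with its own distal "target" region, so
#' that voxels of a subregion have distinctive whole-brain connectivity
#' profiles. Defaults emulate the study conditions the pipeline was designed
#' around: 25 subjects, TR 0.555 s, ~10 minutes of data (1090 volumes,
#' including the 10 later discarded), 2 mm isotropic voxels, and a
#' coupling/noise ratio giving within-network voxel correlations near 0.4.
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param subregions list of subregion descriptions, each a list with `name`
#'   (character), `voxels` (n x 3 integer matrix of 1-based voxel coordinates)
#'   and `targets` (m x 3 integer matrix: that subregion's distal network).
#' @param n_subjects cohort size.
#' @param n_timepoints volumes per subject.
#' @param tr_seconds repetition time.
#' @param voxel_size_mm isotropic voxel size.
#' @param coupling_amplitude gain of the shared latent signal; 0 gives a null
#'   phantom with no planted structure. The default `sqrt(2/3)` with
#'   `noise_sd = 1` yields expected within-network r of 0.4.
#' @param noise_sd standard deviation of i.i.d. Gaussian voxel noise.
#' @param baseline additive constant inside the brain (BOLD mean intensity).
#' @param drift_coeffs_sd sd of per-voxel polynomial drift coefficients
#'   (order-2 basis); 0 disables drift.
#' @param n_motion_regressors number of motion-like nuisance time courses.
#' @param motion_gain_sd sd of per-voxel loadings on the motion regressors.
#' @param tissue_gain gain of the shared white-matter / CSF signals in their
#'   tissue compartments.
#' @param latent_band_hz passband (Hz) of the band-limited latent signals;
#'   chosen inside the conventional resting-state analysis band so planted
#'   structure survives band-pass filtering.
#' @param shared_networks optional list of additional networks shared by
#'   several subregions, each a list with `members` (character, subregion
#'   names), `targets` (m x 3 integer matrix, disjoint from all subregion
#'   voxel sets) and `amplitude`. A shared latent time course is injected
#'   into all member subregions' voxels and into the shared target set,
#'   making the members' connectivity profiles mutually similar (the
#'   structure that lets a k = 2 parcellation separate, e.g., olfactory from
#'   non-olfactory subregions).
#' @param mirror_symmetry if `TRUE`, every subregion and target voxel set is
#'   reflected about the mid-sagittal (x) plane and the mirrored voxels carry
#'   the same subregion identity, tagged with hemisphere.
#' @param master_seed integer seed from which all per-subject streams derive.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape,
                           subregions,
                           n_subjects = 25L,
                           n_timepoints = 1090L,
                           tr_seconds = 0.555,
                           voxel_size_mm = 2,
                           coupling_amplitude = sqrt(2 / 3),
                           noise_sd = 1,
                           baseline = 1000,
                           drift_coeffs_sd = 0.5,
                           n_motion_regressors = 6L,
                           motion_gain_sd = 0.3,
                           tissue_gain = 1,
                           latent_band_hz = c(0.01, 0.08),
                           shared_networks = NULL,
                           mirror_symmetry = FALSE,
                           master_seed = 1L) {
  grid <- volume_grid(grid_shape, voxel_size_mm = voxel_size_mm)
  if (coupling_amplitude < 0)
    stop("`coupling_amplitude` must be nonnegative", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (drift_coeffs_sd < 0) stop("`drift_coeffs_sd` must be >= 0", call. = FALSE)
  n_motion_regressors <- as.integer(n_motion_regressors)
  if (n_motion_regressors < 0L)
    stop("`n_motion_regressors` must be >= 0", call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints <= n_motion_regressors + 2L + 3L)
    stop("`n_timepoints` must exceed the nuisance regressor count + 3",
         call. = FALSE)
  if (length(subregions) < 1L) stop("need at least one subregion", call. = FALSE)
  subregions <- lapply(subregions, function(s) {
    if (is.null(s$name) || is.null(s$voxels) || is.null(s$targets))
      stop("each subregion needs `name`, `voxels`, `targets`", call. = FALSE)
    s$voxels <- matrix(as.integer(s$voxels), ncol = 3L)
    s$targets <- matrix(as.integer(s$targets), ncol = 3L)
    s
  })
  if (!is.null(shared_networks)) {
    nm <- vapply(subregions, `[[`, character(1), "name")
    shared_networks <- lapply(shared_networks, function(g) {
      if (is.null(g$members) || is.null(g$targets) || is.null(g$amplitude))
        stop("each shared network needs `members`, `targets`, `amplitude`",
             call. = FALSE)
      if (!all(g$members %in% nm))
        stop("shared network members must be subregion names", call. = FALSE)
      if (g$amplitude < 0) stop("shared amplitude must be >= 0", call. = FALSE)
      g$targets <- matrix(as.integer(g$targets), ncol = 3L)
      g
    })
  }
  cfg <- structure(list(grid = grid, subregions = subregions,
                        shared_networks = shared_networks,
                        n_subjects = as.integer(n_subjects),
                        n_timepoints = n_timepoints,
                        tr_seconds = tr_seconds,
                        coupling_amplitude = coupling_amplitude,
                        noise_sd = noise_sd, baseline = baseline,
                        drift_coeffs_sd = drift_coeffs_sd,
                        n_motion_regressors = n_motion_regressors,
                        motion_gain_sd = motion_gain_sd,
                        tissue_gain = tissue_gain,
                        latent_band_hz = as.numeric(latent_band_hz),
                        mirror_symmetry = isTRUE(mirror_symmetry),
                        master_seed = as.integer(master_seed)),
                   class = "phantom_config")
  validate_phantom_voxel_sets(cfg)
  cfg
}

# Mirror 1-based x-coordinates about the mid-sagittal plane.
mirror_coords <- function(xyz, nx) {
  out <- xyz
  out[, 1L] <- nx + 1L - out[, 1L]
  out
}

# Expand each subregion's voxel/target sets with mirrored copies (if enabled),
# returning per-subregion lists of flat indices split by hemisphere.
phantom_voxel_sets <- function(cfg) {
  nx <- cfg$grid$shape[1L]
  lapply(cfg$subregions, function(s) {
    v <- list(right = s$voxels)
    t <- list(right = s$targets)
    if (cfg$mirror_symmetry) {
      v$left <- mirror_coords(s$voxels, nx)
      t$left <- mirror_coords(s$targets, nx)
    }
    list(name = s$name,
         voxels = lapply(v, function(m) sort(voxel_to_flat(cfg$grid, m))),
         targets = lapply(t, function(m) sort(voxel_to_flat(cfg$grid, m))))
  })
}

validate_phantom_voxel_sets <- function(cfg) {
  sets <- phantom_voxel_sets(cfg)  # voxel_to_flat errors on out-of-grid
  sub_idx <- lapply(sets, function(s) unlist(s$voxels, use.names = FALSE))
  tar_idx <- lapply(sets, function(s) unlist(s$targets, use.names = FALSE))
  nm <- vapply(sets, `[[`, character(1), "name")
  n <- length(sets)
  if (anyDuplicated(nm)) stop("duplicate subregion names", call. = FALSE)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (length(intersect(sub_idx[[i]], sub_idx[[j]])))
        stop(sprintf("subregions '%s' and '%s' share voxels", nm[i], nm[j]),
             call. = FALSE)
    }
  }
  all_sub <- unlist(sub_idx)
  for (i in seq_len(n)) {
    if (length(intersect(tar_idx[[i]], all_sub)))
      stop(sprintf("target set of '%s' overlaps a subregion voxel set", nm[i]),
           call. = FALSE)
  }
  for (g in shared_network_sets(cfg)) {
    if (length(intersect(g$target_idx, all_sub)))
      stop("a shared-network target set overlaps a subregion voxel set",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Shared-network voxel sets as flat indices (with mirroring applied).
shared_network_sets <- function(cfg) {
  if (is.null(cfg$shared_networks)) return(list())
  nx <- cfg$grid$shape[1L]
  lapply(cfg$shared_networks, function(g) {
    tar <- g$targets
    if (cfg$mirror_symmetry) tar <- rbind(tar, mirror_coords(tar, nx))
    list(members = g$members, amplitude = g$amplitude,
         target_idx = sort(unique(voxel_to_flat(cfg$grid, tar))))
  })
}

#' Build the phantom's anatomy: masks, gray prior, atlas, ground truth
#'
#' Deterministically derives, from a [phantom_config()], the shared brain
#' mask, a gray-matter prior volume (255 in gray matter, 40 in the
#' white-matter shell, 10 in the CSF shell, 0 outside the brain), the
#' integer-labeled subregion atlas, and the ground-truth voxel-to-subregion
#' table used to score parcellations.
#'
#' @param cfg a [phantom_config()].
#' @return A list with `brain_mask`, `gray_prior` (3D array), `wm_mask`,
#'   `csf_mask`, `atlas` (a [label_volume()]) and `truth` (data.frame with
#'   columns `voxel` (flat index), `label`, `name`, `hemisphere`).
#' @export
build_phantom_atlas <- function(cfg) {
  grid <- cfg$grid
  d <- grid$shape
  sets <- phantom_voxel_sets(cfg)

  # Brain = everything except a 1-voxel outer shell (when the grid allows).
  inside <- array(TRUE, dim = d)
  if (all(d >= 3L)) {
    inside[c(1L, d[1]), , ] <- FALSE
    inside[, c(1L, d[2]), ] <- FALSE
    inside[, , c(1L, d[3])] <- FALSE
  }
  brain <- binary_mask(grid, inside)

  # Tissue compartments: the first interior x-plane is white matter, the last
  # is CSF (unless a planted voxel lands there); the rest is gray matter.
  gray <- array(0, dim = d)
  gray[inside] <- 255
  wm <- array(FALSE, dim = d); csf <- array(FALSE, dim = d)
  if (d[1] >= 6L) {
    wm[2L, , ] <- inside[2L, , ]
    csf[d[1] - 1L, , ] <- inside[d[1] - 1L, , ]
  }
  planted <- c(unlist(lapply(sets, function(s) c(unlist(s$voxels),
                                                 unlist(s$targets)))),
               unlist(lapply(shared_network_sets(cfg), `[[`, "target_idx")))
  wm[planted] <- FALSE; csf[planted] <- FALSE
  gray[wm] <- 40; gray[csf] <- 10

  labels <- array(0L, dim = d)
  truth <- NULL
  for (i in seq_along(sets)) {
    for (hemi in names(sets[[i]]$voxels)) {
      idx <- sets[[i]]$voxels[[hemi]]
      labels[idx] <- i
      truth <- rbind(truth, data.frame(voxel = idx, label = i,
                                       name = sets[[i]]$name,
                                       hemisphere = hemi))
    }
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  atlas <- label_volume(grid, labels, stats::setNames(nm, seq_along(nm)))
  list(brain_mask = brain, gray_prior = gray,
       wm_mask = binary_mask(grid, wm), csf_mask = binary_mask(grid, csf),
       atlas = atlas, truth = truth[order(truth$voxel), ])
}

# Deterministic 32-bit sub-seed for (master seed, stream name / index).
derive_seed <- function(master, salt) {
  if (is.character(salt))
    salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(master) * 100003 + as.numeric(salt) * 7919 + 12345) %%
               2147483647)
}

# Band-limited unit-variance Gaussian process of length T: white noise whose
# Fourier bins outside [lo, hi] Hz are zeroed, then standardized.
band_limited_signal <- function(T, tr, band) {
  x <- stats::rnorm(T)
  f <- (seq_len(T) - 1) / (T * tr)
  f <- pmin(f, 1 / tr - f)
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) keep <- f > 0 & f <= max(f)  # degenerate band: keep all AC
  F <- stats::fft(x)
  F[!keep] <- 0
  y <- Re(stats::fft(F, inverse = TRUE)) / T
  as.numeric(scale(y))
}

#' Simulate a phantom cohort
#'
#' Generates the full multi-subject dataset described by a [phantom_config()]:
#' per subject, each subregion's latent band-limited time course is injected
#' (scaled by `coupling_amplitude`) into that subregion's voxels and its
#' target-region voxels; every brain voxel additionally receives polynomial
#' drift, motion-like nuisance components, shared tissue signals in the
#' white-matter/CSF compartments, a constant baseline, and i.i.d. Gaussian
#' noise. The result is a pure function of the config (bit-identical reruns).
#'
#' @param cfg a [phantom_config()].
#' @return A list of class `phantom_dataset` with elements `cfg`, `anatomy`
#'   (see [build_phantom_atlas()]), `subjects` (list of [bold_series()]),
#'   and `nuisance` (list of data.frames: motion_1..m, wm, csf per subject).
#' @export
simulate_cohort <- function(cfg) {
  anat <- build_phantom_atlas(cfg)
  grid <- cfg$grid
  V <- n_voxels(grid); T <- cfg$n_timepoints
  brain_idx <- mask_indices(anat$brain_mask)
  wm_idx <- mask_indices(anat$wm_mask)
  csf_idx <- mask_indices(anat$csf_mask)
  sets <- phantom_voxel_sets(cfg)
  poly <- poly_basis(T, 2L)[, -1, drop = FALSE]  # drift excludes the constant

  subjects <- vector("list", cfg$n_subjects)
  nuisance <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(derive_seed(cfg$master_seed, s))
    Y <- matrix(0, nrow = T, ncol = V)
    Y[, brain_idx] <- cfg$baseline +
      stats::rnorm(T * length(brain_idx), sd = cfg$noise_sd)

    # planted networks
    for (sub in sets) {
      L <- band_limited_signal(T, cfg$tr_seconds, cfg$latent_band_hz)
      idx <- c(unlist(sub$voxels), unlist(sub$targets))
      Y[, idx] <- Y[, idx] + cfg$coupling_amplitude * L
    }

    # shared networks across member subregions
    sub_names <- vapply(sets, `[[`, character(1), "name")
    for (g in shared_network_sets(cfg)) {
      L <- band_limited_signal(T, cfg$tr_seconds, cfg$latent_band_hz)
      member_idx <- unlist(lapply(sets[match(g$members, sub_names)],
                                  function(s) unlist(s$voxels)))
      idx <- c(member_idx, g$target_idx)
      Y[, idx] <- Y[, idx] + g$amplitude * L
    }

    # polynomial drift, per-voxel coefficients
    if (cfg$drift_coeffs_sd > 0) {
      coef <- matrix(stats::rnorm(ncol(poly) * length(brain_idx),
                                  sd = cfg$drift_coeffs_sd), ncol(poly))
      Y[, brain_idx] <- Y[, brain_idx] + poly %*% coef
    }

    # motion-like regressors: smooth random walks, per-voxel loadings
    m <- cfg$n_motion_regressors
    motion <- NULL
    if (m > 0L) {
      motion <- sapply(seq_len(m), function(i) {
        w <- cumsum(stats::rnorm(T)); as.numeric(scale(w))
      })
      colnames(motion) <- paste0("motion_", seq_len(m))
      if (cfg$motion_gain_sd > 0) {
        gains <- matrix(stats::rnorm(m * length(brain_idx),
                                     sd = cfg$motion_gain_sd), m)
        Y[, brain_idx] <- Y[, brain_idx] + motion %*% gains
      }
    }

    # shared tissue signals in their compartments
    wm_sig <- band_limited_signal(T, cfg$tr_seconds, cfg$latent_band_hz)
    csf_sig <- band_limited_signal(T, cfg$tr_seconds, cfg$latent_band_hz)
    if (length(wm_idx))
      Y[, wm_idx] <- Y[, wm_idx] + cfg$tissue_gain * wm_sig
    if (length(csf_idx))
      Y[, csf_idx] <- Y[, csf_idx] + cfg$tissue_gain * csf_sig

    subjects[[s]] <- bold_series(grid, Y, cfg$tr_seconds)
    tab <- data.frame(row.names = seq_len(T))
    if (!is.null(motion)) tab <- cbind(tab, as.data.frame(motion))
    tab$wm <- cfg$tissue_gain * wm_sig
    tab$csf <- cfg$tissue_gain * csf_sig
    nuisance[[s]] <- tab
  }
  structure(list(cfg = cfg, anatomy = anat, subjects = subjects,
                 nuisance = nuisance),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset: %d subjects, T=%d, grid %s, %d subregions%s>\n",
              length(x$subjects), x$cfg$n_timepoints,
              paste(x$cfg$grid$shape, collapse = "x"),
              length(x$cfg$subregions),
              if (x$cfg$mirror_symmetry) ", mirrored" else ""))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Writes per-subject 4D NIfTI series and nuisance TSVs, the brain mask,
#' gray prior and atlas NIfTIs, the atlas name table and ground-truth labels
#' as JSON.
#'
#' @param dataset a `phantom_dataset` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_phantom <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- dataset$cfg$grid
  paths <- c()
  for (s in seq_along(dataset$subjects)) {
    p1 <- file.path(dir, sprintf("sub-%02d_bold.nii.gz", s))
    write_bold(p1, dataset$subjects[[s]])
    p2 <- file.path(dir, sprintf("sub-%02d_nuisance.tsv", s))
    utils::write.table(dataset$nuisance[[s]], p2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p1, p2)
  }
  an <- dataset$anatomy
  pm <- file.path(dir, "brain_mask.nii.gz")
  write_volume(pm, g, array(as.numeric(an$brain_mask$inside), g$shape))
  pg <- file.path(dir, "gray_prior.nii.gz")
  write_volume(pg, g, an$gray_prior)
  pa <- file.path(dir, "atlas.nii.gz"); pj <- file.path(dir, "atlas_names.json")
  write_atlas(an$atlas, pa, pj)
  pt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(an$truth, pt, dataframe = "columns")
  invisible(c(paths, pm, pg, pa, pj, pt))
}

#' Compact phantom layout helper
#'
#' Places `n_subregions` rectangular subregion blocks and one rectangular
#' target block per subregion on a grid, pairwise disjoint, and returns the
#' `subregions` list for [phantom_config()]. Subregion blocks are stacked
#' along y at small x (one "hemisphere"); target blocks at large x. With
#' `mirror = TRUE` in the eventual config, callers should leave the left half
#' of the grid free; this helper then only uses x-coordinates in the right
#' half when `hemi_width` is given.
#'
#' @param grid_shape 3 integers.
#' @param n_subregions number of planted subregions (default 3, named
#'   "MeA", "CoA", "PAC" for the first three).
#' @param sub_dims dimensions of each subregion block (default `c(5, 4, 3)`,
#'   60 voxels).
#' @param target_dims dimensions of each target block (default `c(4, 4, 4)`,
#'   64 voxels).
#' @param hemi_width restrict placement to x > `grid_shape[1] - hemi_width`
#'   (for mirror-symmetric phantoms); default uses the whole x range.
#' @return List of subregion descriptions.
#' @export
phantom_layout <- function(grid_shape, n_subregions = 3L,
                           sub_dims = c(5L, 4L, 3L),
                           target_dims = c(4L, 4L, 4L),
                           hemi_width = NULL) {
  d <- as.integer(grid_shape)
  x0 <- if (is.null(hemi_width)) 3L else d[1] - as.integer(hemi_width) + 1L
  names_pool <- c("MeA", "CoA", "PAC",
                  paste0("region_", seq_len(max(0L, n_subregions - 3L)) + 3L))
  block <- function(lo, dims) {
    as.matrix(expand.grid(lo[1]:(lo[1] + dims[1] - 1L),
                          lo[2]:(lo[2] + dims[2] - 1L),
                          lo[3]:(lo[3] + dims[3] - 1L)))
  }
  subs <- vector("list", n_subregions)
  for (i in seq_len(n_subregions)) {
    y_sub <- 2L + (i - 1L) * (sub_dims[2] + 1L)
    y_tar <- 2L + (i - 1L) * (target_dims[2] + 1L)
    sub_lo <- c(x0, y_sub, 2L)
    tar_lo <- c(d[1] - target_dims[1] - 1L, y_tar, d[3] - target_dims[3])
    sv <- block(sub_lo, sub_dims)
    tv <- block(tar_lo, target_dims)
    if (any(sv > matrix(d, nrow(sv), 3, byrow = TRUE)) ||
        any(tv > matrix(d, nrow(tv), 3, byrow = TRUE)))
      stop("grid too small for the requested layout", call. = FALSE)
    subs[[i]] <- list(name = names_pool[i], voxels = sv, targets = tv)
  }
  subs
}
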