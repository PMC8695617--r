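# Small phantom fixtures shared across test files. Everything is generated
# in code at test time; sizes are deliberately tiny.

# Default test phantom: 3 subregions of 60 voxels, 3 target blocks, on a
# 20x16x8 grid (gray matter ~1300 voxels).
tiny_phantom_cfg <- function(n_subjects = 3L, n_timepoints = 120L,
                             coupling = sqrt(2 / 3), seed = 1L, ...) {
  phantom_config(c(20L, 16L, 8L), phantom_layout(c(20L, 16L, 8L)),
                 n_subjects = n_subjects, n_timepoints = n_timepoints,
                 tr_seconds = 2, coupling_amplitude = coupling,
                 master_seed = seed, ...)
}

# Group-level connectivity profiles from a phantom dataset: light cleaning
# (detrend + nuisance), no band-pass/smoothing, gray-matter targets.
phantom_group_profiles <- function(ds, seed_names = NULL) {
  an <- ds$anatomy
  gray <- make_gray_matter_mask(ds$cfg$grid, an$gray_prior, 100)
  seed <- combine_roi_masks(an$atlas,
                            seed_names %||% unname(an$atlas$names))
  cleaned <- lapply(seq_along(ds$subjects), function(i)
    preprocess_bold(ds$subjects[[i]], ds$nuisance[[i]], drop_n = 0L,
                    grand_mean = NA, band = NULL, sigma_mm = 0))
  group_average_profiles(lapply(cleaned, voxelwise_profiles,
                                seed_mask = seed, target_mask = gray))
}

# Ground-truth subregion labels aligned to a parcellation's seed voxels.
truth_labels <- function(ds, seed_voxels) {
  ds$anatomy$truth$label[match(seed_voxels, ds$anatomy$truth$voxel)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force 3D morphological erosion (6-neighborhood), the oracle for
# erode_mask: direct per-voxel neighbor scan.
erode_bruteforce <- function(inside) {
  d <- dim(inside)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!inside[i, j, k]) next
    ok <- TRUE
    for (off in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0),
                     c(0,0,-1), c(0,0,1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !inside[p[1], p[2], p[3]]) {
        ok <- FALSE; break
      }
    }
    out[i, j, k] <- ok
  }
  out
}

# Brute-force TFCE oracle: explicit per-threshold connected-component
# labeling (BFS) and summation, independent of the compiled implementation.
tfce_bruteforce <- function(map, mask, E = 0.5, H = 2, dh = NULL,
                            n_steps = 100L, connectivity = 6L) {
  d <- dim(map)
  vals <- ifelse(mask, map, 0)
  vmax <- max(vals)
  out <- array(0, dim = d)
  if (vmax <= 0) return(out)
  if (is.null(dh)) dh <- vmax / n_steps
  offs <- switch(as.character(connectivity),
                 "6" = rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0),
                             c(0,0,-1), c(0,0,1)),
                 stop("oracle supports 6-connectivity"))
  n_thresh <- floor(vmax / dh + 1e-9)
  for (s in seq_len(n_thresh)) {
    h <- s * dh
    supra <- mask & vals >= h
    if (!any(supra)) break
    seen <- array(FALSE, dim = d)
    coords <- which(supra, arr.ind = TRUE)
    for (r in seq_len(nrow(coords))) {
      start <- coords[r, ]
      if (seen[start[1], start[2], start[3]]) next
      # BFS flood fill
      comp <- matrix(start, ncol = 3)
      seen[start[1], start[2], start[3]] <- TRUE
      queue <- list(start)
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (o in seq_len(nrow(offs))) {
          p <- cur + offs[o, ]
          if (any(p < 1) || any(p > d)) next
          if (supra[p[1], p[2], p[3]] && !seen[p[1], p[2], p[3]]) {
            seen[p[1], p[2], p[3]] <- TRUE
            comp <- rbind(comp, p)
            queue <- c(queue, list(p))
          }
        }
      }
      add <- nrow(comp)^E * h^H * dh
      for (m in seq_len(nrow(comp)))
        out[comp[m, 1], comp[m, 2], comp[m, 3]] <-
          out[comp[m, 1], comp[m, 2], comp[m, 3]] + add
    }
  }
  out
}
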