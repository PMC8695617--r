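test_that("phantom atlas has exactly the configured voxels and labels", {
  blocks <- list(
    list(name = "A", voxels = as.matrix(expand.grid(2:3, 2:3, 2:3)),
         targets = cbind(10, 2, 2)),
    list(name = "B", voxels = as.matrix(expand.grid(5:6, 2:3, 2:3)),
         targets = cbind(10, 3, 2)),
    list(name = "C", voxels = as.matrix(expand.grid(8:9, 2:3, 2:3)),
         targets = cbind(10, 4, 2)))
  cfg <- phantom_config(c(12, 6, 5), blocks, n_subjects = 1,
                        n_timepoints = 40, tr_seconds = 2)
  an <- build_phantom_atlas(cfg)
  expect_equal(sum(an$atlas$labels > 0), 24L)
  expect_equal(sort(unique(as.vector(an$atlas$labels))), 0:3)
  expect_equal(nrow(an$truth), 24L)
})

test_that("mirror symmetry reflects voxel sets about the mid-sagittal plane", {
  blocks <- list(list(name = "A", voxels = cbind(3L, 4L, 3L),
                      targets = cbind(6L, 4L, 3L)))
  cfg <- phantom_config(c(16, 8, 6), blocks, n_subjects = 1,
                        n_timepoints = 40, tr_seconds = 2,
                        mirror_symmetry = TRUE)
  an <- build_phantom_atlas(cfg)
  # x = 3 mirrors to x = 16 + 1 - 3 = 14, same subregion label
  expect_equal(an$atlas$labels[3, 4, 3], 1L)
  expect_equal(an$atlas$labels[14, 4, 3], 1L)
  expect_equal(sum(an$atlas$labels > 0), 2L)
  expect_setequal(an$truth$hemisphere, c("left", "right"))
})

test_that("overlapping or out-of-grid voxel sets are configuration errors", {
  shared <- cbind(3L, 3L, 3L)
  blocks <- list(list(name = "A", voxels = shared, targets = cbind(6L, 3L, 3L)),
                 list(name = "B", voxels = shared, targets = cbind(6L, 4L, 3L)))
  expect_error(phantom_config(c(8, 8, 8), blocks, n_timepoints = 40),
               "'A' and 'B' share voxels")
  expect_error(
    phantom_config(c(8, 8, 8),
                   list(list(name = "A", voxels = cbind(9L, 1L, 1L),
                             targets = cbind(2L, 2L, 2L))),
                   n_timepoints = 40),
    "outside grid")
  expect_error(
    phantom_config(c(8, 8, 8),
                   list(list(name = "A", voxels = cbind(3L, 3L, 3L),
                             targets = cbind(3L, 3L, 3L))),
                   n_timepoints = 40),
    "overlaps a subregion")
  expect_error(tiny_phantom_cfg(coupling = -1), "nonnegative")
  expect_error(tiny_phantom_cfg(n_timepoints = 8), "exceed")
})

test_that("simulation is a pure function of the config", {
  cfg <- tiny_phantom_cfg(n_subjects = 2, n_timepoints = 60)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$subjects[[2]]$data, b$subjects[[2]]$data)
  expect_identical(a$nuisance, b$nuisance)
  # different master seed changes the data
  c <- simulate_cohort(tiny_phantom_cfg(n_subjects = 2, n_timepoints = 60,
                                        seed = 99))
  expect_false(identical(a$subjects[[1]]$data, c$subjects[[1]]$data))
})

test_that("null phantom has no seed-target correlation; strong coupling saturates it", {
  # coupling 0: mean r between subregion voxels and their targets ~ 0
  rs <- numeric(0)
  for (s in 1:20) {
    cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 100, coupling = 0,
                            seed = s, drift_coeffs_sd = 0,
                            n_motion_regressors = 0)
    ds <- simulate_cohort(cfg)
    sets <- connparc:::phantom_voxel_sets(cfg)
    sub1 <- sets[[1]]$voxels$right[1:10]
    tar1 <- sets[[1]]$targets$right[1:10]
    rs <- c(rs, as.vector(cor(ds$subjects[[1]]$data[, sub1],
                              ds$subjects[[1]]$data[, tar1])))
  }
  expect_lt(abs(mean(rs)), 3 / sqrt(100))

  # coupling 10x noise: within-subregion correlations > 0.9
  cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 100, coupling = 10,
                          drift_coeffs_sd = 0, n_motion_regressors = 0)
  ds <- simulate_cohort(cfg)
  sub1 <- connparc:::phantom_voxel_sets(cfg)[[1]]$voxels$right
  R <- cor(ds$subjects[[1]]$data[, sub1])
  expect_gt(mean(R[upper.tri(R)]), 0.9)
})

test_that("seed-target correlation increases with coupling and is nil across networks", {
  mean_r <- vapply(c(0.3, 0.8, 2), function(a) {
    cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 200, coupling = a,
                            drift_coeffs_sd = 0, n_motion_regressors = 0)
    ds <- simulate_cohort(cfg)
    sets <- connparc:::phantom_voxel_sets(cfg)
    mean(cor(ds$subjects[[1]]$data[, sets[[1]]$voxels$right],
             ds$subjects[[1]]$data[, sets[[1]]$targets$right]))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))

  cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 200)
  ds <- simulate_cohort(cfg)
  sets <- connparc:::phantom_voxel_sets(cfg)
  cross <- cor(ds$subjects[[1]]$data[, sets[[1]]$voxels$right],
               ds$subjects[[1]]$data[, sets[[2]]$targets$right])
  expect_lt(abs(mean(cross)), 3 / sqrt(200))
})

test_that("default coupling yields within-network r near 0.4", {
  cfg <- tiny_phantom_cfg(n_subjects = 2, n_timepoints = 300,
                          drift_coeffs_sd = 0, n_motion_regressors = 0)
  ds <- simulate_cohort(cfg)
  sets <- connparc:::phantom_voxel_sets(cfg)
  r <- mean(cor(ds$subjects[[1]]$data[, sets[[1]]$voxels$right],
                ds$subjects[[1]]$data[, sets[[1]]$targets$right]))
  expect_gt(r, 0.3); expect_lt(r, 0.5)
})

test_that("shared networks raise correlations among member subregions' profiles", {
  grid_shape <- c(24L, 22L, 9L)
  subs <- phantom_layout(grid_shape, n_subregions = 4L)
  subs[[4]]$name <- "BLA"
  shared <- list(list(members = c("MeA", "CoA", "PAC"),
                      targets = as.matrix(expand.grid(10:13, 2:5, 5:8)),
                      amplitude = 0.8))
  cfg <- phantom_config(grid_shape, subs, shared_networks = shared,
                        n_subjects = 1, n_timepoints = 200, tr_seconds = 2,
                        drift_coeffs_sd = 0, n_motion_regressors = 0)
  ds <- simulate_cohort(cfg)
  sets <- connparc:::phantom_voxel_sets(cfg)
  shared_tar <- connparc:::shared_network_sets(cfg)[[1]]$target_idx
  Y <- ds$subjects[[1]]$data
  r_olf <- mean(cor(Y[, sets[[1]]$voxels$right], Y[, shared_tar]))
  r_bla <- mean(cor(Y[, sets[[4]]$voxels$right], Y[, shared_tar]))
  expect_gt(r_olf, 0.2)
  expect_lt(abs(r_bla), 0.1)
})

test_that("phantom datasets write to disk with all expected artifacts", {
  cfg <- tiny_phantom_cfg(n_subjects = 2, n_timepoints = 40)
  ds <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_phantom(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "sub-01_bold.nii.gz", "sub-01_nuisance.tsv", "sub-02_bold.nii.gz",
    "brain_mask.nii.gz", "gray_prior.nii.gz", "atlas.nii.gz",
    "atlas_names.json", "ground_truth.json")))))
  nuis <- read.delim(file.path(dir, "sub-01_nuisance.tsv"))
  expect_equal(nrow(nuis), 40L)
  expect_true(all(c("motion_1", "wm", "csf") %in% names(nuis)))
  back <- read_bold(file.path(dir, "sub-02_bold.nii.gz"))
  expect_equal(back$data, ds$subjects[[2]]$data, tolerance = 1e-5)
})
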