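profiles_from_matrix <- function(X) {
  # z scale: unbounded feature values are fine for clustering tests
  connectivity_profiles(seq_len(nrow(X)), nrow(X) + seq_len(ncol(X)),
                        X, scale = "z")
}

test_that("k-means with correlation distance separates exact profile groups", {
  A <- c(0.9, 0.1, -0.5); B <- c(-0.3, 0.8, 0.2)
  X <- rbind(A, A, A, B, B, B); rownames(X) <- NULL
  res <- kmeans_parcellate(profiles_from_matrix(X), k = 2, n_replicates = 5,
                           seed = 3)
  expect_equal(res$objective, 0, tolerance = 1e-12)
  expect_equal(res$cluster[1:3], rep(res$cluster[1], 3))
  expect_equal(res$cluster[4:6], rep(res$cluster[4], 3))
  expect_false(res$cluster[1] == res$cluster[4])
  expect_false(res$degenerate)
})

test_that("k = 1 yields a single cluster; invalid inputs error", {
  X <- matrix(rnorm(40), 8, 5)
  res <- kmeans_parcellate(profiles_from_matrix(X), k = 1, seed = 1,
                           n_replicates = 2)
  expect_equal(res$cluster, rep(1L, 8))
  expect_error(kmeans_parcellate(profiles_from_matrix(X), k = 9, seed = 1),
               "exceeds")
  Xc <- X; Xc[3, ] <- 2
  expect_error(kmeans_parcellate(profiles_from_matrix(Xc), k = 2, seed = 1),
               "constant profile.*3")
})

test_that("parcellation is deterministic and invariant to voxel order", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 1), 6, 10) + rep(sin(1:10), each = 6),
             matrix(rnorm(60), 6, 10) + rep(cos(1:10), each = 6))
  prof <- profiles_from_matrix(X)
  r1 <- kmeans_parcellate(prof, 2, n_replicates = 8, seed = 42)
  r2 <- kmeans_parcellate(prof, 2, n_replicates = 8, seed = 42)
  expect_identical(r1$cluster, r2$cluster)
  expect_identical(r1$objective, r2$objective)
  # permuted voxel order: same partition up to relabeling
  perm <- sample(nrow(X))
  Xp <- X[perm, ]
  rp <- kmeans_parcellate(profiles_from_matrix(Xp), 2, n_replicates = 8,
                          seed = 42)
  expect_equal(adjusted_rand_index(rp$cluster, r1$cluster[perm]), 1)
})

test_that("objective never increases with more replicates", {
  set.seed(6)
  X <- matrix(rnorm(300), 30, 10)
  prof <- profiles_from_matrix(X)
  o1 <- kmeans_parcellate(prof, 3, n_replicates = 1, seed = 7)$objective
  o10 <- kmeans_parcellate(prof, 3, n_replicates = 10, seed = 7)$objective
  expect_lte(o10, o1 + 1e-12)
})

test_that("high-SNR phantom parcellation recovers planted subregions exactly", {
  cfg <- tiny_phantom_cfg(n_subjects = 2, n_timepoints = 150, coupling = 3)
  ds <- simulate_cohort(cfg)
  prof <- phantom_group_profiles(ds)
  res <- kmeans_parcellate(prof, 3, n_replicates = 5, seed = 1)
  expect_equal(adjusted_rand_index(res$cluster,
                                   truth_labels(ds, res$seed_voxels)), 1)
})

test_that("k above the planted count splits clusters rather than mixing them", {
  cfg <- tiny_phantom_cfg(n_subjects = 2, n_timepoints = 150, coupling = 3)
  ds <- simulate_cohort(cfg)
  prof <- phantom_group_profiles(ds)
  res <- kmeans_parcellate(prof, 5, n_replicates = 5, seed = 2)
  truth <- truth_labels(ds, res$seed_voxels)
  # each resulting cluster lies inside a single planted subregion
  for (c in unique(res$cluster)) {
    expect_equal(length(unique(truth[res$cluster == c])), 1L)
  }
})

test_that("cluster-ROI matching maximizes overlap with deterministic ties", {
  grid <- volume_grid(c(6, 1, 1))
  labs <- array(c(1L, 1L, 2L, 2L, 3L, 3L), c(6, 1, 1))
  atlas <- label_volume(grid, labs, c("1" = "MeA", "2" = "CoA", "3" = "PAC"))
  res <- structure(list(seed_voxels = 1:6, cluster = c(3L, 3L, 1L, 1L, 2L, 2L),
                        k = 3L), class = "parcellation_result")
  map <- match_clusters(res, atlas)
  expect_equal(unname(map), c(2L, 3L, 1L))  # recovers the permutation
  expect_equal(names(map), c("CoA", "PAC", "MeA"))

  # overlap [[6,4],[4,6]] -> identity beats the swap (12 > 8), via the
  # exhaustive-search oracle
  labs2 <- array(rep(c(1L, 2L), c(10, 10)), c(20, 1, 1))
  atlas2 <- label_volume(volume_grid(c(20, 1, 1)), labs2,
                         c("1" = "A", "2" = "B"))
  cl <- c(rep(1L, 6), rep(2L, 4), rep(1L, 4), rep(2L, 6))
  res2 <- structure(list(seed_voxels = 1:20, cluster = cl, k = 2L),
                    class = "parcellation_result")
  O <- table(cl, labs2[1:20])
  best <- if (O[1, 1] + O[2, 2] >= O[1, 2] + O[2, 1]) c(1L, 2L) else c(2L, 1L)
  expect_equal(unname(match_clusters(res2, atlas2)), best)
  expect_equal(unname(match_clusters(res2, atlas2)), c(1L, 2L))
})

test_that("adjusted Rand index matches the mclust oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  skip_if_not_installed("mclust")
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("independent random partitions have near-zero ARI", {
  set.seed(10)
  a <- sample(1:4, 1000, replace = TRUE)
  b <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.02)
})

test_that("parcellation results persist as TSV + JSON + NIfTI", {
  cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 80)
  ds <- simulate_cohort(cfg)
  res <- kmeans_parcellate(phantom_group_profiles(ds), 3, n_replicates = 3,
                           seed = 4)
  pt <- withr::local_tempfile(fileext = ".tsv")
  pj <- withr::local_tempfile(fileext = ".json")
  pn <- withr::local_tempfile(fileext = ".nii.gz")
  write_parcellation(res, pt, pj, pn)
  tab <- read.delim(pt)
  expect_equal(nrow(tab), length(res$seed_voxels))
  expect_equal(tab$cluster, res$cluster)
  vol <- read_volume(pn)
  expect_equal(vol$values[res$seed_voxels], as.numeric(res$cluster))
  diag <- jsonlite::read_json(pj)
  expect_equal(diag$k, 3L)
})
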