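#' Default study-like pipeline configuration
#'
#' Builds a complete nested configuration for [run_pipeline()]: a phantom
#' with three "olfactory" subregions (MeA, CoA, PAC) plus one non-olfactory
#' subregion (BLA), a shared network linking the three olfactory ones (so a
#' k = 2 parcellation can separate olfactory from non-olfactory, and k = 3
#' on the olfactory mask can separate the three), and analysis defaults that
#' follow the conventional resting-state pipeline (drop 10 volumes, order-2
#' detrend, nuisance regression, grand-mean 10000, band-pass 0.008-0.01 Hz,
#' 3 mm smoothing; k in {2, 3}; 10,000 permutations; Bonferroni and
#' TFCE-FWE alpha 0.05). Every value can be overridden via `...` or by
#' editing the returned list.
#'
#' @param output_dir output directory for [run_pipeline()].
#' @param master_seed master RNG seed.
#' @param n_subjects,n_timepoints cohort size and series length (defaults are
#'   deliberately desk-scale; pass study-scale values for a full emulation).
#' @param ... overrides for top-level phantom fields
#'   (e.g. `coupling_amplitude`, `mirror_symmetry`).
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(output_dir = tempfile("connparc_run_"),
                                    master_seed = 1L,
                                    n_subjects = 8L, n_timepoints = 220L,
                                    ...) {
  grid_shape <- c(24L, 22L, 9L)
  subs <- phantom_layout(grid_shape, n_subregions = 4L)
  subs[[4]]$name <- "BLA"
  shared <- list(list(members = c("MeA", "CoA", "PAC"),
                      targets = as.matrix(expand.grid(10:13, 2:5, 5:8)),
                      amplitude = 0.6))
  list(
    output_dir = output_dir,
    master_seed = as.integer(master_seed),
    phantom = list(grid_shape = grid_shape, subregions = subs,
                   shared_networks = shared,
                   n_subjects = as.integer(n_subjects),
                   n_timepoints = as.integer(n_timepoints),
                   tr_seconds = 2.0, ...),
    olfactory = c("MeA", "CoA", "PAC"),
    preprocess = list(drop_n = 10L, detrend_order = 2L, grand_mean = 10000,
                      band = NULL, sigma_mm = 0),
    gray_threshold = 100,
    analysis = list(k_values = c(2L, 3L), n_replicates = 10L,
                    n_perms = 10000L, alpha = 0.05,
                    fwe_n_perms = 200L,
                    tfce = list(E = 0.5, H = 2, n_steps = 100L,
                                connectivity = 6L))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Subregion / target voxel tables may be given in YAML as lists of
#' `[x, y, z]` rows; they are coerced to integer matrices.
#'
#' @param path YAML file.
#' @return Configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fix_mat <- function(m) matrix(as.integer(unlist(m)), ncol = 3L, byrow = TRUE)
  if (!is.null(cfg$phantom$subregions))
    cfg$phantom$subregions <- lapply(cfg$phantom$subregions, function(s) {
      s$voxels <- fix_mat(s$voxels); s$targets <- fix_mat(s$targets); s
    })
  if (!is.null(cfg$phantom$shared_networks))
    cfg$phantom$shared_networks <- lapply(cfg$phantom$shared_networks,
                                          function(g) {
                                            g$targets <- fix_mat(g$targets); g
                                          })
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates phantom simulation, per-subject preprocessing, voxelwise
#' connectivity profiles with Fisher-z group averaging, correlation-distance
#' k-means parcellation for each requested k, the k = 2 olfactory-separation
#' permutation test, the k = 3 cluster-by-ROI proportion permutation test,
#' per-subregion seed connectivity maps with sign-flip max-TFCE FWE
#' correction, the 8-way network category map and Venn voxel counts. Every
#' intermediate is written under `config$output_dir` and hashed into
#' `manifest.json`; identical configurations give identical manifests.
#'
#' @param config nested configuration list (see
#'   [default_pipeline_config()]), or a path to a YAML file.
#' @return The manifest, invisibly: list with `files` (named md5 hashes) and
#'   `summary` (headline numbers of each stage).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is required", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list()

  ## stage 1: phantom -------------------------------------------------------
  pcfg <- do.call(phantom_config, c(config$phantom,
                                    list(master_seed = config$master_seed)))
  dataset <- simulate_cohort(pcfg)
  write_phantom(dataset, file.path(out, "phantom"))
  anat <- dataset$anatomy
  grid <- pcfg$grid

  ## stage 2: preprocessing -------------------------------------------------
  pp <- config$preprocess
  drop_n <- pp$drop_n %||% 10L
  gray <- make_gray_matter_mask(grid, anat$gray_prior,
                                config$gray_threshold %||% 100)
  dir.create(file.path(out, "clean"), showWarnings = FALSE)
  clean <- vector("list", length(dataset$subjects))
  for (s in seq_along(dataset$subjects)) {
    nuis <- dataset$nuisance[[s]]
    if (drop_n > 0L) nuis <- nuis[-seq_len(drop_n), , drop = FALSE]
    clean[[s]] <- preprocess_bold(dataset$subjects[[s]], nuisance = nuis,
                                  drop_n = drop_n,
                                  detrend_order = pp$detrend_order %||% 2L,
                                  grand_mean = pp$grand_mean %||% 10000,
                                  band = pp$band, sigma_mm = pp$sigma_mm %||% 0,
                                  mask = anat$brain_mask)
    write_bold(file.path(out, "clean", sprintf("sub-%02d_clean.nii.gz", s)),
               clean[[s]])
  }

  ## stage 3: connectivity profiles ----------------------------------------
  atlas <- anat$atlas
  seed_mask <- combine_roi_masks(atlas, unname(atlas$names))
  profiles <- lapply(clean, voxelwise_profiles,
                     seed_mask = seed_mask, target_mask = gray)
  group <- group_average_profiles(profiles)
  dir.create(file.path(out, "profiles"), showWarnings = FALSE)
  write_profiles(group, file.path(out, "profiles", "group_profiles.tsv"),
                 file.path(out, "profiles", "group_profiles.json"))

  ## stage 4: parcellation + permutation tests ------------------------------
  an <- config$analysis
  dir.create(file.path(out, "parcellation"), showWarnings = FALSE)
  dir.create(file.path(out, "permtests"), showWarnings = FALSE)
  olf_names <- config$olfactory %||% unname(atlas$names)
  olf_mask <- combine_roi_masks(atlas, olf_names)
  for (k in (an$k_values %||% c(2L, 3L))) {
    if (k == 3L && !setequal(olf_names, unname(atlas$names))) {
      # the k = 3 analysis runs on the olfactory subregions only
      prof_k <- lapply(clean, voxelwise_profiles,
                       seed_mask = olf_mask, target_mask = gray)
      prof_k <- group_average_profiles(prof_k)
    } else prof_k <- group
    parc <- kmeans_parcellate(prof_k, k = k,
                              n_replicates = an$n_replicates %||% 50L,
                              seed = derive_seed(config$master_seed,
                                                 paste0("kmeans", k)))
    write_parcellation(parc,
                       file.path(out, "parcellation", sprintf("k%d.tsv", k)),
                       file.path(out, "parcellation", sprintf("k%d.json", k)),
                       file.path(out, "parcellation", sprintf("k%d.nii.gz", k)))
    if (k == 2L) {
      sep <- olfactory_separation_test(parc, olf_mask,
                                       n_perms = an$n_perms %||% 10000L,
                                       seed = derive_seed(config$master_seed,
                                                          "septest"))
      jsonlite::write_json(sep[c("observed", "null_mean", "null_sd", "z", "p",
                                 "n_perms", "tail", "rng_seed")],
                           file.path(out, "permtests", "separation_k2.json"),
                           auto_unbox = TRUE, digits = NA)
      summary$separation_z <- sep$z
      summary$separation_p <- sep$p
    }
    if (k == 3L) {
      prop <- proportion_permutation_test(parc, atlas,
                                          n_perms = an$n_perms %||% 10000L,
                                          seed = derive_seed(config$master_seed,
                                                             "proptest"),
                                          alpha = an$alpha %||% 0.05)
      utils::write.table(prop$proportions,
                         file.path(out, "permtests", "proportion_k3.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(z = prop$z_matrix, p = prop$p_matrix,
                                significant = prop$significant,
                                n_perms = prop$n_perms, alpha = prop$alpha,
                                correction = prop$correction),
                           file.path(out, "permtests", "proportion_k3.json"),
                           digits = NA)
      map <- match_clusters(parc, atlas)
      summary$k3_matched_rois <- names(map)
      summary$k3_min_matched_z <- min(prop$z_matrix[cbind(
        seq_len(parc$k), match(names(map), colnames(prop$proportions)))])
    }
  }

  ## stage 5: network maps --------------------------------------------------
  dir.create(file.path(out, "netmaps"), showWarnings = FALSE)
  tf <- an$tfce %||% list()
  analysis_mask <- binary_mask(grid, gray$inside & !seed_mask$inside)
  binaries <- list()
  for (nm in olf_names[1:min(3L, length(olf_names))]) {
    roi <- combine_roi_masks(atlas, nm)
    zmaps <- lapply(clean, roi_seed_map, roi = roi, brain = gray)
    fwe <- signflip_fwe(zmaps, analysis_mask,
                        n_perms = an$fwe_n_perms %||% 1000L,
                        alpha = an$alpha %||% 0.05,
                        E = tf$E %||% 0.5, H = tf$H %||% 2,
                        n_steps = tf$n_steps %||% 100L,
                        connectivity = tf$connectivity %||% 6L,
                        seed = derive_seed(config$master_seed,
                                           paste0("fwe_", nm)))
    write_volume(file.path(out, "netmaps", sprintf("%s_tstat.nii.gz", nm)),
                 grid, fwe$stat)
    write_volume(file.path(out, "netmaps", sprintf("%s_binary.nii.gz", nm)),
                 grid, array(as.numeric(fwe$binary), grid$shape))
    binaries[[nm]] <- fwe$binary
    summary[[paste0("fwe_nsig_", nm)]] <- sum(fwe$binary)
  }
  if (length(binaries) == 3L) {
    catmap <- assign_categories(binaries[[1]], binaries[[2]], binaries[[3]],
                                grid = grid)
    write_volume(file.path(out, "netmaps", "categories.nii.gz"), grid,
                 array(as.numeric(catmap$category), grid$shape))
    jsonlite::write_json(as.list(network_categories()),
                         file.path(out, "netmaps", "category_codes.json"),
                         auto_unbox = TRUE)
    vc <- venn_counts(catmap)
    utils::write.table(data.frame(category = names(vc), voxels = vc),
                       file.path(out, "netmaps", "venn_counts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$venn <- as.list(vc)
  }

  ## manifest ---------------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  hashes <- tools::md5sum(files)
  names(hashes) <- sub(paste0("^", out, "/?"), "", names(hashes))
  manifest <- list(files = as.list(hashes), summary = summary)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
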