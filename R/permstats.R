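#' Normal-fit z score from a permutation null
#'
#' Summarizes a permutation null by a normal fit: the z score of the observed
#' statistic is `(observed - mean(null)) / sd(null)` with the usual n-1
#' standard deviation.
#'
#' @param observed observed statistic.
#' @param null_samples numeric vector of permuted statistics (length >= 2).
#' @return List with `z`, `null_mean`, `null_sd`.
#' @export
z_from_null <- function(observed, null_samples) {
  if (length(null_samples) < 2L)
    stop("need at least 2 null samples", call. = FALSE)
  m <- mean(null_samples)
  s <- stats::sd(null_samples)
  if (s == 0) stop("degenerate null: all permuted values equal", call. = FALSE)
  list(z = (observed - m) / s, null_mean = m, null_sd = s)
}

#' Normal-theory p value from a z score
#'
#' @param z z score.
#' @param tail `"two_sided"` (default), `"greater"` or `"less"`.
#' @return p value in `[0, 1]`.
#' @export
p_from_z <- function(z, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (!is.finite(z)) stop("`z` must be finite", call. = FALSE)
  switch(tail,
         two_sided = 2 * stats::pnorm(-abs(z)),
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z))
}

new_permutation_result <- function(observed, null_samples, tail, n_perms,
                                   rng_seed, draws = NULL) {
  fit <- z_from_null(observed, null_samples)
  structure(list(observed = observed, null_mean = fit$null_mean,
                 null_sd = fit$null_sd, z = fit$z,
                 p = p_from_z(fit$z, tail), n_perms = as.integer(n_perms),
                 tail = tail, rng_seed = as.integer(rng_seed),
                 null_draws = draws),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: observed=%.4g, null %.4g +/- %.4g, z=%.3f, p=%.3g (%s, %d perms)>\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$p, x$tail, x$n_perms))
  invisible(x)
}

#' Olfactory-separation permutation test (k = 2)
#'
#' Tests how strongly a two-cluster parcellation separates a designated set
#' of "olfactory" seed voxels from the rest. The statistic is the difference
#' in the percentage of olfactory voxels between the two clusters, with
#' clusters ordered so the observed olfactory-richer cluster comes first.
#' Each permutation shuffles the olfactory/non-olfactory voxel labels
#' uniformly at random (cluster assignment fixed, olfactory count preserved)
#' and recomputes the difference in the same fixed cluster order; z and
#' two-sided p come from a normal fit to the permuted differences.
#'
#' @param result a [kmeans_parcellate()] result with `k = 2`.
#' @param olf logical vector per seed voxel (TRUE = olfactory), or a
#'   [binary_mask()] evaluated at the result's seed voxels.
#' @param n_perms number of permutations (default 10000).
#' @param seed RNG seed.
#' @param keep_draws store the permuted differences in the result.
#' @return A `permutation_result`.
#' @export
olfactory_separation_test <- function(result, olf, n_perms = 10000L,
                                      seed = 1L, keep_draws = TRUE) {
  if (result$k != 2L) stop("separation test requires k = 2", call. = FALSE)
  if (inherits(olf, "binary_mask")) olf <- olf$inside[result$seed_voxels]
  olf <- as.logical(olf)
  n <- length(result$cluster)
  if (length(olf) != n)
    stop("`olf` length does not match seed voxels", call. = FALSE)
  n_olf <- sum(olf)
  if (n_olf == 0L || n_olf == n)
    stop("olfactory set must be a nonempty proper subset of seed voxels",
         call. = FALSE)

  cl <- result$cluster
  pct <- function(o) 100 * c(sum(o & cl == 1L) / sum(cl == 1L),
                             sum(o & cl == 2L) / sum(cl == 2L))
  obs_pct <- pct(olf)
  ord <- order(-obs_pct)              # observed olfactory-richer cluster first
  observed <- obs_pct[ord[1]] - obs_pct[ord[2]]

  set.seed(derive_seed(seed, "separation"))
  draws <- vapply(seq_len(n_perms), function(i) {
    o <- olf[sample.int(n)]
    p <- pct(o)
    p[ord[1]] - p[ord[2]]             # same fixed cluster order
  }, numeric(1))
  new_permutation_result(observed, draws, "two_sided", n_perms, seed,
                         draws = if (keep_draws) draws)
}

#' Cluster-by-ROI proportion matrix
#'
#' `P[c, r]` = fraction of cluster `c`'s voxels that lie inside atlas ROI
#' `r`. Rows sum to 1 when the ROIs tile the seed mask.
#'
#' @param result a [kmeans_parcellate()] result.
#' @param atlas a [label_volume()]; every seed voxel must carry a nonzero
#'   label.
#' @return k x R matrix with ROI names as column names.
#' @export
proportion_matrix <- function(result, atlas) {
  labs <- atlas$labels[result$seed_voxels]
  if (any(labs == 0L))
    stop("unlabeled seed voxel(s) at flat index: ",
         paste(utils::head(result$seed_voxels[labs == 0L], 10L),
               collapse = ", "), call. = FALSE)
  sizes <- tabulate(result$cluster, nbins = result$k)
  if (any(sizes == 0L))
    stop("empty cluster(s): ", paste(which(sizes == 0L), collapse = ", "),
         call. = FALSE)
  roi_ids <- sort(unique(labs))
  P <- matrix(0, result$k, length(roi_ids),
              dimnames = list(NULL, atlas$names[as.character(roi_ids)]))
  for (c in seq_len(result$k))
    P[c, ] <- tabulate(match(labs[result$cluster == c], roi_ids),
                       nbins = length(roi_ids)) / sizes[c]
  P
}

#' Proportion permutation test (parcellation accuracy)
#'
#' For each (cluster, ROI) cell of the proportion matrix, builds a
#' permutation null by shuffling the anatomical ROI labels across seed voxels
#' (label multiset preserved, cluster assignment fixed), fits a normal to the
#' permuted proportions, and reports per-cell z and two-sided p with
#' multiple-testing correction over all k x R cells.
#'
#' @param result a [kmeans_parcellate()] result.
#' @param atlas a [label_volume()] labeling every seed voxel.
#' @param n_perms permutations (default 10000).
#' @param seed RNG seed.
#' @param alpha significance level after correction (default 0.05).
#' @param correction `"bonferroni"` (default) or any method of
#'   [stats::p.adjust()].
#' @return An object of class `proportion_test_result`: list with
#'   `proportions`, `z_matrix`, `p_matrix`, `p_corrected`, `significant`,
#'   `alpha`, `correction`, `n_perms`, `rng_seed`.
#' @export
proportion_permutation_test <- function(result, atlas, n_perms = 10000L,
                                        seed = 1L, alpha = 0.05,
                                        correction = "bonferroni") {
  obs <- proportion_matrix(result, atlas)
  labs <- atlas$labels[result$seed_voxels]
  roi_ids <- sort(unique(labs))
  k <- result$k; R <- length(roi_ids)
  n <- length(labs)
  sizes <- tabulate(result$cluster, nbins = k)

  set.seed(derive_seed(seed, "proportion"))
  sum1 <- matrix(0, k, R); sum2 <- matrix(0, k, R)
  for (i in seq_len(n_perms)) {
    perm <- labs[sample.int(n)]
    P <- matrix(0, k, R)
    for (c in seq_len(k))
      P[c, ] <- tabulate(match(perm[result$cluster == c], roi_ids),
                         nbins = R) / sizes[c]
    sum1 <- sum1 + P
    sum2 <- sum2 + P^2
  }
  null_mean <- sum1 / n_perms
  null_sd <- sqrt(pmax(0, (sum2 - n_perms * null_mean^2) / (n_perms - 1)))
  if (any(null_sd == 0))
    stop("degenerate permutation null in at least one cell", call. = FALSE)
  zmat <- (obs - null_mean) / null_sd
  pmat <- 2 * stats::pnorm(-abs(zmat))
  pcor <- matrix(stats::p.adjust(pmat, method = correction), k, R,
                 dimnames = dimnames(obs))
  structure(list(proportions = obs, z_matrix = zmat, p_matrix = pmat,
                 p_corrected = pcor, significant = pcor < alpha,
                 alpha = alpha, correction = correction,
                 null_mean = null_mean, null_sd = null_sd,
                 n_perms = as.integer(n_perms), rng_seed = as.integer(seed)),
            class = "proportion_test_result")
}

#' @export
print.proportion_test_result <- function(x, ...) {
  cat(sprintf("<proportion_test_result %dx%d, %d perms, %s alpha=%g>\n",
              nrow(x$proportions), ncol(x$proportions), x$n_perms,
              x$correction, x$alpha))
  print(round(x$proportions, 3))
  cat("z:\n"); print(round(x$z_matrix, 2))
  invisible(x)
}
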