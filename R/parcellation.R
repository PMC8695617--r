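#' Correlation-distance k-means parcellation
#'
#' Clusters seed voxels by their whole-brain connectivity profiles using
#' Lloyd's algorithm with the correlation distance
#' `d(x, c) = 1 - cor(x, c)` (Pearson correlation between a voxel's profile
#' and a centroid profile, both centered). Centroids are arithmetic means of
#' member profiles. Each of `n_replicates` runs starts from a k-means++-style
#' initialization drawn from its own sub-seed; the run with the lowest
#' objective (sum of correlation distances of voxels to their assigned
#' centroid) is returned. The result is deterministic given
#' `(profiles, k, n_replicates, seed)`.
#'
#' @param profiles a [connectivity_profiles()] (group level, scale `"r"`).
#' @param k number of clusters.
#' @param n_replicates independent restarts (default 50).
#' @param seed integer RNG seed.
#' @param max_iter Lloyd iteration cap per replicate.
#' @return An object of class `parcellation_result`: list with `seed_voxels`,
#'   `cluster` (integer 1..k per seed voxel), `k`, `objective`,
#'   `n_replicates`, `seed`, `iterations`, `degenerate` (TRUE if any final
#'   cluster is empty), and `grid`.
#' @export
kmeans_parcellate <- function(profiles, k, n_replicates = 50L, seed = 1L,
                              max_iter = 100L) {
  X <- profiles$values
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds %d seed voxels", k, n), call. = FALSE)
  if (any(!is.finite(X))) stop("profiles contain non-finite values", call. = FALSE)
  row_sd <- apply(X, 1L, stats::sd)
  if (any(row_sd == 0))
    stop("constant profile at seed voxel(s): ",
         paste(utils::head(profiles$seed_voxels[row_sd == 0], 10L),
               collapse = ", "), call. = FALSE)

  # center + unit-norm rows once: cor(x, c) = Xn %*% cn
  Xn <- X - rowMeans(X)
  Xn <- Xn / sqrt(rowSums(Xn^2))

  normalize <- function(C) {  # rows of C -> centered unit vectors
    C <- C - rowMeans(C)
    nrm <- sqrt(rowSums(C^2))
    nrm[nrm == 0] <- 1
    C / nrm
  }

  best <- NULL
  for (rep_i in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, rep_i * 2L + 1L))
    # k-means++ style seeding on correlation distance
    centers <- integer(k)
    centers[1] <- sample.int(n, 1L)
    if (k > 1L) {
      d2 <- 1 - as.numeric(Xn %*% Xn[centers[1], ])
      d2 <- pmax(d2, 0)
      for (j in 2:k) {
        if (sum(d2) <= 0) centers[j] <- sample.int(n, 1L)
        else centers[j] <- sample.int(n, 1L, prob = d2)
        d2 <- pmin(d2, pmax(1 - as.numeric(Xn %*% Xn[centers[j], ]), 0))
      }
    }
    C <- X[centers, , drop = FALSE]
    assign_old <- rep(0L, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      S <- Xn %*% t(normalize(C))          # n x k correlations
      assign_new <- max.col(S, ties.method = "first")
      # repair empty clusters: reseed at the point farthest from its centroid
      repeat {
        sizes <- tabulate(assign_new, nbins = k)
        empties <- which(sizes == 0L)
        if (!length(empties)) break
        dmin <- 1 - S[cbind(seq_len(n), assign_new)]
        far <- which.max(dmin)
        assign_new[far] <- empties[1]
        S[far, ] <- -Inf; S[far, empties[1]] <- Inf  # pin it this iteration
      }
      for (j in seq_len(k))
        C[j, ] <- colMeans(X[assign_new == j, , drop = FALSE])
      if (identical(assign_new, assign_old) || iter >= max_iter) break
      assign_old <- assign_new
    }
    S <- Xn %*% t(normalize(C))
    obj <- sum(1 - S[cbind(seq_len(n), assign_new)])
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(cluster = assign_new, objective = obj, iterations = iter)
    }
  }

  # canonical labels: clusters renumbered by first occurrence in voxel order
  relab <- match(best$cluster, unique(best$cluster))
  structure(list(seed_voxels = profiles$seed_voxels,
                 cluster = relab, k = k, objective = best$objective,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), iterations = best$iterations,
                 degenerate = length(unique(relab)) < k,
                 grid = profiles$grid),
            class = "parcellation_result")
}

#' @export
print.parcellation_result <- function(x, ...) {
  cat(sprintf("<parcellation_result k=%d, %d voxels, objective=%.4f (%d replicates)>\n",
              x$k, length(x$cluster), x$objective, x$n_replicates))
  invisible(x)
}

# All permutations of 1..n in lexicographic order (n <= 8 guarded by caller).
perms_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_lex(n - 1L)
  out <- matrix(0L, 0L, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Match parcellation clusters to atlas ROIs
#'
#' Finds the one-to-one assignment of clusters to atlas labels that maximizes
#' the total voxel overlap (the overlap matrix is padded square with zeros if
#' cluster and ROI counts differ), by exhaustive search over assignments
#' (exact; sizes here are small). Ties break to the lexicographically first
#' assignment: lowest cluster index first, lowest ROI label first.
#'
#' @param result a [kmeans_parcellate()] result.
#' @param atlas a [label_volume()] labeling (at least) the seed voxels.
#' @return Named integer vector: for each cluster 1..k, the matched ROI label
#'   (0 for padded, unmatched clusters), with ROI names as names.
#' @export
match_clusters <- function(result, atlas) {
  labs <- atlas$labels[result$seed_voxels]
  roi_ids <- sort(unique(labs[labs > 0L]))
  k <- result$k
  m <- max(k, length(roi_ids))
  if (m > 8L) stop("exhaustive matching supports at most 8 clusters/ROIs",
                   call. = FALSE)
  O <- matrix(0, m, m)
  for (c in seq_len(k)) for (r in seq_along(roi_ids))
    O[c, r] <- sum(result$cluster == c & labs == roi_ids[r])
  if (all(O == 0))
    warning("clusters and atlas ROIs have no overlapping voxels", call. = FALSE)
  P <- perms_lex(m)
  tot <- vapply(seq_len(nrow(P)), function(i)
    sum(O[cbind(seq_len(m), P[i, ])]), numeric(1))
  bestp <- P[which.max(tot), ]              # first max = lexicographic tie-break
  out <- integer(k)
  nm <- character(k)
  for (c in seq_len(k)) {
    j <- bestp[c]
    if (j <= length(roi_ids)) {
      out[c] <- roi_ids[j]
      nm[c] <- atlas$names[as.character(roi_ids[j])]
    } else {
      out[c] <- 0L; nm[c] <- NA_character_
    }
  }
  stats::setNames(out, nm)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones.
#'
#' @param labels_a,labels_b vectors of cluster labels, equal length >= 2.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Write a parcellation result
#'
#' Writes a TSV (flat voxel index, x, y, z, cluster), a JSON diagnostics
#' sidecar, and (when the grid is known) a cluster-label NIfTI.
#'
#' @param result a [kmeans_parcellate()] result.
#' @param path_tsv,path_json,path_nii output paths (`path_nii` optional).
#' @return `path_tsv`, invisibly.
#' @export
write_parcellation <- function(result, path_tsv, path_json, path_nii = NULL) {
  if (!is.null(result$grid)) {
    ijk <- flat_to_voxel(result$grid, result$seed_voxels)
  } else ijk <- matrix(NA_integer_, length(result$seed_voxels), 3L)
  tab <- data.frame(voxel = result$seed_voxels, x = ijk[, 1], y = ijk[, 2],
                    z = ijk[, 3], cluster = result$cluster)
  utils::write.table(tab, path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(k = result$k, objective = result$objective,
                            n_replicates = result$n_replicates,
                            seed = result$seed, iterations = result$iterations,
                            degenerate = result$degenerate),
                       path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_nii) && !is.null(result$grid)) {
    vol <- array(0, dim = result$grid$shape)
    vol[result$seed_voxels] <- result$cluster
    write_volume(path_nii, result$grid, vol)
  }
  invisible(path_tsv)
}
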