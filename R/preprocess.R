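#' BOLD time series on a voxel grid
#'
#' A `bold_series` stores one subject's 4D resting-state acquisition as a
#' timepoints x voxels matrix (columns in the grid's flat-index order),
#' together with the grid and the repetition time.
#'
#' @param grid a [volume_grid()].
#' @param data timepoints x voxels numeric matrix (`ncol == prod(grid$shape)`),
#'   or a 4D array whose first three dimensions match the grid.
#' @param tr_seconds repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(grid, data, tr_seconds) {
  if (is.array(data) && length(dim(data)) == 4L) {
    if (!identical(as.integer(dim(data)[1:3]), grid$shape))
      stop("4D data does not match grid shape", call. = FALSE)
    data <- t(matrix(data, nrow = prod(dim(data)[1:3])))
  }
  data <- as.matrix(data)
  if (ncol(data) != n_voxels(grid))
    stop("`data` must have one column per grid voxel", call. = FALSE)
  if (nrow(data) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be positive", call. = FALSE)
  structure(list(grid = grid, data = data, tr_seconds = as.numeric(tr_seconds)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series %s, T=%d, TR=%.3gs>\n",
              paste(x$grid$shape, collapse = "x"), nrow(x$data), x$tr_seconds))
  invisible(x)
}

#' @rdname bold_series
#' @param series a `bold_series`.
#' @return `n_timepoints()` returns the number of timepoints.
#' @export
n_timepoints <- function(series) nrow(series$data)

#' Convert a bold_series to a 4D array
#' @param series a [bold_series()].
#' @return 4D array `c(grid$shape, T)`.
#' @export
as_array_4d <- function(series) {
  array(t(series$data), dim = c(series$grid$shape, nrow(series$data)))
}

#' Read / write a 4D series as NIfTI
#' @param path NIfTI path.
#' @param series a [bold_series()].
#' @param tr_seconds repetition time override when the header lacks one.
#' @return `read_bold()` returns a [bold_series()].
#' @export
read_bold <- function(path, tr_seconds = NULL) {
  v <- read_volume(path)
  if (length(dim(v$values)) != 4L)
    stop("expected a 4D series in ", path, call. = FALSE)
  if (is.null(tr_seconds)) {
    hdr <- RNifti::niftiHeader(RNifti::readNifti(path))
    tr_seconds <- hdr$pixdim[5]
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 1
  }
  bold_series(v$grid, v$values, tr_seconds)
}

#' @rdname read_bold
#' @export
write_bold <- function(path, series) {
  write_volume(path, series$grid, as_array_4d(series),
               tr_seconds = series$tr_seconds)
}

#' Drop initial volumes
#'
#' Removes the first `n` timepoints (dummy scans acquired before steady-state
#' magnetization; 10 by convention here).
#'
#' @param series a [bold_series()].
#' @param n number of leading volumes to drop (0 <= n < T).
#' @return The shortened [bold_series()].
#' @export
drop_initial_volumes <- function(series, n = 10L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be nonnegative", call. = FALSE)
  if (n >= n_timepoints(series))
    stop(sprintf("cannot drop %d of %d volumes", n, n_timepoints(series)),
         call. = FALSE)
  if (n == 0L) return(series)
  series$data <- series$data[-seq_len(n), , drop = FALSE]
  series
}

# Orthonormal basis (QR) of a design matrix; used so residuals are computed as
# y - Q (Q'y), numerically stable and rank-tolerant (minimum-norm fit).
ortho_basis <- function(X) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  if (sum(keep) < ncol(X))
    warning("rank-deficient design (", ncol(X) - sum(keep),
            " dependent column(s)); using minimum-norm fit", call. = FALSE)
  s$u[, keep, drop = FALSE]
}

residualize <- function(Y, X) {
  Q <- ortho_basis(X)
  Y - Q %*% crossprod(Q, Y)
}

# Polynomial basis 1, t, ..., t^order on a [-1, 1]-scaled time axis.
poly_basis <- function(T, order) {
  t <- seq(-1, 1, length.out = T)
  outer(t, 0:order, `^`)
}

#' Polynomial detrending
#'
#' Removes, per voxel, the least-squares fit of a polynomial in time of the
#' given order (order 2 = linear and quadratic trends, plus the mean).
#'
#' @param series a [bold_series()].
#' @param order polynomial order (default 2).
#' @return The detrended [bold_series()].
#' @export
detrend_poly <- function(series, order = 2L) {
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop("`order` must be >= 0", call. = FALSE)
  if (n_timepoints(series) <= order + 1L)
    stop("too few timepoints for polynomial order ", order, call. = FALSE)
  series$data <- residualize(series$data, poly_basis(n_timepoints(series), order))
  series
}

#' Nuisance regression
#'
#' Regresses a set of nuisance time courses (head-motion parameters, mean
#' white-matter and CSF signals) plus an intercept out of every voxel's
#' series by ordinary least squares, keeping the residuals.
#'
#' @param series a [bold_series()].
#' @param table data.frame of nuisance regressors, one row per timepoint.
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, table) {
  table <- as.data.frame(table)
  if (nrow(table) != n_timepoints(series))
    stop(sprintf("nuisance table has %d rows for %d timepoints",
                 nrow(table), n_timepoints(series)), call. = FALSE)
  X <- cbind(1, as.matrix(table))
  if (nrow(X) <= ncol(X))
    stop("design has at least as many columns as timepoints", call. = FALSE)
  series$data <- residualize(series$data, X)
  series
}

#' Grand-mean intensity normalization
#'
#' Scales the whole 4D series so that the grand mean of in-mask values equals
#' `target` (10000 by the usual convention).
#'
#' @param series a [bold_series()].
#' @param target desired grand mean.
#' @param mask optional [binary_mask()] over which the grand mean is taken;
#'   default all voxels.
#' @return The rescaled [bold_series()].
#' @export
grand_mean_normalize <- function(series, target = 10000, mask = NULL) {
  if (target <= 0) stop("`target` must be positive", call. = FALSE)
  vals <- if (is.null(mask)) series$data else {
    stopifnot_same_grid(series$grid, mask$grid, "series and mask")
    series$data[, mask_indices(mask), drop = FALSE]
  }
  gm <- mean(vals)
  if (abs(gm) < 1e-9 * stats::sd(vals))
    stop("grand mean is (numerically) zero; cannot normalize", call. = FALSE)
  series$data <- series$data * (target / gm)
  series
}

#' Ideal Fourier band-pass filter
#'
#' Retains exactly the discrete-Fourier frequency bins with
#' `low_hz <= f <= high_hz` and zeroes all others, including the DC component
#' whenever `low_hz > 0`. This is the sharp Fourier-domain filter used by
#' classical resting-state pipelines.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz <= 1/(2 tr)`.
#' @return The filtered [bold_series()].
#' @export
bandpass <- function(series, low_hz = 0.008, high_hz = 0.01) {
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz <= nyq + 1e-12))
    stop(sprintf("band [%g, %g] Hz outside (0, Nyquist=%g]",
                 low_hz, high_hz, nyq), call. = FALSE)
  T <- n_timepoints(series)
  f <- (seq_len(T) - 1) / (T * series$tr_seconds)
  f <- pmin(f, 1 / series$tr_seconds - f)  # fold to [0, Nyquist]
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12
  F <- stats::mvfft(series$data)
  F[!keep, ] <- 0
  series$data <- Re(stats::mvfft(F, inverse = TRUE)) / T
  series
}

# 1D discrete Gaussian kernel, truncated at 4 sigma, unit sum.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Row-normalized 1D convolution matrix with edge renormalization, so constant
# inputs stay constant near the boundary.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- kernel[ok] / sum(kernel[ok])
  }
  M
}

#' Spatial Gaussian smoothing
#'
#' Convolves each timepoint's volume with a separable 3D Gaussian kernel.
#' `sigma_mm` is given in millimeters and converted to voxels per axis using
#' the grid's voxel size; the kernel is truncated at 4 sigma and renormalized
#' at the volume boundary (so constant volumes are unchanged).
#'
#' @param x a [bold_series()] or a 3D array paired with `grid`.
#' @param sigma_mm Gaussian sigma in mm (0 = identity).
#' @param grid required when `x` is a bare array.
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, sigma_mm = 3, grid = NULL) {
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0", call. = FALSE)
  if (sigma_mm == 0) return(x)
  if (inherits(x, "bold_series")) {
    g <- x$grid
    M <- lapply(1:3, function(ax)
      conv_matrix(g$shape[ax], gauss_kernel(sigma_mm / g$voxel_size_mm[ax])))
    x$data <- t(apply(x$data, 1L, function(v)
      as.vector(smooth_volume_3d(array(v, g$shape), M))))
    return(x)
  }
  if (is.null(grid)) stop("`grid` required for array input", call. = FALSE)
  M <- lapply(1:3, function(ax)
    conv_matrix(grid$shape[ax], gauss_kernel(sigma_mm / grid$voxel_size_mm[ax])))
  smooth_volume_3d(x, M)
}

# Apply per-axis convolution matrices to a 3D array (separable smoothing).
smooth_volume_3d <- function(vol, M) {
  d <- dim(vol)
  a <- M[[1]] %*% matrix(vol, d[1])                     # along x
  a <- array(a, d)
  a <- aperm(apply(a, c(1, 3), function(v) M[[2]] %*% v), c(2, 1, 3))
  a <- array(a, d)
  a <- aperm(apply(a, c(1, 2), function(v) M[[3]] %*% v), c(2, 3, 1))
  array(a, d)
}

#' Mean time course over a mask
#'
#' @param series a [bold_series()].
#' @param mask a nonempty [binary_mask()] on the same grid.
#' @return Numeric vector of length T: the per-timepoint mean of in-mask
#'   voxel values (used for white-matter / CSF nuisance signals).
#' @export
extract_mean_signal <- function(series, mask) {
  stopifnot_same_grid(series$grid, mask$grid, "series and mask")
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  rowMeans(series$data[, idx, drop = FALSE])
}

#' Full preprocessing pipeline
#'
#' Applies the template-space cleaning stages in the canonical order:
#' drop initial volumes, polynomial detrend, nuisance regression, grand-mean
#' normalization, band-pass, spatial smoothing. Any stage can be switched off
#' (`drop_n = 0`, `detrend_order = NA`, `nuisance = NULL`, `grand_mean = NA`,
#' `band = NULL`, `sigma_mm = 0`).
#'
#' @param series a [bold_series()].
#' @param nuisance data.frame of nuisance regressors (rows must match the
#'   series length *after* dropping).
#' @param drop_n leading volumes to discard (default 10).
#' @param detrend_order polynomial order (default 2).
#' @param grand_mean grand-mean target (default 10000).
#' @param band length-2 numeric `c(low_hz, high_hz)` (default `c(0.008, 0.01)`).
#' @param sigma_mm smoothing sigma in mm (default 3).
#' @param mask optional [binary_mask()] for the grand-mean computation.
#' @return The cleaned [bold_series()], with a `log` attribute recording each
#'   applied stage and its parameters.
#' @export
preprocess_bold <- function(series, nuisance = NULL, drop_n = 10L,
                            detrend_order = 2L, grand_mean = 10000,
                            band = c(0.008, 0.01), sigma_mm = 3, mask = NULL) {
  log <- list()
  if (drop_n > 0L) {
    series <- drop_initial_volumes(series, drop_n)
    log$drop <- list(n = drop_n)
  }
  # the scaling factor is taken from the series as it enters the pipeline:
  # detrending / nuisance regression remove the mean, so the grand mean is
  # only meaningful before those stages
  gm0 <- if (is.na(grand_mean)) NA_real_ else {
    vals <- if (is.null(mask)) series$data
            else series$data[, mask_indices(mask), drop = FALSE]
    mean(vals)
  }
  if (!is.na(detrend_order)) {
    series <- detrend_poly(series, detrend_order)
    log$detrend <- list(order = detrend_order)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.data.frame(nuisance)
    if (!is.na(detrend_order)) {
      # detrend the regressors with the same basis so the sequential fit
      # equals a joint regression with polynomial columns (Frisch-Waugh)
      B <- poly_basis(nrow(nuisance), detrend_order)
      nuisance[] <- residualize(as.matrix(nuisance), B)
    }
    series <- regress_nuisance(series, nuisance)
    log$nuisance <- list(columns = colnames(nuisance))
  }
  if (!is.na(grand_mean)) {
    if (abs(gm0) < 1e-9 * stats::sd(series$data))
      stop("grand mean of the input series is (numerically) zero", call. = FALSE)
    series$data <- series$data * (grand_mean / gm0)
    log$grand_mean <- list(target = grand_mean, input_grand_mean = gm0)
  }
  if (!is.null(band)) {
    series <- bandpass(series, band[1], band[2])
    log$bandpass <- list(low_hz = band[1], high_hz = band[2])
  }
  if (sigma_mm > 0) {
    series <- smooth_gaussian(series, sigma_mm)
    log$smooth <- list(sigma_mm = sigma_mm)
  }
  attr(series, "log") <- log
  series
}
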