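grid1 <- volume_grid(c(2, 1, 1))

series_of <- function(..., tr = 2) {
  cols <- list(...)
  bold_series(volume_grid(c(length(cols), 1, 1)),
              do.call(cbind, cols), tr_seconds = tr)
}

test_that("dropping initial volumes shortens the series and keeps the rest", {
  ser <- bold_series(grid1, matrix(rnorm(600), 300), tr_seconds = 0.555)
  out <- drop_initial_volumes(ser, 10)
  expect_equal(n_timepoints(out), 290L)
  expect_equal(out$data, ser$data[11:300, ])
  expect_identical(drop_initial_volumes(ser, 0), ser)
  short <- bold_series(grid1, matrix(rnorm(22), 11), tr_seconds = 1)
  expect_equal(n_timepoints(drop_initial_volumes(short, 10)), 1L)
  expect_error(drop_initial_volumes(short, 11), "cannot drop")
})

test_that("polynomial detrending removes exactly the polynomial span", {
  t <- 1:50
  ser <- series_of(3 + 2 * t, t^2, sin(2 * pi * t / 50))
  out <- detrend_poly(ser, 2)
  expect_lt(max(abs(out$data[, 1])), 1e-8)   # linear -> 0
  expect_lt(max(abs(out$data[, 2])), 1e-7)   # quadratic -> 0
  # sine + trend: residual equals lm() residuals (independent oracle)
  y <- sin(2 * pi * t / 50) + t
  ser2 <- series_of(y)
  fit <- lm(y ~ poly(t, 2))
  expect_equal(as.vector(detrend_poly(ser2, 2)$data), unname(resid(fit)),
               tolerance = 1e-10)
  # residual orthogonal to the basis
  B <- cbind(1, t, t^2)
  expect_lt(max(abs(crossprod(B, detrend_poly(ser2, 2)$data))),
            1e-8 * sqrt(sum(y^2)) * max(abs(B)))
  expect_error(detrend_poly(series_of(c(1, 2, 3)), 2), "too few")
})

test_that("detrending is idempotent", {
  set.seed(1)
  ser <- bold_series(grid1, matrix(rnorm(200), 100), tr_seconds = 1)
  once <- detrend_poly(ser, 2)
  twice <- detrend_poly(once, 2)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("nuisance regression projects out the regressor span", {
  set.seed(2)
  T <- 60
  wm <- rnorm(T); csf <- rnorm(T)
  tab <- data.frame(wm = wm, csf = csf)
  # voxel equal to a regressor -> zero residual
  ser <- series_of(wm, rnorm(T))
  out <- regress_nuisance(ser, tab)
  expect_lt(max(abs(out$data[, 1])), 1e-10)
  # residual orthogonal to every column
  expect_lt(max(abs(crossprod(cbind(1, wm, csf), out$data))), 1e-8)
  # series orthogonal to the regressors -> just demeaned
  Q <- qr.Q(qr(cbind(1, wm, csf)))
  y <- rnorm(T); y_orth <- y - Q %*% crossprod(Q, y)
  out2 <- regress_nuisance(series_of(as.vector(y_orth), rnorm(T)), tab)
  expect_equal(out2$data[, 1], as.vector(y_orth - mean(y_orth)),
               tolerance = 1e-10)
  # duplicated regressor column: same projection (span unchanged)
  out3 <- suppressWarnings(
    regress_nuisance(ser, data.frame(wm = wm, csf = csf, wm2 = wm)))
  base <- regress_nuisance(ser, tab)
  expect_equal(out3$data, base$data, tolerance = 1e-10)
  expect_warning(regress_nuisance(ser, data.frame(wm = wm, wm2 = wm)),
                 "rank-deficient")
  expect_error(regress_nuisance(ser, data.frame(wm = wm[1:10])), "rows")
})

test_that("detrend-then-regress (with detrended regressors) equals one joint regression", {
  # Frisch-Waugh: sequential residualization matches the joint fit when the
  # nuisance regressors are detrended with the same basis, which is what
  # preprocess_bold() does
  set.seed(3)
  T <- 80
  tab <- data.frame(m1 = rnorm(T), m2 = cumsum(rnorm(T)) / sqrt(T))
  Y <- matrix(rnorm(T * 4), T)
  ser <- bold_series(volume_grid(c(4, 1, 1)), Y, tr_seconds = 1)
  tab_dt <- as.data.frame(
    detrend_poly(bold_series(volume_grid(c(2, 1, 1)), as.matrix(tab), 1),
                 2)$data)
  names(tab_dt) <- names(tab)
  seq_res <- regress_nuisance(detrend_poly(ser, 2), tab_dt)$data
  t <- seq(-1, 1, length.out = T)
  X <- cbind(1, t, t^2, as.matrix(tab))
  joint <- Y - X %*% qr.solve(crossprod(X), crossprod(X, Y))
  expect_equal(seq_res, joint, tolerance = 1e-8)
})

test_that("grand-mean normalization scales by target over grand mean", {
  ser <- bold_series(grid1, matrix(500, 10, 2), tr_seconds = 1)
  out <- grand_mean_normalize(ser, 10000)
  expect_equal(out$data, ser$data * 20)
  ser2 <- bold_series(grid1, matrix(10000 + 0 * rnorm(20), 10, 2), 1)
  expect_equal(grand_mean_normalize(ser2, 10000)$data, ser2$data)
  zm <- bold_series(grid1, matrix(c(-1, 1), 10, 2), tr_seconds = 1)
  expect_error(grand_mean_normalize(zm, 10000), "grand mean")
})

test_that("ideal band-pass keeps in-band bins and removes everything else", {
  T <- 200; tr <- 0.5
  tt <- (0:(T - 1)) * tr
  f_in <- 8 / (T * tr)       # an FFT bin inside [0.05, 0.12]
  f_out <- 40 / (T * tr)     # a bin above the band
  ser <- series_of(rep(5, T), sin(2 * pi * f_in * tt),
                   sin(2 * pi * f_out * tt), tr = tr)
  out <- bandpass(ser, 0.05, 0.12)
  expect_lt(max(abs(out$data[, 1])), 1e-10)                    # DC removed
  expect_equal(out$data[, 2], sin(2 * pi * f_in * tt), tolerance = 1e-6)
  expect_lt(max(abs(out$data[, 3])), 1e-6)
  # spectrum zero outside the band
  spec <- abs(fft(out$data[, 2]))
  f <- (0:(T - 1)) / (T * tr); f <- pmin(f, 1 / tr - f)
  expect_lt(max(spec[f < 0.05 - 1e-9 | f > 0.12 + 1e-9]), 1e-8 * max(spec))
  # idempotent for the same band
  expect_equal(bandpass(out, 0.05, 0.12)$data, out$data, tolerance = 1e-10)
  expect_error(bandpass(ser, 0.5, 1.2), "Nyquist")
  expect_error(bandpass(ser, 0.12, 0.05), "Nyquist")
})

test_that("Gaussian smoothing preserves constants and normalizes impulses", {
  grid <- volume_grid(c(9, 9, 9), voxel_size_mm = 2)
  const <- array(7, c(9, 9, 9))
  expect_equal(smooth_gaussian(const, 3, grid = grid), const,
               tolerance = 1e-6)
  expect_identical(smooth_gaussian(const, 0, grid = grid), const)
  # impulse far from the boundary: discrete normalized Gaussian, unit sum
  big <- volume_grid(c(17, 17, 17), voxel_size_mm = 2)
  imp <- array(0, c(17, 17, 17)); imp[9, 9, 9] <- 1
  sm <- smooth_gaussian(imp, 2, grid = big)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_gt(sm[9, 9, 9], sm[8, 9, 9])  # peak at the impulse
  # matches the direct separable kernel construction (oracle)
  k <- connparc:::gauss_kernel(1)
  expect_equal(sm[9, 9, 9], k[5]^3 * 1, tolerance = 1e-12)
  expect_error(smooth_gaussian(const, -1, grid = grid), ">= 0")
})

test_that("mean signal extraction averages in-mask voxels", {
  grid <- volume_grid(c(2, 1, 1))
  ser <- bold_series(grid, cbind(c(1, 2), c(3, 4)), tr_seconds = 1)
  full <- binary_mask(grid, c(TRUE, TRUE))
  expect_equal(extract_mean_signal(ser, full), c(2, 3))
  one <- binary_mask(grid, c(FALSE, TRUE))
  expect_equal(extract_mean_signal(ser, one), c(3, 4))
  expect_error(extract_mean_signal(ser, binary_mask(grid, c(FALSE, FALSE))),
               "empty")
  other <- binary_mask(volume_grid(c(3, 1, 1)), c(TRUE, TRUE, TRUE))
  expect_error(extract_mean_signal(ser, other), "grid mismatch")
})

test_that("the pipeline wrapper applies stages in order and logs them", {
  cfg <- tiny_phantom_cfg(n_subjects = 1, n_timepoints = 60)
  ds <- simulate_cohort(cfg)
  nuis <- ds$nuisance[[1]][-(1:5), ]
  out <- preprocess_bold(ds$subjects[[1]], nuis, drop_n = 5,
                         detrend_order = 2, grand_mean = 10000,
                         band = c(0.01, 0.08), sigma_mm = 2,
                         mask = ds$anatomy$brain_mask)
  expect_equal(n_timepoints(out), 55L)
  expect_named(attr(out, "log"),
               c("drop", "detrend", "nuisance", "grand_mean", "bandpass",
                 "smooth"))
})
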