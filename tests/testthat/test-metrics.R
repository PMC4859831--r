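# NPS / NNPS estimation, radial profiles, crossed comparisons.

# build a spectrum_result by hand (for constructed-spectrum oracles)
fake_spectrum <- function(grid, pitch) {
  ff <- function(n) {
    k <- seq_len(n) - 1
    ifelse(k <= n %/% 2, k, k - n) / (n * pitch)
  }
  structure(list(grid_2d = grid, freq_u = ff(nrow(grid)),
                 freq_v = ff(ncol(grid)), pitch_mm = pitch,
                 normalization = "none", n_rois = 1L,
                 large_area_signal = 1, noise_variance = NA_real_),
            class = "spectrum_result")
}

test_that("zero-noise ROIs give an all-zero spectrum", {
  rois <- replicate(4, matrix(5, 64, 64), simplify = FALSE)
  sp <- nps_2d(rois, 0.07)
  expect_equal(sp$grid_2d, matrix(0, 64, 64))
})

test_that("white-noise NPS is flat at sigma^2 * dx * dy and conserves variance", {
  set.seed(21)
  rois <- replicate(100, matrix(rnorm(64 * 64, 100, 2), 64, 64),
                    simplify = FALSE)
  sp <- nps_2d(rois, 0.07)
  expect_equal(mean(sp$grid_2d), 4 * 0.07^2, tolerance = 0.02)
  # Parseval: spectral integral equals the ROI noise variance
  df2 <- (1 / (64 * 0.07))^2
  expect_equal(sum(sp$grid_2d) * df2, sp$noise_variance, tolerance = 0.01)
})

test_that("nnps divides by the squared large-area signal", {
  set.seed(22)
  rois <- replicate(50, matrix(rnorm(64 * 64, 100, 2), 64, 64),
                    simplify = FALSE)
  sp <- nps_2d(rois, 0.07)
  expect_equal(nnps(sp, 1)$grid_2d, sp$grid_2d)
  expect_equal(nnps(sp, 200)$grid_2d, nnps(sp, 100)$grid_2d / 4)
  # composition of the two closed forms: flat at sigma^2 dx dy / L^2
  n1 <- nnps(sp, 100)
  expect_equal(mean(n1$grid_2d), 1.96e-6, tolerance = 0.02)
  expect_error(nnps(sp, 0), "> 0")
})

test_that("NNPS is invariant under gray-level rescaling of the images", {
  set.seed(23)
  rois <- replicate(20, matrix(rnorm(32 * 32, 50, 3), 32, 32),
                    simplify = FALSE)
  n1 <- nnps(nps_2d(rois, 0.07))
  n2 <- nnps(nps_2d(lapply(rois, function(r) 3 * r), 0.07))
  expect_equal(n2$grid_2d, n1$grid_2d, tolerance = 1e-12)
})

test_that("radial profile averages a flat spectrum to its constant", {
  sp <- fake_spectrum(matrix(0.5, 128, 128), 0.07)
  prof <- radial_profile_1d(sp, band = c(1.5, 7.1))
  expect_equal(prof$density, rep(0.5, nrow(prof)))
  expect_lte(max(prof$freq), 7.1)
  expect_gte(min(prof$freq), 1.5)
})

test_that("radial profile reproduces a radially symmetric f(r) = r spectrum", {
  pitch <- 0.07
  ff <- function(n) {
    k <- seq_len(n) - 1
    ifelse(k <= n %/% 2, k, k - n) / (n * pitch)
  }
  r <- sqrt(outer(ff(128)^2, ff(128)^2, `+`))
  prof <- radial_profile_1d(fake_spectrum(r, pitch), band = c(1.5, 7))
  df <- 1 / (128 * pitch)
  expect_equal(prof$density, prof$freq, tolerance = df)
})

test_that("radial profile refuses an empty band", {
  sp <- fake_spectrum(matrix(1, 64, 64), 0.07)
  expect_error(radial_profile_1d(sp, band = c(7.2, 8)), "empty")
})

test_that("tiled variance comparison: identical sets give zero error", {
  a <- list(rmat(256, 256, sd = 3, seed = 31))
  rep <- tiled_variance_compare(a, a, window = 64)
  expect_equal(rep$average_error, 0)
  expect_true(rep$ci95[1] <= 0 && rep$ci95[2] >= 0)
})

test_that("tiled variance comparison recovers a constructed 10% offset", {
  a <- lapply(1:3, function(i) rmat(512, 512, sd = sqrt(9.9), seed = 40 + i))
  b <- lapply(1:3, function(i) rmat(512, 512, sd = 3, seed = 50 + i))
  rep <- tiled_variance_compare(a, b, window = 64)
  expect_equal(rep$average_error, 10, tolerance = 0.15)
  expect_equal(rep$n_comparisons, 3 * 3 * 64)
})

test_that("window bookkeeping matches the closed-form count", {
  a <- list(rmat(2048, 512, sd = 1, seed = 61))
  b <- list(rmat(2048, 512, sd = 1, seed = 62))
  rep <- tiled_variance_compare(a, b, window = 64)
  expect_equal(rep$n_comparisons, 256L)  # (2048/64) x (512/64)
  roi_rep <- tiled_variance_compare(a, b, window = 64,
                                    roi = c(1, 1024, 1, 512))
  expect_equal(roi_rep$n_comparisons, 128L)
  expect_error(tiled_variance_compare(a, b, roi = c(1, 3000, 1, 512)),
               "roi outside")
})

test_that("spectrum comparison: identical sets give zero error", {
  a <- list(rmat(256, 256, sd = 2, mean = 100, seed = 63))
  rep <- spectrum_compare(a, a, pitch_mm = 0.07, window = 128)
  expect_equal(rep$average_error, 0)
  expect_equal(rep$n_comparisons, 4L)
})

test_that("spectrum comparison tracks an exact gray-level scaling", {
  a <- list(rmat(256, 256, sd = 2, mean = 100, seed = 64))
  b <- lapply(a, function(x) 1.02 * x)
  # raw PS scales by 1.02^2; the per-bin relative error against b is exact
  rep <- spectrum_compare(a, b, pitch_mm = 0.07, window = 128,
                          normalize = "none")
  expect_equal(rep$average_error, 100 * (1 - 1 / 1.02^2), tolerance = 1e-9)
  # under NNPS normalization the same scaling cancels entirely
  rep_n <- spectrum_compare(a, b, pitch_mm = 0.07, window = 128,
                            normalize = "nnps")
  expect_lt(rep_n$average_error, 1e-9)
})

test_that("crossed comparison symmetry: swapping sets negates the difference", {
  a <- lapply(1:2, function(i) rmat(256, 256, sd = 3.02, seed = 70 + i))
  b <- lapply(1:2, function(i) rmat(256, 256, sd = 3.00, seed = 80 + i))
  r_ab <- tiled_variance_compare(a, b, window = 64)
  r_ba <- tiled_variance_compare(b, a, window = 64)
  expect_equal(r_ba$average_difference, -r_ab$average_difference,
               tolerance = 1e-12)
  expect_equal(r_ba$average_error, r_ab$average_error, tolerance = 0.1)
})

test_that("ensemble signal estimate removes structured background", {
  # structured images: same deterministic pattern + iid noise
  patt <- outer(sin(seq(0, 6, length.out = 256)),
                cos(seq(0, 6, length.out = 256))) * 50 + 200
  a <- lapply(1:3, function(i) patt + rmat(256, 256, sd = 2, seed = 90 + i))
  sp_mean <- nps_2d(a, 0.07, signal_estimate = "roi_mean")
  ens <- Reduce(`+`, a) / 3
  sp_ens <- nps_2d(a, 0.07, signal_estimate = ens)
  # subtracting only the scalar mean leaves the pattern power in the NPS
  expect_gt(sum(sp_mean$grid_2d), 5 * sum(sp_ens$grid_2d))
})

test_that("comparison reports serialize to CSV and summary text", {
  a <- list(rmat(128, 128, sd = 1, seed = 95))
  b <- list(rmat(128, 128, sd = 1, seed = 96))
  rep <- tiled_variance_compare(a, b, window = 64)
  prefix <- file.path(withr::local_tempdir(), "cmp")
  paths <- write_comparison_report(rep, prefix)
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[1])
  expect_equal(nrow(tab), rep$n_comparisons)
  expect_match(readLines(paths[2])[1], "tiled local variance")
})
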