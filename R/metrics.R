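## Validation metrics: 2D NPS / NNPS, band-restricted 1D radial profiles,
## tiled local variance, and crossed-comparison statistics.
##
## The 2D noise power spectrum of M equal ROIs is
##   NPS(u,v) = (dx * dy / (Nx * Ny)) * mean_m | DFT{ ROI_m - S_m } |^2 ,
## the discrete form whose integral over frequency equals the ROI noise
## variance (Parseval). NNPS divides by the squared large-area signal.

#' DFT frequency vector in mm^-1
#' @noRd
.fft_freq <- function(n, pitch) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2L, k, k - n) / (n * pitch)
}

#' 2D noise power spectrum from a set of ROIs
#'
#' @param rois list of equal-size numeric matrices (or a single matrix).
#' @param pitch_mm pixel pitch in mm (dx = dy).
#' @param signal_estimate the noiseless-signal approximation S subtracted
#'   from each ROI before the transform: `"roi_mean"` (default; the ROI's
#'   own scalar mean, appropriate for uniform images), a single matrix
#'   used for every ROI, or a list of matrices, one per ROI (ensemble
#'   averages of replicate realizations, for structured images).
#' @return an object of class `spectrum_result`: list with `grid_2d`
#'   (unshifted DFT-order spectral density, mm^2 x value^2), `freq_u`,
#'   `freq_v` (mm^-1), `pitch_mm`, `normalization` (`"none"`), `n_rois`,
#'   `large_area_signal` (mean of the S fields, for later normalization),
#'   `noise_variance` (mean unbiased ROI variance about S).
#' @export
nps_2d <- function(rois, pitch_mm, signal_estimate = "roi_mean") {
  if (is.matrix(rois)) rois <- list(rois)
  stopifnot(length(rois) >= 1L, pitch_mm > 0)
  rois <- lapply(rois, .as_matrix, name = "rois")
  for (r in rois[-1L]) .check_same_shape(rois[[1L]], r, "rois[[1]]", "roi")
  n_r <- nrow(rois[[1L]]); n_c <- ncol(rois[[1L]])
  get_s <- function(i) {
    if (identical(signal_estimate, "roi_mean")) {
      matrix(mean(rois[[i]]), n_r, n_c)
    } else if (is.matrix(signal_estimate)) {
      signal_estimate
    } else if (is.list(signal_estimate)) {
      .as_matrix(signal_estimate[[i]], "signal_estimate")
    } else {
      stop("invalid signal_estimate", call. = FALSE)
    }
  }
  acc <- matrix(0, n_r, n_c)
  l_acc <- 0
  v_acc <- 0
  for (i in seq_along(rois)) {
    s <- get_s(i)
    .check_same_shape(rois[[i]], s, "roi", "signal_estimate")
    d <- rois[[i]] - s
    acc <- acc + Mod(stats::fft(d))^2
    l_acc <- l_acc + mean(s)
    v_acc <- v_acc + sum(d^2) / (length(d) - 1L)
  }
  grid <- acc / length(rois) * pitch_mm^2 / (n_r * n_c)
  structure(list(grid_2d = grid,
                 freq_u = .fft_freq(n_r, pitch_mm),
                 freq_v = .fft_freq(n_c, pitch_mm),
                 pitch_mm = pitch_mm,
                 normalization = "none",
                 n_rois = length(rois),
                 large_area_signal = l_acc / length(rois),
                 noise_variance = v_acc / length(rois)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_result> %d x %d grid, pitch %.3g mm, ",
                     "%d ROIs, normalization: %s\n"),
              nrow(x$grid_2d), ncol(x$grid_2d), x$pitch_mm, x$n_rois,
              x$normalization))
  invisible(x)
}

#' Normalize an NPS by the squared large-area signal
#'
#' @param spec a `spectrum_result` from [nps_2d()].
#' @param large_area_signal positive scalar L; defaults to the mean signal
#'   recorded when the spectrum was computed.
#' @return the `spectrum_result` with `grid_2d` divided by `L^2` and
#'   `normalization` set.
#' @export
nnps <- function(spec, large_area_signal = NULL) {
  stopifnot(inherits(spec, "spectrum_result"))
  L <- if (is.null(large_area_signal)) spec$large_area_signal else
    large_area_signal
  if (!is.finite(L) || L <= 0) {
    stop("large_area_signal must be > 0", call. = FALSE)
  }
  spec$grid_2d <- spec$grid_2d / L^2
  spec$normalization <- "large-area-signal-squared"
  spec$large_area_signal <- L
  spec
}

#' Band-restricted 1D radial profile of a 2D spectrum
#'
#' Averages the 2D spectral density in annular frequency bins of width
#' `1/(N * pitch)` (the grid's own spacing). The zero-frequency axes
#' (u = 0 or v = 0) are excluded to keep fixed-pattern leakage out of the
#' noise profile, and the profile is restricted to the stated band.
#'
#' @param spec a `spectrum_result`.
#' @param band numeric length-2, `c(lo, hi)` in mm^-1; the upper edge is
#'   clipped to the Nyquist frequency `1/(2 * pitch)`.
#' @return data.frame with columns `freq` (bin center, mm^-1), `density`,
#'   `n` (2D bins averaged).
#' @export
radial_profile_1d <- function(spec, band = c(1.5, 7.1)) {
  stopifnot(inherits(spec, "spectrum_result"), length(band) == 2L)
  nyq <- 1 / (2 * spec$pitch_mm)
  lo <- band[1L]; hi <- min(band[2L], nyq)
  if (!(lo < hi)) stop("empty frequency band", call. = FALSE)
  fu <- spec$freq_u; fv <- spec$freq_v
  r <- sqrt(outer(fu^2, fv^2, `+`))
  on_axis <- outer(fu == 0, fv == 0, `|`)
  df <- max(fu[2L] - fu[1L], fv[2L] - fv[1L])
  keep <- !on_axis & r >= lo & r <= hi
  bin <- floor(r[keep] / df + 0.5)
  dens <- tapply(spec$grid_2d[keep], bin, mean)
  cnt <- tapply(spec$grid_2d[keep], bin, length)
  centers <- as.numeric(names(dens)) * df
  out <- data.frame(freq = centers, density = as.numeric(dens),
                    n = as.integer(cnt))
  out[out$freq >= lo & out$freq <= hi, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Crossed comparisons

#' @noRd
.crop_roi <- function(x, roi) {
  if (is.null(roi)) return(x)
  stopifnot(length(roi) == 4L)
  if (roi[1L] < 1L || roi[3L] < 1L || roi[2L] > nrow(x) ||
      roi[4L] > ncol(x) || roi[1L] > roi[2L] || roi[3L] > roi[4L]) {
    stop("roi outside the image", call. = FALSE)
  }
  x[roi[1L]:roi[2L], roi[3L]:roi[4L], drop = FALSE]
}

#' @noRd
.comparison_report <- function(metric, rel_err_pct, diffs, n_comparisons) {
  se <- stats::sd(diffs) / sqrt(length(diffs))
  md <- mean(diffs)
  structure(list(metric = metric,
                 errors = rel_err_pct,
                 average_error = mean(rel_err_pct),
                 error_sd = stats::sd(rel_err_pct),
                 average_difference = md,
                 ci95 = c(md - stats::qnorm(0.975) * se,
                          md + stats::qnorm(0.975) * se),
                 n_comparisons = n_comparisons),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%d comparisons)\n",
              x$metric, x$n_comparisons))
  cat(sprintf("  average error (%%): %.3g +/- %.3g\n",
              x$average_error, x$error_sd))
  cat(sprintf("  average difference: %.4g [%.4g, %.4g] (95%% CI)\n",
              x$average_difference, x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Crossed comparison of tiled local variances
#'
#' Computes the per-window (unbiased) variance of every image in each set
#' inside the analysis ROI, then compares every image of `set_a` against
#' every image of `set_b` (the crossed design), window by window. Relative
#' errors use `set_b` as the reference, so `set_b` is conventionally the
#' set of real acquisitions.
#'
#' @param set_a,set_b lists of matrices or [raw_image()]s, all sharing one
#'   shape. `set_a` is the set under test (e.g. simulated images).
#' @param window square window side in pixels (default 64).
#' @param roi optional analysis rectangle `c(row1, row2, col1, col2)`;
#'   `NULL` uses the whole image.
#' @return a `comparison_report` with the per-comparison relative errors
#'   (%), their mean and spread, the mean difference `a - b` with its 95%
#'   normal-theory CI, and `n_comparisons = |A| * |B| * windows`.
#' @export
tiled_variance_compare <- function(set_a, set_b, window = 64L, roi = NULL) {
  prep <- function(s) {
    if (!is.list(s) || is.matrix(s)) s <- list(s)
    lapply(s, function(x) .crop_roi(.as_matrix(x, "set"), roi))
  }
  a <- prep(set_a); b <- prep(set_b)
  for (m in c(a[-1L], b)) .check_same_shape(a[[1L]], m, "set_a[[1]]", "image")
  va <- lapply(a, function(x) as.vector(.tile_stat(x, window, stats::var)))
  vb <- lapply(b, function(x) as.vector(.tile_stat(x, window, stats::var)))
  n_win <- length(va[[1L]])
  errs <- c(); diffs <- c()
  for (x in va) for (y in vb) {
    errs <- c(errs, 100 * abs(x - y) / y)
    diffs <- c(diffs, x - y)
  }
  .comparison_report("tiled local variance", errs, diffs,
                     length(a) * length(b) * n_win)
}

#' Crossed comparison of band-restricted 1D noise spectra
#'
#' For every image: the ROI is cut into non-overlapping square windows,
#' the 2D spectrum of the windows is computed with [nps_2d()], optionally
#' normalized ([nnps()]), and reduced to its band-restricted radial
#' profile. Every profile of `set_a` is then compared against every
#' profile of `set_b` frequency bin by frequency bin; relative errors use
#' `set_b` as reference.
#'
#' @inheritParams tiled_variance_compare
#' @param pitch_mm pixel pitch in mm.
#' @param window spectral ROI side in pixels (default 128, i.e. 0.90 cm at
#'   0.07 mm pitch).
#' @param band analysis band in mm^-1 (default `c(1.5, 7.1)`).
#' @param normalize `"nnps"` (default; divide by the squared mean signal,
#'   for uniform images), `"none"` (raw NPS / PS).
#' @param signal `"roi_mean"` (default) or `"ensemble"`: with
#'   `"ensemble"`, the noiseless approximation for every image of a set is
#'   the pixelwise average of all images in that set (use with >= 2
#'   structured realizations per set).
#' @return a `comparison_report`; `n_comparisons = |A| * |B| * windows`
#'   following the crossed design bookkeeping.
#' @export
spectrum_compare <- function(set_a, set_b, pitch_mm, window = 128L,
                             band = c(1.5, 7.1), roi = NULL,
                             normalize = c("nnps", "none"),
                             signal = c("roi_mean", "ensemble")) {
  normalize <- match.arg(normalize)
  signal <- match.arg(signal)
  prep <- function(s) {
    if (!is.list(s) || is.matrix(s)) s <- list(s)
    lapply(s, function(x) .crop_roi(.as_matrix(x, "set"), roi))
  }
  a <- prep(set_a); b <- prep(set_b)
  for (m in c(a[-1L], b)) .check_same_shape(a[[1L]], m, "set_a[[1]]", "image")
  tile_list <- function(x, w) {
    nt_r <- nrow(x) %/% w; nt_c <- ncol(x) %/% w
    out <- vector("list", nt_r * nt_c)
    k <- 1L
    for (j in seq_len(nt_c)) for (i in seq_len(nt_r)) {
      out[[k]] <- x[((i - 1L) * w + 1L):(i * w),
                    ((j - 1L) * w + 1L):(j * w), drop = FALSE]
      k <- k + 1L
    }
    out
  }
  profile_of <- function(x, ens) {
    rois <- tile_list(x, window)
    sig_est <- if (signal == "ensemble") tile_list(ens, window) else
      "roi_mean"
    sp <- nps_2d(rois, pitch_mm, signal_estimate = sig_est)
    if (normalize == "nnps") sp <- nnps(sp)
    radial_profile_1d(sp, band)
  }
  ens_a <- if (signal == "ensemble") Reduce(`+`, a) / length(a) else NULL
  ens_b <- if (signal == "ensemble") Reduce(`+`, b) / length(b) else NULL
  pa <- lapply(a, profile_of, ens = ens_a)
  pb <- lapply(b, profile_of, ens = ens_b)
  n_win <- (nrow(a[[1L]]) %/% window) * (ncol(a[[1L]]) %/% window)
  errs <- c(); diffs <- c()
  for (x in pa) for (y in pb) {
    errs <- c(errs, 100 * abs(x$density - y$density) / y$density)
    diffs <- c(diffs, x$density - y$density)
  }
  metric <- if (normalize == "nnps") "band NNPS" else "band PS"
  .comparison_report(metric, errs, diffs, length(a) * length(b) * n_win)
}

#' Write a comparison report as CSV plus a plain-text summary
#'
#' @param report a `comparison_report`.
#' @param prefix output path prefix; writes `<prefix>_errors.csv` and
#'   `<prefix>_summary.txt`.
#' @return the two paths, invisibly.
#' @export
write_comparison_report <- function(report, prefix) {
  stopifnot(inherits(report, "comparison_report"))
  p1 <- paste0(prefix, "_errors.csv")
  p2 <- paste0(prefix, "_summary.txt")
  utils::write.csv(data.frame(relative_error_pct = report$errors), p1,
                   row.names = FALSE)
  writeLines(c(sprintf("metric: %s", report$metric),
               sprintf("n_comparisons: %d", report$n_comparisons),
               sprintf("average_error_pct: %.6g +/- %.6g",
                       report$average_error, report$error_sd),
               sprintf("average_difference: %.6g", report$average_difference),
               sprintf("ci95: [%.6g, %.6g]", report$ci95[1L],
                       report$ci95[2L])),
             p2)
  invisible(c(p1, p2))
}
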