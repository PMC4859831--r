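## Detector offset / linearity calibration from flat-field exposures.
##
## An a-Se mammography detector responds linearly to entrance dose with an
## additive offset: mean pixel value = theta + slope * dose. The offset is
## the intercept of an ordinary least-squares fit of windowed flat-field
## means against dose; it is subtracted before any scaling and restored as
## the very last pipeline step.

#' Estimate the detector offset and linearity from flat-field images
#'
#' Fits mean pixel value against dose by ordinary least squares. Rather
#' than one mean per image, the mean is taken over square windows tiled
#' across each flat (the spatial nonuniformity of the field then shows up
#' in the fit's spread without biasing the intercept). The regression
#' intercept is the detector offset theta; the slope is the system gain in
#' pixel value per dose unit.
#'
#' @param flats list of [raw_image()] flat-field exposures covering at
#'   least two distinct dose levels.
#' @param window square window side in pixels for the tiled means
#'   (default 64).
#' @param n_windows optionally use only the first `n_windows` tiles (in
#'   column-major tile order) of each flat; `NULL` uses all complete tiles.
#' @param dose_from which metadata field provides the regression abscissa:
#'   `"mas"` (default) or `"dose_label"`. The intercept is invariant to
#'   any linear rescaling of the abscissa.
#' @return an object of class `calibration_model`: list with
#'   `offset_theta`, `slope`, `r_squared`, `n_points`, `window`,
#'   `dose_from`.
#' @examples
#' det <- detector_model(offset_theta = 50, shape = c(256, 256))
#' flats <- lapply(c(80, 160), function(m) generate_flat(det, m, seed = m))
#' estimate_offset(flats, window = 64)
#' @export
estimate_offset <- function(flats, window = 64L, n_windows = NULL,
                            dose_from = c("mas", "dose_label")) {
  dose_from <- match.arg(dose_from)
  if (inherits(flats, "raw_image")) flats <- list(flats)
  stopifnot(length(flats) >= 1L)
  dose <- vapply(flats, function(f) as.numeric(f[[dose_from]]), 0)
  if (anyNA(dose)) {
    stop(sprintf("every flat needs a finite '%s' value", dose_from),
         call. = FALSE)
  }
  if (length(unique(dose)) < 2L) {
    stop("need flats at >= 2 distinct dose levels to fit a line",
         call. = FALSE)
  }
  pts <- lapply(seq_along(flats), function(i) {
    m <- .tile_stat(flats[[i]]$pixels, window, mean)
    v <- as.vector(m)
    if (!is.null(n_windows)) {
      if (n_windows > length(v)) {
        stop("n_windows exceeds the number of complete tiles", call. = FALSE)
      }
      v <- v[seq_len(n_windows)]
    }
    data.frame(dose = dose[i], value = v)
  })
  pts <- do.call(rbind, pts)
  fit <- stats::lm(value ~ dose, data = pts)
  ss_tot <- sum((pts$value - mean(pts$value))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(offset_theta = unname(coef(fit)[1L]),
                 slope = unname(coef(fit)[2L]),
                 r_squared = r2,
                 n_points = nrow(pts),
                 window = as.integer(window),
                 dose_from = dose_from),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> offset theta = %.4g, slope = %.4g",
                     " per %s\n  r^2 = %.6f from %d windowed means",
                     " (window %d)\n"),
              x$offset_theta, x$slope, x$dose_from, x$r_squared,
              x$n_points, x$window))
  invisible(x)
}

#' Build a calibration model from a known offset
#'
#' Convenience constructor for when the offset is known (e.g. from the
#' manufacturer) rather than fitted.
#'
#' @param offset_theta detector offset in pixel-value units.
#' @param slope system gain (pixel value per dose unit), if known.
#' @return a `calibration_model`.
#' @export
calibration_model <- function(offset_theta, slope = NA_real_) {
  stopifnot(is.finite(offset_theta))
  structure(list(offset_theta = offset_theta, slope = slope,
                 r_squared = NA_real_, n_points = 0L, window = NA_integer_,
                 dose_from = "mas"),
            class = "calibration_model")
}

#' Linearize an image by removing the detector offset
#'
#' Subtracts the offset theta so pixel values become proportional to dose;
#' results are clamped at zero (pixels below theta carry no usable signal
#' and a negative count domain would break the Anscombe transform).
#'
#' @param img [raw_image()] or numeric matrix.
#' @param cal a `calibration_model`, or a single number taken as theta.
#' @return numeric matrix of linearized values.
#' @export
linearize <- function(img, cal) {
  px <- .as_matrix(img, "img")
  theta <- if (inherits(cal, "calibration_model")) cal$offset_theta else cal
  stopifnot(is.finite(theta))
  pmax(px - theta, 0)
}

#' Scale a linearized image to a reduced dose
#'
#' Multiplies elementwise by the reduction rate alpha, the mAs ratio of
#' the simulated to the full acquisition. The mean scales by alpha and the
#' variance by alpha^2 - which is precisely why noise must be injected
#' afterwards: a real low-dose image has variance proportional to alpha,
#' not alpha^2.
#'
#' @param lin numeric matrix, linearized (offset-free) image.
#' @param alpha reduction rate in (0, 1]; dose increase is not supported.
#' @return scaled numeric matrix.
#' @export
scale_to_dose <- function(lin, alpha) {
  lin <- .as_matrix(lin, "lin")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  alpha * lin
}

#' Dose-reduction rate from mAs values
#'
#' @param mas_full mAs of the full-dose acquisition.
#' @param mas_sim mAs of the simulated acquisition; must not exceed
#'   `mas_full`.
#' @return `mas_sim / mas_full`.
#' @examples
#' compute_alpha(160, 80)   # 0.5
#' compute_alpha(160, 140)  # 0.875
#' @export
compute_alpha <- function(mas_full, mas_sim) {
  stopifnot(is.finite(mas_full), is.finite(mas_sim))
  if (mas_full <= 0 || mas_sim <= 0) {
    stop("mAs values must be > 0", call. = FALSE)
  }
  if (mas_sim > mas_full) {
    stop("mas_sim > mas_full: dose increase is not supported", call. = FALSE)
  }
  mas_sim / mas_full
}

#' Serialize / read a calibration model as key-value text
#'
#' @param cal a `calibration_model`.
#' @param path file to write / read.
#' @return `write_calibration`: `path` invisibly; `read_calibration`: a
#'   `calibration_model`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  lines <- c(sprintf("offset_theta=%.17g", cal$offset_theta),
             sprintf("slope=%.17g", cal$slope),
             sprintf("r_squared=%.17g", cal$r_squared),
             sprintf("n_points=%d", cal$n_points),
             sprintf("window=%d", cal$window),
             sprintf("dose_from=%s", cal$dose_from))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  structure(list(offset_theta = as.numeric(vals[["offset_theta"]]),
                 slope = as.numeric(vals[["slope"]]),
                 r_squared = as.numeric(vals[["r_squared"]]),
                 n_points = as.integer(vals[["n_points"]]),
                 window = as.integer(vals[["window"]]),
                 dose_from = vals[["dose_from"]]),
            class = "calibration_model")
}
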