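## Synthetic a-Se detector and breast-texture phantom simulator.
##
## The generator targets the statistical contract of flat-fielded raw
## mammograms, not anatomical realism. A flat-fielded detector has an
## (approximately) uniform mean response across the field, but the
## flat-field correction rescales the quantum noise by a position-
## dependent factor, so the local variance-to-mean ratio of an
## offset-subtracted flat varies smoothly across the field (typically
## ~0.1-0.3 on a-Se systems). That behavior is reproduced by drawing
##   pixel = theta + g(x,y) * Poisson( q * mAs * att(x,y) / g(x,y) )
##           + N(0, readout_sigma),
## where g is the smooth flat-field gain map: the offset-subtracted mean
## is q * mAs * att (independent of g) while variance/mean = g.

#' Synthetic detector model
#'
#' @param offset_theta additive detector offset in pixel-value units
#'   (default 50, a typical manufacturer value for a-Se units).
#' @param gain_range range `c(lo, hi)` spanned by the smooth gain map,
#'   which equals the variance/mean ratio of offset-subtracted flats
#'   (default `c(0.1, 0.3)`).
#' @param gain_map optional user-supplied gain matrix (positive), used as
#'   is; its shape must match the generated images.
#' @param quanta_per_mas expected offset-subtracted pixel value per mAs at
#'   unit attenuation (default 10: a 160 mAs flat sits near pixel value
#'   1600).
#' @param readout_sigma additive Gaussian readout noise std (default 0 so
#'   the noise model is exactly gain-scaled Poisson).
#' @param bit_depth detector bit depth (default 14).
#' @param pixel_pitch_mm pixel pitch (default 0.07 mm).
#' @param shape default image shape `c(rows, cols)` (default
#'   `c(2048, 512)`, a breast-sized analysis strip).
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(offset_theta = 50, gain_range = c(0.1, 0.3),
                           gain_map = NULL, quanta_per_mas = 10,
                           readout_sigma = 0, bit_depth = 14L,
                           pixel_pitch_mm = 0.07, shape = c(2048L, 512L)) {
  stopifnot(quanta_per_mas > 0, readout_sigma >= 0,
            length(gain_range) == 2L, gain_range[1L] > 0,
            gain_range[2L] >= gain_range[1L])
  if (!is.null(gain_map)) {
    gain_map <- .as_matrix(gain_map, "gain_map")
    if (min(gain_map) <= 0) stop("gain_map must be > 0", call. = FALSE)
  }
  structure(list(offset_theta = offset_theta, gain_range = gain_range,
                 gain_map = gain_map, quanta_per_mas = quanta_per_mas,
                 readout_sigma = readout_sigma,
                 bit_depth = as.integer(bit_depth),
                 pixel_pitch_mm = pixel_pitch_mm,
                 shape = as.integer(shape)),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(paste0("<detector_model> theta %.3g, gain [%.3g, %.3g], ",
                     "%.3g counts/mAs, readout %.3g, %d-bit, %s px\n"),
              x$offset_theta, x$gain_range[1L], x$gain_range[2L],
              x$quanta_per_mas, x$readout_sigma, x$bit_depth,
              paste(x$shape, collapse = " x ")))
  invisible(x)
}

## Smooth low-order cosine gain field spanning gain_range.
#' @noRd
.gain_field <- function(det, shape) {
  if (!is.null(det$gain_map)) {
    if (!identical(dim(det$gain_map), as.integer(shape))) {
      stop("gain_map shape does not match the requested image shape",
           call. = FALSE)
    }
    return(det$gain_map)
  }
  u <- seq(0, 1, length.out = shape[1L])
  v <- seq(0, 1, length.out = shape[2L])
  ramp <- (1 - outer(cos(pi * u), cos(pi * v))) / 2  # in [0, 1]
  det$gain_range[1L] + diff(det$gain_range) * ramp
}

#' @noRd
.detector_draw <- function(det, mas, att, seed) {
  shape <- dim(att)
  g <- .gain_field(det, shape)
  lam <- det$quanta_per_mas * mas * att / g
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(lam), lam), shape[1L], shape[2L])
  px <- det$offset_theta + g * counts
  if (det$readout_sigma > 0) {
    px <- px + matrix(stats::rnorm(length(lam), 0, det$readout_sigma),
                      shape[1L], shape[2L])
  }
  px <- pmin(pmax(round(px), 0), 2^det$bit_depth - 1)
  raw_image(px, pixel_pitch_mm = det$pixel_pitch_mm, mas = mas,
            bit_depth = det$bit_depth)
}

#' Generate a synthetic flat-field exposure
#'
#' Draws a uniform-phantom ("flat") raw image from the detector model at
#' the given mAs. Offset-subtracted values are linear in mAs with
#' variance/mean ratio equal to the local gain.
#'
#' @param det a [detector_model()].
#' @param mas current-exposure-time product.
#' @param shape image shape `c(rows, cols)`; defaults to `det$shape`.
#' @param seed integer RNG seed (images are reproducible given the seed).
#' @return a [raw_image()].
#' @export
generate_flat <- function(det, mas, shape = NULL, seed = 1L) {
  stopifnot(inherits(det, "detector_model"), mas > 0)
  if (is.null(shape)) shape <- det$shape
  .detector_draw(det, mas, matrix(1, shape[1L], shape[2L]), seed)
}

#' Synthetic breast-texture phantom model
#'
#' A transmission (attenuation) map in `[0, 1]` built from power-law
#' (`1/f^beta`) filtered Gaussian noise - the standard mammographic
#' texture model - rescaled into `att_range`, with optional
#' microcalcification-like spots that locally reduce transmission.
#'
#' @param shape phantom shape `c(rows, cols)`.
#' @param beta power-law exponent of the texture spectrum (default 3).
#' @param att_range transmission range of the texture (default
#'   `c(0.4, 0.9)`).
#' @param calc_spots data.frame with columns `row`, `col`, `diameter_px`,
#'   `contrast` (fractional transmission drop in (0, 1)); `NULL` for
#'   none.
#' @param seed RNG seed for the texture field.
#' @return an object of class `phantom_model` with the realized
#'   `attenuation` matrix.
#' @export
phantom_model <- function(shape = c(2048L, 512L), beta = 3,
                          att_range = c(0.4, 0.9), calc_spots = NULL,
                          seed = 1L) {
  stopifnot(length(shape) == 2L, beta >= 0,
            att_range[1L] >= 0, att_range[2L] <= 1,
            att_range[1L] < att_range[2L])
  n_r <- as.integer(shape[1L]); n_c <- as.integer(shape[2L])
  set.seed(as.integer(seed))
  white <- matrix(stats::rnorm(n_r * n_c), n_r, n_c)
  fu <- .fft_freq(n_r, 1); fv <- .fft_freq(n_c, 1)
  r <- sqrt(outer(fu^2, fv^2, `+`))
  filt <- r^(-beta / 2)   # amplitude filter: power goes as 1/f^beta
  filt[1L, 1L] <- 0
  tex <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) /
    (n_r * n_c)
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  att <- att_range[1L] + diff(att_range) * tex
  if (!is.null(calc_spots)) {
    stopifnot(all(c("row", "col", "diameter_px", "contrast") %in%
                    names(calc_spots)))
    for (k in seq_len(nrow(calc_spots))) {
      cs <- calc_spots[k, ]
      if (cs$row < 1 || cs$row > n_r || cs$col < 1 || cs$col > n_c) {
        stop("calc spot outside the image", call. = FALSE)
      }
      rad <- cs$diameter_px / 2
      rr <- max(1L, floor(cs$row - rad)):min(n_r, ceiling(cs$row + rad))
      cc <- max(1L, floor(cs$col - rad)):min(n_c, ceiling(cs$col + rad))
      d2 <- outer((rr - cs$row)^2, (cc - cs$col)^2, `+`)
      inside <- d2 <= rad^2
      att[rr, cc][inside] <- att[rr, cc][inside] * (1 - cs$contrast)
    }
  }
  structure(list(attenuation = att, beta = beta, att_range = att_range,
                 calc_spots = calc_spots, seed = as.integer(seed)),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf(paste0("<phantom_model> %d x %d, beta %.3g, transmission ",
                     "[%.3g, %.3g], %d calc spots\n"),
              nrow(x$attenuation), ncol(x$attenuation), x$beta,
              min(x$attenuation), max(x$attenuation),
              if (is.null(x$calc_spots)) 0L else nrow(x$calc_spots)))
  invisible(x)
}

#' Generate a synthetic phantom exposure
#'
#' Like [generate_flat()] but with the expected quanta modulated by the
#' phantom's transmission map.
#'
#' @inheritParams generate_flat
#' @param phantom a [phantom_model()]; its shape fixes the image shape.
#' @return a [raw_image()].
#' @export
generate_phantom_image <- function(det, phantom, mas, seed = 1L) {
  stopifnot(inherits(det, "detector_model"),
            inherits(phantom, "phantom_model"), mas > 0)
  .detector_draw(det, mas, phantom$attenuation, seed)
}

#' Generate paired image sets across doses
#'
#' Produces, for each mAs level, `n_per_dose` independent phantom
#' realizations and `n_flats_per_dose` flat-field exposures, each with a
#' distinct seed derived from `seed`. This mirrors the acquisition design
#' used to validate dose simulation: replicate exposures at the standard
#' dose and at each reduced dose, plus flats for the noise model.
#'
#' @inheritParams generate_flat
#' @param phantom a [phantom_model()] shared by all realizations.
#' @param mas_list numeric vector of mAs levels.
#' @param n_per_dose phantom realizations per dose (default 5).
#' @param n_flats_per_dose flat exposures per dose (default 2).
#' @return a list with elements `phantoms` and `flats`, each a named list
#'   (one entry per mAs level, named by the mAs value) of lists of
#'   [raw_image()]s.
#' @export
make_paired_doses <- function(det, phantom, mas_list, n_per_dose = 5L,
                              n_flats_per_dose = 2L, seed = 1L) {
  stopifnot(length(mas_list) >= 1L)
  seed <- as.integer(seed)
  out_p <- list(); out_f <- list()
  for (d in seq_along(mas_list)) {
    mas <- mas_list[d]
    base <- (seed + d * 10000L) %% .Machine$integer.max
    out_p[[as.character(mas)]] <- lapply(seq_len(n_per_dose), function(i) {
      generate_phantom_image(det, phantom, mas, seed = base + i)
    })
    out_f[[as.character(mas)]] <- lapply(
      seq_len(n_flats_per_dose),
      function(i) generate_flat(det, mas, shape = dim(phantom$attenuation),
                                seed = base + 1000L + i))
  }
  list(phantoms = out_p, flats = out_f)
}
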