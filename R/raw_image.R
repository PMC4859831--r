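## raw_image: a raw ("for processing") detector frame plus the acquisition
## metadata the simulation needs. Pixels are stored as a base numeric
## matrix (rows = detector rows).

#' Construct a raw detector image
#'
#' Bundles a 2D pixel array with the acquisition metadata used throughout
#' the package: pixel pitch, current-exposure-time product (mAs), a
#' nominal dose label and the detector bit depth.
#'
#' @param pixels numeric matrix of nonnegative pixel values.
#' @param pixel_pitch_mm detector pixel pitch in mm (default 0.07, typical
#'   of a-Se full-field digital mammography).
#' @param mas current-exposure-time product of the acquisition (mAs), or
#'   `NA` if unknown.
#' @param dose_label optional nominal entrance dose (any linear dose unit).
#' @param bit_depth detector bit depth; pixels must fit in
#'   `[0, 2^bit_depth - 1]`.
#' @return an object of class `raw_image` (a list with the fields above).
#' @export
raw_image <- function(pixels, pixel_pitch_mm = 0.07, mas = NA_real_,
                      dose_label = NA_real_, bit_depth = 14L) {
  pixels <- .as_matrix(pixels, "pixels")
  .check_finite(pixels, "pixels")
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be > 0", call. = FALSE)
  if (!is.na(mas) && mas <= 0) stop("mas must be > 0", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1) {
    stop(sprintf("pixels outside [0, 2^%d - 1]", bit_depth), call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_pitch_mm = pixel_pitch_mm,
                 mas = mas, dose_label = dose_label,
                 bit_depth = as.integer(bit_depth)),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d px, pitch %.3g mm, mas %s, bit depth %d\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_mm,
              ifelse(is.na(x$mas), "?", format(x$mas)), x$bit_depth))
  cat(sprintf("  pixel range [%.4g, %.4g], mean %.5g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' @export
dim.raw_image <- function(x) dim(x$pixels)

#' Read a raw image from disk
#'
#' Supported formats, chosen by file extension:
#' \describe{
#'   \item{`.tif` / `.tiff`}{16-bit grayscale TIFF; stored sample values
#'     are returned unscaled.}
#'   \item{anything else}{whitespace-delimited text matrix ("raw array"
#'     format), one image row per line.}
#' }
#' Acquisition metadata is not carried by either format and is supplied
#' through the arguments.
#'
#' @param path file to read.
#' @inheritParams raw_image
#' @return a [raw_image()].
#' @export
read_raw_image <- function(path, pixel_pitch_mm = 0.07, mas = NA_real_,
                           dose_label = NA_real_, bit_depth = 14L) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px <- px * 1.0
  } else {
    px <- as.matrix(utils::read.table(path))
    dimnames(px) <- NULL
  }
  raw_image(px, pixel_pitch_mm = pixel_pitch_mm, mas = mas,
            dose_label = dose_label, bit_depth = bit_depth)
}

#' Write an image to disk
#'
#' `.tif`/`.tiff` paths get a 16-bit grayscale TIFF (values are rounded
#' and clipped to `[0, 65535]`; integer inputs round-trip exactly). Any
#' other extension gets a whitespace-delimited text matrix written with
#' full `%.17g` precision, which round-trips doubles exactly and is
#' byte-stable across runs.
#'
#' @param img a [raw_image()] or numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raw_image <- function(img, path) {
  px <- .as_matrix(img, "img")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- pmin(pmax(round(px), 0), 65535)
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else {
    lines <- apply(px, 1L, function(r) paste(sprintf("%.17g", r),
                                             collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}
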