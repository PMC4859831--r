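## Local noise estimation from uniform images and construction of the
## noise mask that the pipeline embeds in the Anscombe domain.
##
## The target per-pixel standard deviation of the noise to be added is
## sigma_sim(x,y) = sqrt( var[H_sim^L](x,y) - var[H_o^{L,S}](x,y) ),
## the pointwise difference between the local variance of the linearized
## target-dose flat and that of the linearized, alpha-scaled full-dose
## flat. Both variance fields are measured with a square window, either
## tiled (block-constant) or sliding (per pixel).

## Apply stat_fn over complete non-overlapping w x w tiles.
## Returns an (nrow %/% w) x (ncol %/% w) matrix; incomplete border tiles
## are dropped.
#' @noRd
.tile_stat <- function(x, w, stat_fn) {
  w <- as.integer(w)
  nt_r <- nrow(x) %/% w
  nt_c <- ncol(x) %/% w
  if (nt_r < 1L || nt_c < 1L) {
    stop("window larger than the image", call. = FALSE)
  }
  x <- x[seq_len(nt_r * w), seq_len(nt_c * w), drop = FALSE]
  out <- matrix(0, nt_r, nt_c)
  for (j in seq_len(nt_c)) {
    cols <- ((j - 1L) * w + 1L):(j * w)
    block <- x[, cols, drop = FALSE]
    a <- array(block, c(w, nt_r, w))
    for (i in seq_len(nt_r)) out[i, j] <- stat_fn(as.vector(a[, i, ]))
  }
  out
}

## Expand a tile-level map back to per-pixel resolution.
#' @noRd
.expand_tiles <- function(tiles, w, shape, method = c("block", "bilinear")) {
  method <- match.arg(method)
  nt_r <- nrow(tiles); nt_c <- ncol(tiles)
  if (method == "block") {
    full <- tiles[rep(seq_len(nt_r), each = w),
                  rep(seq_len(nt_c), each = w), drop = FALSE]
  } else {
    # bilinear between tile centers, constant beyond the outermost centers
    ctr_r <- (seq_len(nt_r) - 0.5) * w
    ctr_c <- (seq_len(nt_c) - 0.5) * w
    interp1 <- function(centers, vals_mat, at) {
      # rowwise linear interpolation of a matrix whose rows index 'centers'
      idx <- findInterval(at, centers, all.inside = TRUE)
      lo <- centers[idx]; hi <- centers[idx + 1L]
      t <- pmin(pmax((at - lo) / (hi - lo), 0), 1)
      vals_mat[idx, , drop = FALSE] * (1 - t) +
        vals_mat[idx + 1L, , drop = FALSE] * t
    }
    rows_at <- seq_len(nt_r * w)
    cols_at <- seq_len(nt_c * w)
    tmp <- interp1(ctr_r, tiles, rows_at)
    full <- t(interp1(ctr_c, t(tmp), cols_at))
  }
  # pad (replicate last row/col) if the image was not a tile multiple
  if (nrow(full) < shape[1L]) {
    full <- full[c(seq_len(nrow(full)),
                   rep(nrow(full), shape[1L] - nrow(full))), , drop = FALSE]
  }
  if (ncol(full) < shape[2L]) {
    full <- full[, c(seq_len(ncol(full)),
                     rep(ncol(full), shape[2L] - ncol(full))), drop = FALSE]
  }
  full
}

## Sliding-window box sum via cumulative sums with symmetric (reflective)
## padding; x padded by r on every side, window w = 2r + 1.
#' @noRd
.box_sum <- function(x, w) {
  r <- (w - 1L) %/% 2L
  n_r <- nrow(x); n_c <- ncol(x)
  pr <- c(rev(seq_len(r)), seq_len(n_r), n_r + 1L - seq_len(r))
  pc <- c(rev(seq_len(r)), seq_len(n_c), n_c + 1L - seq_len(r))
  xp <- x[pr, pc, drop = FALSE]
  cs <- apply(xp, 2L, cumsum)
  cs <- rbind(0, cs)
  v <- cs[(w + 1L):(n_r + w), , drop = FALSE] -
    cs[seq_len(n_r), , drop = FALSE]
  cs2 <- t(apply(v, 1L, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (w + 1L):(n_c + w), drop = FALSE] -
    cs2[, seq_len(n_c), drop = FALSE]
}

#' Local variance map of an image
#'
#' Unbiased sample variance in a square window, either per tile
#' (non-overlapping windows, result expanded block-constant to pixel
#' resolution) or per pixel (sliding window with reflective padding at the
#' borders).
#'
#' @param img numeric matrix or [raw_image()].
#' @param window window side in pixels; must be odd in sliding mode and no
#'   larger than either image dimension.
#' @param mode `"tiled"` (default, the validation-window convention) or
#'   `"sliding"`.
#' @param expand how tile-level values are brought back to pixel
#'   resolution in tiled mode: `"block"` (default, no interpolation) or
#'   `"bilinear"`.
#' @return numeric matrix of local variances, same shape as `img`.
#' @export
local_variance_map <- function(img, window = 64L,
                               mode = c("tiled", "sliding"),
                               expand = c("block", "bilinear")) {
  mode <- match.arg(mode)
  x <- .as_matrix(img, "img")
  .check_finite(x, "img")
  window <- as.integer(window)
  if (window > nrow(x) || window > ncol(x)) {
    stop("window larger than the image", call. = FALSE)
  }
  if (mode == "tiled") {
    tiles <- .tile_stat(x, window, stats::var)
    .expand_tiles(tiles, window, dim(x), match.arg(expand))
  } else {
    if (window %% 2L == 0L) {
      stop("sliding mode needs an odd window", call. = FALSE)
    }
    n <- window^2
    s1 <- .box_sum(x, window)
    s2 <- .box_sum(x * x, window)
    pmax((s2 - s1 * s1 / n) / (n - 1), 0)
  }
}

#' Target noise standard-deviation map
#'
#' Builds the per-pixel standard deviation of the noise the simulation
#' must add: the square root of the difference between the local variance
#' of the linearized target-dose flat and the local variance of the
#' linearized, alpha-scaled full-dose flat. Where sampling fluctuation
#' makes the difference negative it is clamped to zero and counted.
#'
#' @param h_sim_lin linearized flat(s) at the target (simulated) dose: a
#'   matrix or a list of matrices (variance maps are averaged across
#'   replicate flats).
#' @param h_o_lin_scaled linearized and alpha-scaled flat(s) at the full
#'   dose, same shape.
#' @param window,mode,expand passed to [local_variance_map()].
#' @return an object of class `sigma_map`: list with `sigma` (matrix),
#'   `window`, `mode`, `n_clamped` (number of clamped pixels).
#' @export
sigma_sim_map <- function(h_sim_lin, h_o_lin_scaled, window = 64L,
                          mode = c("tiled", "sliding"),
                          expand = c("block", "bilinear")) {
  mode <- match.arg(mode); expand <- match.arg(expand)
  as_list <- function(x) if (is.list(x) && !is.matrix(x)) x else list(x)
  hs <- lapply(as_list(h_sim_lin), .as_matrix, name = "h_sim_lin")
  ho <- lapply(as_list(h_o_lin_scaled), .as_matrix, name = "h_o_lin_scaled")
  for (m in c(hs[-1L], ho)) .check_same_shape(hs[[1L]], m,
                                              "h_sim_lin", "h_o_lin_scaled")
  avg_var <- function(lst) {
    Reduce(`+`, lapply(lst, local_variance_map, window = window,
                       mode = mode, expand = expand)) / length(lst)
  }
  v_sim <- avg_var(hs)
  v_os <- avg_var(ho)
  diff <- v_sim - v_os
  n_clamped <- sum(diff < 0)
  if (n_clamped > 0) {
    message(sprintf("sigma_sim_map: clamped %d negative variance pixels",
                    n_clamped))
  }
  structure(list(sigma = sqrt(pmax(diff, 0)), window = as.integer(window),
                 mode = mode, n_clamped = n_clamped),
            class = "sigma_map")
}

#' @export
print.sigma_map <- function(x, ...) {
  cat(sprintf(paste0("<sigma_map> %d x %d, window %d (%s), sigma in ",
                     "[%.4g, %.4g], %d clamped\n"),
              nrow(x$sigma), ncol(x$sigma), x$window, x$mode,
              min(x$sigma), max(x$sigma), x$n_clamped))
  invisible(x)
}

#' Generate the spatial noise mask
#'
#' Draws an i.i.d. standard Gaussian field and modulates it elementwise by
#' the target standard-deviation map, giving a zero-mean white noise field
#' whose local standard deviation follows `sig`.
#'
#' @param sig a `sigma_map` from [sigma_sim_map()], or a plain numeric
#'   matrix of standard deviations.
#' @param seed integer RNG seed; the mask is reproducible given the seed.
#' @return an object of class `noise_mask`: list with `values` (matrix)
#'   and `seed`.
#' @export
generate_noise_mask <- function(sig, seed = 1L) {
  s <- if (inherits(sig, "sigma_map")) sig$sigma else .as_matrix(sig, "sig")
  if (min(s) < 0) stop("sigma map must be nonnegative", call. = FALSE)
  set.seed(as.integer(seed))
  vals <- matrix(stats::rnorm(length(s)), nrow(s), ncol(s)) * s
  structure(list(values = vals, seed = as.integer(seed)),
            class = "noise_mask")
}

#' Embed a noise mask in the Anscombe domain
#'
#' A pure noise field has no signal, so the forward transform cannot be
#' applied to it directly. A positive DC level - the mean of the
#' linearized target-dose flat - is added first, the transform applied,
#' and the transformed DC level subtracted:
#' `N_A = A{N + h_sim_mean} - A{h_sim_mean}`. A zero mask maps exactly to
#' zero.
#'
#' By construction the DC level is the scalar image mean; a per-pixel
#' local mean field can be supplied instead via `dc` (a matrix), which
#' tracks field nonuniformity more closely but departs from the scalar
#' formulation.
#'
#' @param mask a `noise_mask` or numeric matrix (zero-mean noise values).
#' @param h_sim_mean positive scalar: mean pixel value of the linearized
#'   target-dose flat.
#' @param dc optional matrix of per-pixel DC levels overriding the scalar.
#' @return numeric matrix: the Anscombe-domain noise mask.
#' @export
embed_noise_anscombe <- function(mask, h_sim_mean, dc = NULL) {
  m <- if (inherits(mask, "noise_mask")) mask$values else
    .as_matrix(mask, "mask")
  if (!is.null(dc)) {
    dc <- .as_matrix(dc, "dc")
    .check_same_shape(m, dc, "mask", "dc")
    if (min(dc) <= 0) stop("dc levels must be > 0", call. = FALSE)
    return(anscombe_forward(m + dc) - anscombe_forward(dc))
  }
  if (!is.finite(h_sim_mean) || h_sim_mean <= 0) {
    stop("h_sim_mean must be > 0", call. = FALSE)
  }
  anscombe_forward(m + h_sim_mean) -
    2 * sqrt(h_sim_mean + 3 / 8)
}

#' Serialize a sigma map or noise mask to a text array
#'
#' Writes the field as a whitespace-delimited text matrix (full double
#' precision) for external inspection.
#'
#' @param x a `sigma_map`, `noise_mask`, or numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field <- function(x, path) {
  m <- if (inherits(x, "sigma_map")) x$sigma else
    if (inherits(x, "noise_mask")) x$values else .as_matrix(x, "x")
  write_raw_image(m, path)
}
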