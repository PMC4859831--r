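## End-to-end dose-reduction simulation:
##   Y_sim = A^-1( A{ alpha * (Y_o - theta) } + N_A ) + theta
## with N_A the Anscombe-domain embedding of the noise mask built from the
## flat-field exposures at the full and target doses.

#' Simulation recipe
#'
#' Collects the knobs of a dose-reduction simulation: the reduction rate,
#' the calibration (offset), the noise-estimation window, the RNG seed and
#' whether the output is quantized back to detector integers.
#'
#' @param alpha reduction rate in (0, 1] (mAs ratio simulated / full).
#' @param cal a `calibration_model` or a scalar detector offset theta.
#' @param window noise-estimation window side in pixels (default 64).
#' @param mode `"tiled"` (default) or `"sliding"` local variance
#'   estimation.
#' @param expand tile expansion, `"block"` (default) or `"bilinear"`.
#' @param seed RNG seed for the noise mask.
#' @param quantize round and clip the output to detector integers
#'   (default `FALSE`: keep floating point).
#' @param local_dc use a per-pixel local mean of the target-dose flat as
#'   the DC level of the Anscombe embedding instead of the scalar mean
#'   (default `FALSE`, the scalar formulation).
#' @return an object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(alpha, cal, window = 64L,
                              mode = c("tiled", "sliding"),
                              expand = c("block", "bilinear"),
                              seed = 1L, quantize = FALSE,
                              local_dc = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  if (!inherits(cal, "calibration_model")) cal <- calibration_model(cal)
  structure(list(alpha = alpha, cal = cal, window = as.integer(window),
                 mode = match.arg(mode), expand = match.arg(expand),
                 seed = as.integer(seed), quantize = isTRUE(quantize),
                 local_dc = isTRUE(local_dc)),
            class = "simulation_recipe")
}

#' @export
print.simulation_recipe <- function(x, ...) {
  cat(sprintf(paste0("<simulation_recipe> alpha %.4g, theta %.4g, window ",
                     "%d (%s/%s), seed %d, quantize %s\n"),
              x$alpha, x$cal$offset_theta, x$window, x$mode, x$expand,
              x$seed, x$quantize))
  invisible(x)
}

#' Simulate a reduced-dose acquisition
#'
#' Runs the full simulation chain on a standard-dose raw image:
#' \enumerate{
#'   \item linearize `y_o` and the flats against the detector offset
#'     theta;
#'   \item scale the linearized image and full-dose flat(s) by alpha;
#'   \item estimate the local noise std to add,
#'     `sigma_sim = sqrt(var[H_sim^L] - var[H_o^{L,S}])`;
#'   \item draw the zero-mean noise mask and embed it in the Anscombe
#'     domain against the target-dose flat mean;
#'   \item add the embedded mask to the Anscombe transform of the scaled
#'     image, apply the exact-unbiased inverse and restore theta.
#' }
#' Everything runs in floating point; quantization to detector integers is
#' applied (optionally) only at the very end.
#'
#' @param y_o full-dose clinical/phantom [raw_image()].
#' @param h_o flat-field [raw_image()] (or list of replicates) at the full
#'   dose.
#' @param h_sim flat-field [raw_image()] (or list) at the target dose.
#' @param recipe a [simulation_recipe()].
#' @return a [raw_image()] at the simulated dose; its `mas` is
#'   `alpha * y_o$mas` when known.
#' @examples
#' det <- detector_model(shape = c(512, 256))
#' y <- generate_flat(det, 160, seed = 1)
#' ho <- generate_flat(det, 160, seed = 2)
#' hs <- generate_flat(det, 80, seed = 3)
#' rec <- simulation_recipe(0.5, calibration_model(50), seed = 4)
#' ysim <- simulate_dose_reduction(y, ho, hs, rec)
#' @export
simulate_dose_reduction <- function(y_o, h_o, h_sim, recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  as_list <- function(x) if (is.list(x) && !inherits(x, "raw_image")) x else
    list(x)
  h_o <- as_list(h_o); h_sim <- as_list(h_sim)
  px_y <- .as_matrix(y_o, "y_o")
  for (h in c(h_o, h_sim)) {
    .check_same_shape(px_y, .as_matrix(h, "flat"), "y_o", "flat")
  }
  alpha <- recipe$alpha
  # refuse inconsistent dose metadata when it is present
  mas_of <- function(x) if (inherits(x, "raw_image")) x$mas else NA_real_
  mf <- mas_of(y_o); ms <- mas_of(h_sim[[1L]])
  if (!is.na(mf) && !is.na(ms) &&
      abs(ms / mf - alpha) > 1e-6 * max(1, alpha)) {
    stop(sprintf(paste0("dose metadata inconsistent with alpha: ",
                        "h_sim/y_o mAs ratio is %.6g but alpha = %.6g"),
                 ms / mf, alpha), call. = FALSE)
  }
  theta <- recipe$cal$offset_theta
  y_lin_s <- scale_to_dose(linearize(px_y, theta), alpha)
  hs_lin <- lapply(h_sim, function(h) linearize(.as_matrix(h, "h_sim"),
                                                theta))
  ho_lin_s <- lapply(h_o, function(h) {
    scale_to_dose(linearize(.as_matrix(h, "h_o"), theta), alpha)
  })
  sig <- sigma_sim_map(hs_lin, ho_lin_s, window = recipe$window,
                       mode = recipe$mode, expand = recipe$expand)
  mask <- generate_noise_mask(sig, seed = recipe$seed)
  hbar <- mean(vapply(hs_lin, mean, 0))
  n_a <- if (recipe$local_dc) {
    dc <- Reduce(`+`, lapply(hs_lin, function(h) {
      .expand_tiles(.tile_stat(h, recipe$window, mean), recipe$window,
                    dim(h), recipe$expand)
    })) / length(hs_lin)
    embed_noise_anscombe(mask, hbar, dc = pmax(dc, 1e-6))
  } else {
    embed_noise_anscombe(mask, hbar)
  }
  out <- anscombe_inverse_exact_unbiased(anscombe_forward(y_lin_s) + n_a) +
    theta
  bit_depth <- if (inherits(y_o, "raw_image")) y_o$bit_depth else 14L
  if (recipe$quantize) {
    out <- pmin(pmax(round(out), 0), 2^bit_depth - 1)
  } else {
    out <- pmin(pmax(out, 0), 2^bit_depth - 1)
  }
  raw_image(out, pixel_pitch_mm = if (inherits(y_o, "raw_image"))
              y_o$pixel_pitch_mm else 0.07,
            mas = if (!is.na(mf)) alpha * mf else NA_real_,
            bit_depth = bit_depth)
}
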