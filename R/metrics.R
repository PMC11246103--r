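#' Map a phase image onto the common 8-bit metric scale
#'
#' All image-quality metrics in this package are computed on a common
#' 8-bit-equivalent intensity scale: the interval
#' `[0, reference_max]` (radians) is mapped linearly onto `[0, 255]`
#' and values outside are clipped.  Using one `reference_max` — the
#' ground-truth peak phase — for both images makes the metrics
#' comparable across methods.
#'
#' @param phase A phase map / matrix.
#' @param reference_max Phase value mapped to 255 (> 0).
#' @param scale_max Top of the intensity scale (default 255).
#' @return Real matrix with values in `[0, scale_max]`.
#' @export
to_metric_scale <- function(phase, reference_max, scale_max = 255) {
  phi <- phase_values(phase)
  if (!is.finite(reference_max) || reference_max <= 0)
    stop("to_metric_scale: reference_max must be positive", call. = FALSE)
  pmin(pmax(phi / reference_max * scale_max, 0), scale_max)
}

check_same_shape <- function(a, b, what) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop(what, ": images must be matrices of identical shape", call. = FALSE)
}

#' Mean squared error between two images
#'
#' `MSE = mean((a - b)^2)` over all pixels.
#'
#' @param a,b Real matrices of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(a, b) {
  check_same_shape(a, b, "mse")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(scale_max^2 / MSE)` in decibels.  Identical images
#' (MSE of zero) return `Inf`.
#'
#' @param a,b Real matrices of identical shape.
#' @param scale_max Peak possible pixel value (255 on the metric scale).
#' @return PSNR in dB, `Inf` for identical images.
#' @export
psnr <- function(a, b, scale_max = 255) {
  e <- mse(a, b)
  if (e == 0) return(Inf)
  10 * log10(scale_max^2 / e)
}

#' Mean structural similarity index
#'
#' Local SSIM with an 11 x 11 Gaussian window (sigma 1.5) and stability
#' constants `C1 = (K1 * scale_max)^2`, `C2 = (K2 * scale_max)^2`:
#'
#'   `SSIM = (2 mu_a mu_b + C1)(2 cov_ab + C2) /
#'           ((mu_a^2 + mu_b^2 + C1)(var_a + var_b + C2))`
#'
#' computed per pixel from Gaussian-weighted local moments (symmetric
#' boundary).  The mean is taken after cropping a half-window border,
#' where the local statistics are boundary-dominated.  Values lie in
#' `[-1, 1]`; identical images give exactly 1.
#'
#' @param a,b Real matrices of identical shape on a common scale.
#' @param window Odd window size in pixels.
#' @param sigma Gaussian window width in pixels.
#' @param K1,K2 Stability fractions of the dynamic range.
#' @param scale_max Dynamic range of the scale (255).
#' @param map If `TRUE`, also return the local SSIM map.
#' @return Scalar MSSIM, or a list `(mssim, map)` when `map = TRUE`.
#' @export
mssim <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                  scale_max = 255, map = FALSE) {
  check_same_shape(a, b, "mssim")
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("mssim: window must be an odd integer >= 3", call. = FALSE)
  if (window > min(dim(a)))
    stop("mssim: image smaller than the SSIM window", call. = FALSE)
  r <- (window - 1L) %/% 2L
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  mu_a <- filter_sep(a, k); mu_b <- filter_sep(b, k)
  var_a <- filter_sep(a * a, k) - mu_a^2
  var_b <- filter_sep(b * b, k) - mu_b^2
  cov_ab <- filter_sep(a * b, k) - mu_a * mu_b
  C1 <- (K1 * scale_max)^2
  C2 <- (K2 * scale_max)^2
  S <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  inner <- S[(r + 1):(nrow(S) - r), (r + 1):(ncol(S) - r), drop = FALSE]
  if (map) list(mssim = mean(inner), map = S) else mean(inner)
}

#' Convert an unwrapped phase map to physical thickness
#'
#' For a specimen of refractive index `n_obj` in a medium of index
#' `n_med` under wavelength `lambda`, the optical thickness is
#' `t = phase * lambda / (2 * pi * (n_obj - n_med))`.
#'
#' @param unwrapped_phase Unwrapped phase map / matrix (radians).
#' @param wavelength Wavelength in meters.
#' @param n_obj,n_med Refractive indices of object and medium.
#' @return Thickness map in meters.
#' @export
phase_to_thickness <- function(unwrapped_phase, wavelength, n_obj, n_med) {
  if (n_obj == n_med)
    stop("phase_to_thickness: n_obj must differ from n_med", call. = FALSE)
  phase_values(unwrapped_phase) * wavelength / (2 * pi * (n_obj - n_med))
}

#' Evaluate a reconstruction against ground truth
#'
#' Maps the ground-truth phase and the reconstructed unwrapped phase to
#' the common `[0, 255]` scale (reference maximum = ground-truth peak)
#' and computes MSE, PSNR and MSSIM.
#'
#' @param reconstruction A [reconstruction_result()], [phase_map()] or
#'   matrix (unwrapped phase, radians).
#' @param ground_truth A [phase_object()], [phase_map()] or matrix.
#' @param ... Passed to [mssim()].
#' @return An object of class `metric_report`: a list with `mse`,
#'   `psnr`, `mssim`, `reference_max`, `scale_max`, `window`, `c1`,
#'   `c2`.
#' @export
evaluate_reconstruction <- function(reconstruction, ground_truth, ...) {
  rec <- if (inherits(reconstruction, "reconstruction_result"))
    reconstruction$phase_unwrapped else reconstruction
  gt <- phase_values(ground_truth)
  ref_max <- max(gt)
  a <- to_metric_scale(gt, ref_max)
  b <- to_metric_scale(rec, ref_max)
  e <- mse(a, b)
  structure(list(mse = e, psnr = psnr(a, b), mssim = mssim(a, b, ...),
                 reference_max = ref_max, scale_max = 255,
                 window = "11x11 Gaussian, sigma 1.5",
                 c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MSE %.4g | PSNR %.2f dB | MSSIM %.4f\n",
              x$mse, x$psnr, x$mssim))
  invisible(x)
}
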