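#' Sliding-window variance map of a phase image
#'
#' Local statistic used to separate genuine object phase structure from
#' the slowly varying twin-image background.  Over every centered
#' `m` by `m` window (symmetric boundary reflection at the edges) the
#' default `"as-printed"` mode computes
#'
#'   `V = mean[(phi^2 - mu)^2]`,  `mu = mean(phi)`,
#'
#' i.e. the mean squared deviation of the *squared* phase from the
#' window mean of the phase.  This is not the textbook variance (which
#' would square `phi - mu`); the `"standard"` mode computes the ordinary
#' local variance `mean(phi^2) - mu^2` instead.  Both are nonnegative
#' ridge detectors that light up at abrupt phase changes; the as-printed
#' form is the package default.
#'
#' @param phase A [phase_map()], [phase_object()] or matrix.
#' @param m Odd window size in pixels (>= 3).
#' @param mode `"as-printed"` or `"standard"`.
#' @return An object of class `variance_map` with fields `values`
#'   (nonnegative matrix), `window` and `mode`.
#' @export
variance_map <- function(phase, m = 5L, mode = c("as-printed", "standard")) {
  mode <- match.arg(mode)
  phi <- phase_values(phase)
  m <- as.integer(m)
  if (is.na(m) || m < 3L || m %% 2L == 0L)
    stop("variance_map: window m must be an odd integer >= 3", call. = FALSE)
  if (m > min(dim(phi)))
    stop("variance_map: window larger than the image", call. = FALSE)
  k <- box_kernel(m)
  mu <- filter_sep(phi, k)
  V <- if (mode == "as-printed") {
    # mean[(phi^2 - mu)^2] = mean(phi^4) - 2 mu mean(phi^2) + mu^2
    m2 <- filter_sep(phi^2, k)
    m4 <- filter_sep(phi^4, k)
    m4 - 2 * mu * m2 + mu^2
  } else {
    filter_sep(phi^2, k) - mu^2
  }
  structure(list(values = pmax(V, 0), window = m, mode = mode),
            class = "variance_map")
}

#' Threshold a variance map into a binary support mask
#'
#' The twin-image suppressor: pixels whose local variance strictly
#' exceeds the threshold `tau` form the support.  In the default
#' `"variance-max"` mode `tau = fraction * max(V)`; the `"phase-max"`
#' mode sets `tau = fraction * max(phase)` (a literal percentage of the
#' peak phase value), which requires passing the phase map.  Ties at
#' exactly `tau` fall outside the support.
#'
#' @param vmap A [variance_map()].
#' @param phase Phase map used by `"phase-max"` mode (ignored otherwise).
#' @param fraction Threshold fraction in (0, 1); default 0.5.
#' @param mode `"variance-max"` or `"phase-max"`.
#' @return An object of class `support_mask` with binary `values`, the
#'   threshold `tau`, `fraction` and `mode`.
#' @export
threshold_mask <- function(vmap, phase = NULL, fraction = 0.5,
                           mode = c("variance-max", "phase-max")) {
  mode <- match.arg(mode)
  V <- if (inherits(vmap, "variance_map")) vmap$values else vmap
  stopifnot(is.matrix(V))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("threshold_mask: fraction must lie in (0, 1)", call. = FALSE)
  tau <- if (mode == "variance-max") {
    fraction * max(V)
  } else {
    if (is.null(phase))
      stop("threshold_mask: phase-max mode needs the phase map", call. = FALSE)
    fraction * max(phase_values(phase))
  }
  structure(list(values = (V > tau) * 1, tau = tau,
                 fraction = fraction, mode = mode),
            class = "support_mask")
}

#' Apply a support mask to a phase map
#'
#' Pointwise product of the phase with the binary mask, followed by an
#' optional Gaussian blur to soften the mask edges and suppress noise.
#' In the default `"value"` domain the blur acts on the phase values
#' directly (normalized kernel, symmetric boundary, so the blurred
#' total equals the masked total).  For *wrapped* phase maps that
#' contain 2-pi discontinuities, value-domain blurring averages across
#' the wrap and corrupts the map; the `"phasor"` domain blurs the real
#' and imaginary parts of `exp(i * phase)` instead and takes the
#' argument, which is invariant to wrapping.
#'
#' @param phase A [phase_map()] (or matrix).
#' @param mask A [support_mask()] (or binary matrix).
#' @param blur_sigma Blur width in pixels; 0 disables the blur.
#' @param blur_domain `"value"` or `"phasor"`.
#' @return A [phase_map()] with the wrapped flag of the input.
#' @export
apply_support <- function(phase, mask, blur_sigma = 1,
                          blur_domain = c("value", "phasor")) {
  blur_domain <- match.arg(blur_domain)
  phi <- phase_values(phase)
  mv <- if (inherits(mask, "support_mask")) mask$values else mask
  if (!all(dim(phi) == dim(mv)))
    stop("apply_support: phase/mask shape mismatch", call. = FALSE)
  out <- phi * mv
  if (blur_sigma > 0) {
    out <- if (blur_domain == "value") {
      gaussian_blur(out, blur_sigma)
    } else {
      z <- gaussian_blur(cos(out), blur_sigma) +
        1i * gaussian_blur(sin(out), blur_sigma)
      z[Mod(z) == 0] <- 1 + 0i
      Arg(z)
    }
  }
  phase_map(out, wrapped = if (inherits(phase, "phase_map"))
    phase$wrapped else TRUE)
}
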