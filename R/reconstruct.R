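#' Reconstruction result
#'
#' Container returned by every reconstruction method: the complex object
#' field, its wrapped and unwrapped phase, the amplitude, the method
#' identifier and the full parameter record needed to replay the run.
#'
#' @param field A [complex_field()] at the object plane.
#' @param method Method identifier (`"asm"`, `"itpr"`, `"pcof"`).
#' @param params Named list of all parameters of the run.
#' @param stages Optional named list of intermediate stage outputs.
#' @return An object of class `reconstruction_result` with fields
#'   `field`, `phase` (wrapped), `phase_unwrapped`, `amplitude`,
#'   `method`, `params` and (optionally) `stages`.
#' @export
reconstruction_result <- function(field, method, params = list(),
                                  stages = NULL) {
  stopifnot(inherits(field, "complex_field"))
  res <- list(field = field,
              phase = extract_phase(field),
              phase_unwrapped = unwrap_phase(extract_phase(field)),
              amplitude = Mod(field$values),
              method = method,
              params = params)
  if (!is.null(stages)) res$stages <- stages
  structure(res, class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> method '%s', %d x %d px, peak phase %.4g rad\n",
    x$method, nrow(x$amplitude), ncol(x$amplitude),
    max(x$phase_unwrapped$values)))
  invisible(x)
}

# Linear rescale of the recorded intensity to mean 1.  A purely linear
# preprocessing step: it normalizes exposure without distorting any
# phase structure.
preprocess_hologram <- function(holo) {
  m <- mean(holo$intensity)
  if (m <= 0) return(holo)
  hologram(holo$intensity / m, holo$grid, holo$z_record)
}

# Back-propagate detector data by z and remove the plane-wave carrier
# (the on-axis phase 2*pi*z/lambda picked up by the backward kernel), so
# that an empty field reconstructs to exactly zero phase.
backpropagate_demod <- function(values, grid, z, plane_z = 0) {
  f <- complex_field(values, grid, plane_z = plane_z)
  b <- propagate(f, prop_config(z, "backward"))
  complex_field(b$values * exp(2i * pi * z / grid$wavelength), grid,
                plane_z = b$plane_z)
}

#' Conventional angular-spectrum reconstruction
#'
#' Single back-propagation of the (linearly rescaled) hologram to the
#' object plane, Gabor's direct reconstruction.  The twin image is NOT
#' suppressed: its defocused conjugate overlays the phase map as ringing
#' around each object.
#'
#' @param holo A [hologram()].
#' @param z Reconstruction distance in meters (>= 0); defaults to the
#'   recording distance stored in the hologram.
#' @return A [reconstruction_result()] with `method = "asm"`.
#' @export
reconstruct_asm <- function(holo, z = holo$z_record) {
  stopifnot(inherits(holo, "hologram"))
  if (!is.finite(z) || z < 0)
    stop("reconstruct_asm: z must be >= 0", call. = FALSE)
  Ipp <- preprocess_hologram(holo)
  obj <- backpropagate_demod(Ipp$intensity + 0i, holo$grid, z)
  reconstruction_result(obj, method = "asm",
                        params = list(z = z, grid = holo$grid))
}

#' Suppress the DC term of a hologram by reference-beam normalization
#'
#' Divides the recorded intensity by the squared modulus of the
#' reference beam, suppressing the non-diffracted zero-order component.
#' The reference modulus is floored at `floor_frac` of its maximum
#' before division so the quotient stays finite.
#'
#' @param holo A [hologram()].
#' @param ref Complex matrix of reference-beam values, or `NULL` for the
#'   unit plane wave (division is then the identity).
#' @param floor_frac Relative modulus floor.
#' @return A [hologram()].
#' @export
dc_filter <- function(holo, ref = NULL, floor_frac = 1e-6) {
  stopifnot(inherits(holo, "hologram"))
  if (is.null(ref)) return(holo)
  amp <- Mod(as_complex_matrix(ref))
  amp <- pmax(amp, floor_frac * max(amp))
  hologram(holo$intensity / amp^2, holo$grid, holo$z_record)
}

#' Estimate the reference beam from a recorded hologram
#'
#' For experimental holograms with an uneven illumination envelope: the
#' reference amplitude is estimated as a Gaussian low-pass of the square
#' root of the intensity, which retains the slow source profile and
#' discards the interference fringes.
#'
#' @param holo A [hologram()].
#' @param sigma Low-pass width in pixels.
#' @return Complex matrix usable as `ref` in [dc_filter()].
#' @export
estimate_reference <- function(holo, sigma = 20) {
  stopifnot(inherits(holo, "hologram"))
  gaussian_blur(sqrt(holo$intensity), sigma) + 0i
}

#' Recombine a filtered hologram with phase-only information
#'
#' Pointwise product of the real filtered hologram record with the
#' unit-modulus phase factor of the forward-propagated field: the
#' output keeps the measured values as its modulus and the synthesized
#' phase as its argument.  `use = "amplitude"` (the physically exact
#' choice, and the pipeline default) takes the square root of the
#' filtered intensity, so that a perfect phase model reproduces the
#' detector field `|U| exp(i arg U) = U` identically; `use =
#' "intensity"` multiplies the intensity record itself.
#'
#' @param filtered A [hologram()] (the DC-filtered record).
#' @param forward_field A [complex_field()] at the detector plane.
#' @param use `"amplitude"` or `"intensity"`.
#' @return A [complex_field()] at the detector plane.
#' @export
recombine <- function(filtered, forward_field,
                      use = c("amplitude", "intensity")) {
  stopifnot(inherits(filtered, "hologram"),
            inherits(forward_field, "complex_field"))
  use <- match.arg(use)
  if (!all(dim(filtered$intensity) == dim(forward_field$values)))
    stop("recombine: shape mismatch", call. = FALSE)
  modulus <- if (use == "amplitude") sqrt(filtered$intensity)
             else filtered$intensity
  complex_field(modulus * exp(1i * Arg(forward_field$values)),
                forward_field$grid, forward_field$plane_z)
}

#' PCOF parameters
#'
#' Tunables of the phase-support constrained phase-only reconstruction.
#'
#' @param window Odd sliding-window size for the variance map (pixels).
#' @param threshold_fraction Mask threshold fraction in (0, 1).
#' @param threshold_mode `"variance-max"` or `"phase-max"`, see
#'   [threshold_mask()].
#' @param blur_sigma Gaussian blur width applied to the masked phase
#'   (pixels); 0 disables.
#' @param variance_mode `"as-printed"` or `"standard"`, see
#'   [variance_map()].
#' @param reference Reference beam for [dc_filter()] (`NULL` = unit
#'   plane wave).
#' @param recombine `"amplitude"` (default) or `"intensity"`, see
#'   [recombine()].
#' @param mask_override Optional binary matrix (or [threshold_mask()]
#'   output) replacing the computed support mask, e.g. a user-supplied
#'   support.
#' @return A named list of class `pcof_params`.
#' @export
pcof_params <- function(window = 5L, threshold_fraction = 0.5,
                        threshold_mode = "phase-max", blur_sigma = 1,
                        variance_mode = "as-printed", reference = NULL,
                        recombine = c("amplitude", "intensity"),
                        mask_override = NULL) {
  structure(list(window = window, threshold_fraction = threshold_fraction,
                 threshold_mode = threshold_mode, blur_sigma = blur_sigma,
                 variance_mode = variance_mode, reference = reference,
                 recombine = match.arg(recombine),
                 mask_override = mask_override),
            class = "pcof_params")
}

#' PCOF reconstruction: phase-support constraint on a phase-only function
#'
#' Single-pass twin-image elimination from one in-line hologram.  The
#' pipeline runs, with no iteration:
#'
#' 1. linear rescale of the recorded hologram, back-propagation by `z`
#'    and extraction of the wrapped phase (which still carries the twin
#'    image);
#' 2. sliding-window variance map of that phase, thresholding into a
#'    binary support mask, masking of the phase and Gaussian blur;
#' 3. phase-only object constraint `exp(i * phase)` and forward
#'    propagation back to the detector plane;
#' 4. DC filtering of the recorded hologram, recombination of its
#'    (real) values with the phase of the forward-propagated field, and
#'    a final back-propagation giving the object field, whose unwrapped
#'    phase is the reconstruction.
#'
#' Exactly four FFT pairs are executed; cost is O(N log N).
#'
#' @param holo A [hologram()].
#' @param z Reconstruction distance in meters (> 0); defaults to the
#'   recording distance.
#' @param params A [pcof_params()] record.
#' @param keep_stages If `TRUE`, intermediate stage outputs (initial
#'   phase, variance map, mask, constrained phase) are attached to the
#'   result for inspection.
#' @return A [reconstruction_result()] with `method = "pcof"`.
#' @export
pcof_reconstruct <- function(holo, z = holo$z_record, params = pcof_params(),
                             keep_stages = FALSE) {
  stopifnot(inherits(holo, "hologram"), inherits(params, "pcof_params"))
  if (!is.finite(z) || z <= 0)
    stop("pcof_reconstruct: z must be a positive distance", call. = FALSE)
  grid <- holo$grid

  # Step 1: back-propagate and take the twin-image-laden initial phase
  Ipp <- preprocess_hologram(holo)
  Us <- backpropagate_demod(Ipp$intensity + 0i, grid, z)
  phi0 <- extract_phase(Us)

  # Step 2: variance-map segmentation and support constraint
  if (is.null(params$mask_override)) {
    vmap <- variance_map(phi0, m = params$window, mode = params$variance_mode)
    mask <- threshold_mask(vmap, phase = phi0,
                           fraction = params$threshold_fraction,
                           mode = params$threshold_mode)
  } else {
    vmap <- NULL
    mask <- params$mask_override
  }
  # the initial phase is wrapped, so the smoothing acts in the phasor
  # domain, which is invariant to the 2*pi wrap
  phi <- apply_support(phi0, mask, blur_sigma = params$blur_sigma,
                       blur_domain = "phasor")

  # Step 3: phase-only object, forward propagation to the detector
  Uc <- complex_field(exp(1i * phi$values), grid, plane_z = 0)
  Uo <- propagate(Uc, prop_config(z, "forward"))

  # Step 4: DC filter, recombine, final back-propagation
  filtered <- dc_filter(Ipp, ref = params$reference)
  Inew <- recombine(filtered, Uo, use = params$recombine)
  # carriers of the forward and backward kernels cancel here, so no
  # demodulation is needed
  Uobj <- propagate(Inew, prop_config(z, "backward"))

  reconstruction_result(
    Uobj, method = "pcof",
    params = c(list(z = z), unclass(params)[setdiff(names(params),
                                                    "mask_override")]),
    stages = if (keep_stages)
      list(initial_phase = phi0, variance = vmap, mask = mask,
           constrained_phase = phi))
}

#' Iterative phase retrieval baseline (Gerchberg-Saxton type)
#'
#' Alternating projections between the detector-plane amplitude set (the
#' modulus must match the square root of the recorded intensity) and the
#' object-plane physicality constraint (`|t| <= 1`: a passive specimen
#' cannot amplify the illumination, so reconstructed transmission
#' moduli above one are renormalized to one with the phase kept).  Both
#' steps are exact nearest-point projections — the no-gain set is
#' convex — so the detector-plane amplitude residual is non-increasing;
#' non-convergence is reported through the residual history, never
#' raised.
#'
#' @param holo A [hologram()].
#' @param z Reconstruction distance in meters (> 0).
#' @param n_iter Number of iterations (>= 1); 30 is the conventional
#'   budget for this baseline.
#' @return A [reconstruction_result()] with `method = "itpr"`; the
#'   per-iteration RMS amplitude residuals are in
#'   `params$residuals`.
#' @export
itpr_reconstruct <- function(holo, z = holo$z_record, n_iter = 30L) {
  stopifnot(inherits(holo, "hologram"))
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L)
    stop("itpr_reconstruct: n_iter must be >= 1", call. = FALSE)
  if (!is.finite(z) || z <= 0)
    stop("itpr_reconstruct: z must be a positive distance", call. = FALSE)
  grid <- holo$grid
  amp <- sqrt(preprocess_hologram(holo)$intensity)
  Ud <- amp + 0i                      # initial phase of zeros
  residuals <- numeric(n_iter)
  # carrier factor of the forward kernel; both propagation legs are
  # demodulated by it so the iteration alternates in one fixed frame
  carrier <- exp(2i * pi * z / grid$wavelength)
  for (k in seq_len(n_iter)) {
    Uo <- backpropagate_demod(Ud, grid, z)
    Uc <- project_no_gain(Uo$values)
    Udp <- propagate(complex_field(Uc, grid, 0), prop_config(z, "forward"))
    Udp_vals <- Udp$values / carrier
    residuals[k] <- sqrt(mean((Mod(Udp_vals) - amp)^2))
    Ud <- amp * exp(1i * Arg(Udp_vals))
  }
  obj <- backpropagate_demod(Ud, grid, z)
  reconstruction_result(obj, method = "itpr",
                        params = list(z = z, n_iter = n_iter,
                                      residuals = residuals))
}

# Exact projection onto the no-gain transmission set {|t| <= 1}:
# moduli above one are scaled down to the unit circle, phases kept.
project_no_gain <- function(values) {
  m <- Mod(values)
  over <- m > 1
  values[over] <- values[over] / m[over]
  values
}
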