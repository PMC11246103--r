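#' Propagation configuration
#'
#' Describes one free-space propagation step: an axial distance `z` and a
#' direction.  `"backward"` propagates from the detector toward the
#' object (the reconstruction direction, kernel evaluated at `-z`);
#' `"forward"` propagates from the object toward the detector.
#'
#' @param z Propagation distance in meters (nonnegative; the direction
#'   carries the sign).
#' @param direction `"backward"` or `"forward"`.
#' @return An object of class `prop_config`.
#' @export
prop_config <- function(z, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  if (!is.finite(z)) stop("prop_config: z must be finite", call. = FALSE)
  structure(list(z = z, direction = direction), class = "prop_config")
}

signed_z <- function(cfg) if (cfg$direction == "backward") -cfg$z else cfg$z

#' Angular-spectrum transfer function
#'
#' The exact scalar free-space kernel
#' `H(fx, fy) = exp(i (2*pi/lambda) z sqrt(1 - (lambda fx)^2 - (lambda fy)^2))`
#' on the propagating band.  Evanescent frequencies, where
#' `(lambda fx)^2 + (lambda fy)^2 > 1`, are hard-zeroed: they decay
#' exponentially in forward propagation and would blow up exponentially
#' under backward propagation, so the kernel suppresses them outright.
#'
#' @param freq A [frequency_grid()].
#' @param cfg A [prop_config()]; backward direction evaluates the kernel
#'   at `-z`.
#' @param wavelength Wavelength in meters; defaults to the grid's.
#' @return Complex matrix of kernel values, FFT-ordered like `freq`.
#' @export
angular_spectrum_tf <- function(freq, cfg, wavelength = freq$grid$wavelength) {
  stopifnot(inherits(freq, "frequency_grid"), inherits(cfg, "prop_config"))
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("angular_spectrum_tf: wavelength must be positive", call. = FALSE)
  z <- signed_z(cfg)
  arg <- 1 - (wavelength * freq$fx)^2 - (wavelength * freq$fy)^2
  prop <- arg >= 0
  H <- matrix(0 + 0i, nrow = nrow(arg), ncol = ncol(arg))
  H[prop] <- exp((2i * pi / wavelength) * z * sqrt(arg[prop]))
  H
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Propagate a complex wavefield through free space
#'
#' Applies the angular-spectrum method: FFT, multiplication by the
#' transfer function of [angular_spectrum_tf()], inverse FFT.  The FFT
#' pair is the stats convention (negative-exponent forward transform,
#' `1/N` on the inverse).  No zero-padding is applied by default; an
#' optional integer `pad` factor embeds the field in a `pad`-times larger
#' zero frame to guard against wrap-around at large distances.
#'
#' @param field A [complex_field()].
#' @param cfg A [prop_config()].
#' @param pad Integer padding factor (1 = off).
#' @return A [complex_field()] at the new plane.
#' @export
propagate <- function(field, cfg, pad = 1L) {
  stopifnot(inherits(field, "complex_field"), inherits(cfg, "prop_config"))
  pad <- as.integer(pad)
  g <- field$grid
  v <- field$values
  if (pad > 1L) {
    big <- grid_spec(g$nx * pad, g$ny * pad, g$pitch, g$wavelength)
    vb <- matrix(0 + 0i, big$ny, big$nx)
    r0 <- (big$ny - g$ny) %/% 2L
    c0 <- (big$nx - g$nx) %/% 2L
    vb[r0 + seq_len(g$ny), c0 + seq_len(g$nx)] <- v
    H <- angular_spectrum_tf(frequency_grid(big), cfg)
    out <- ifft2(fft2(vb) * H)[r0 + seq_len(g$ny), c0 + seq_len(g$nx)]
  } else {
    H <- angular_spectrum_tf(frequency_grid(g), cfg)
    if (!all(dim(H) == dim(v)))
      stop("propagate: transfer function / field shape mismatch", call. = FALSE)
    out <- ifft2(fft2(v) * H)
  }
  complex_field(out, g, plane_z = field$plane_z + signed_z(cfg))
}

#' Phase map
#'
#' A 2D real map of phase values in radians.  Wrapped maps lie in
#' `(-pi, pi]`; unwrapped maps are unconstrained.
#'
#' @param values Real matrix of phase values (radians).
#' @param wrapped Logical flag.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(values, wrapped = TRUE) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(list(values = values, wrapped = isTRUE(wrapped)),
            class = "phase_map")
}

phase_values <- function(x) {
  if (inherits(x, "phase_map")) x$values
  else if (inherits(x, "phase_object")) x$phase
  else if (is.matrix(x)) x
  else stop("expected a phase_map, phase_object or matrix", call. = FALSE)
}

#' Extract the wrapped phase of a wavefield
#'
#' Per-pixel four-quadrant arctangent `atan2(Im, Re)` in `(-pi, pi]`.
#' Zero-modulus pixels carry no phase information and are assigned 0
#' rather than propagating a NaN.
#'
#' @param field A [complex_field()] (or complex matrix).
#' @return A wrapped [phase_map()].
#' @export
extract_phase <- function(field) {
  v <- as_complex_matrix(field)
  p <- Arg(v)
  p[Mod(v) == 0] <- 0
  phase_map(p, wrapped = TRUE)
}

#' Reduce a wavefield to its phase-only function
#'
#' Returns `exp(i * arg(field))`: unit modulus everywhere, phase
#' preserved.  Zero-modulus pixels map to `1 + 0i` by convention.
#'
#' @param field A [complex_field()].
#' @return A [complex_field()] with `|values| == 1` at every pixel.
#' @export
phase_only <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  v <- field$values
  out <- exp(1i * Arg(v))
  out[Mod(v) == 0] <- 1 + 0i
  complex_field(out, field$grid, field$plane_z)
}
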