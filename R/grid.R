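#' Sampling grid for a digital holography experiment
#'
#' A `grid_spec` fixes the uniform sampling used by every wavefield in a
#' reconstruction: pixel counts, detector pixel pitch and illumination
#' wavelength.  The defaults correspond to a lensless detector-plane
#' geometry with a 1.55 micron CMOS pitch under 525 nm LED illumination.
#'
#' @param nx,ny Number of pixels along x (columns) and y (rows).  Both
#'   must be at least 8 (the smallest window the test oracles use).
#' @param pitch Pixel size in meters (center-to-center).
#' @param wavelength Illumination wavelength in meters.
#' @return An object of class `grid_spec` with fields `nx`, `ny`,
#'   `pitch`, `wavelength`.
#' @examples
#' g <- grid_spec(256, 256, pitch = 1.55e-6, wavelength = 525e-9)
#' @export
grid_spec <- function(nx, ny = nx, pitch = 1.55e-6, wavelength = 525e-9) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 8L || ny < 8L)
    stop("grid_spec: nx and ny must be integers >= 8", call. = FALSE)
  if (!is.finite(pitch) || pitch <= 0)
    stop("grid_spec: pitch must be a positive length in meters", call. = FALSE)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("grid_spec: wavelength must be a positive length in meters",
         call. = FALSE)
  structure(list(nx = nx, ny = ny, pitch = pitch, wavelength = wavelength),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, pitch %.3g um, lambda %.4g nm\n",
              x$nx, x$ny, x$pitch * 1e6, x$wavelength * 1e9))
  invisible(x)
}

# DFT sample frequencies in cycles/meter, FFT ordering (DC first).
fft_freq <- function(n, pitch) {
  k <- 0L:(n - 1L)
  neg <- k >= (n + 1L) %/% 2L
  k[neg] <- k[neg] - n
  k / (n * pitch)
}

#' Spatial-frequency grid matching a sampling grid
#'
#' Returns the 2D spatial frequencies (cycles/meter) of the discrete
#' Fourier transform of a field sampled on `grid`, in FFT ordering: the
#' DC component sits at matrix index `[1, 1]` and the frequencies span
#' plus/minus the Nyquist rate `1/(2*pitch)`.
#'
#' @param grid A [grid_spec()].
#' @return An object of class `frequency_grid` with matrices `fx`, `fy`
#'   (dimensions `ny` by `nx`) and the originating `grid`.
#' @export
frequency_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  fxv <- fft_freq(grid$nx, grid$pitch)
  fyv <- fft_freq(grid$ny, grid$pitch)
  structure(list(
    fx = matrix(fxv, nrow = grid$ny, ncol = grid$nx, byrow = TRUE),
    fy = matrix(fyv, nrow = grid$ny, ncol = grid$nx),
    grid = grid
  ), class = "frequency_grid")
}

#' Complex wavefield on a sampling grid
#'
#' The currency of all propagation steps: a 2D complex array plus the
#' grid it is sampled on and its axial position.
#'
#' @param values Complex (or real, promoted) matrix of dimensions
#'   `ny` by `nx`.
#' @param grid A [grid_spec()].
#' @param plane_z Axial position of the sampling plane in meters.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, grid, plane_z = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as_complex_matrix(values)
  if (nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop("complex_field: values must be ny x nx for the given grid",
         call. = FALSE)
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("complex_field: values must be finite", call. = FALSE)
  structure(list(values = values, grid = grid, plane_z = plane_z),
            class = "complex_field")
}

as_complex_matrix <- function(x) {
  if (inherits(x, "complex_field")) return(x$values)
  if (!is.matrix(x)) stop("expected a matrix", call. = FALSE)
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at z = %.4g mm\n",
              x$grid$ny, x$grid$nx, x$plane_z * 1e3))
  invisible(x)
}
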