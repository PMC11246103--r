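#' In-line hologram
#'
#' Nonnegative real intensity recorded at the detector plane, plus the
#' sampling grid and the recording distance.
#'
#' @param intensity Real matrix (`ny` by `nx`), nonnegative.
#' @param grid A [grid_spec()].
#' @param z_record Object-to-detector distance in meters.
#' @return An object of class `hologram`.
#' @export
hologram <- function(intensity, grid, z_record) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(intensity))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("hologram: intensity must be finite and nonnegative", call. = FALSE)
  if (nrow(intensity) != grid$ny || ncol(intensity) != grid$nx)
    stop("hologram: intensity must be ny x nx", call. = FALSE)
  structure(list(intensity = intensity, grid = grid, z_record = z_record),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, z = %.4g mm, mean intensity %.4g\n",
              x$grid$ny, x$grid$nx, x$z_record * 1e3, mean(x$intensity)))
  invisible(x)
}

#' Render the in-line hologram of a pure-phase object
#'
#' Simulates Gabor (in-line) recording: a unit-amplitude plane wave
#' illuminates the object, whose transmission is `t = exp(i * phase)`;
#' the transmitted field is propagated forward by `z` with the angular
#' spectrum method and the detector records `|field|^2`.
#'
#' @param obj A [phase_object()].
#' @param z Recording distance in meters (> 0).
#' @param pad Optional propagation padding factor, see [propagate()].
#' @return A [hologram()].
#' @export
render_hologram <- function(obj, z, pad = 1L) {
  stopifnot(inherits(obj, "phase_object"))
  if (!is.finite(z) || z <= 0)
    stop("render_hologram: z must be a positive distance", call. = FALSE)
  tfield <- complex_field(exp(1i * obj$phase), obj$grid, plane_z = 0)
  det <- propagate(tfield, prop_config(z, "forward"), pad = pad)
  hologram(Mod(det$values)^2, obj$grid, z_record = z)
}

#' Add detector noise to a hologram
#'
#' `"gaussian"` adds zero-mean Gaussian noise of standard deviation
#' `level` (intensity units); `"poisson"` draws shot noise with `level`
#' expected photons per unit intensity and rescales back.  Output is
#' clipped at zero.
#'
#' @param holo A [hologram()].
#' @param model `"gaussian"` or `"poisson"`.
#' @param level Noise level (>= 0); 0 returns the input unchanged.
#' @param seed Integer seed.
#' @return A [hologram()].
#' @export
add_noise <- function(holo, model = c("gaussian", "poisson"), level,
                      seed = 1L) {
  stopifnot(inherits(holo, "hologram"))
  model <- match.arg(model)
  if (!is.finite(level) || level < 0)
    stop("add_noise: level must be >= 0", call. = FALSE)
  if (level == 0) return(holo)
  I <- holo$intensity
  noisy <- with_seed(seed, switch(model,
    gaussian = I + matrix(stats::rnorm(length(I), sd = level),
                          nrow(I), ncol(I)),
    poisson  = matrix(stats::rpois(length(I), lambda = I * level) / level,
                      nrow(I), ncol(I))
  ))
  hologram(pmax(noisy, 0), holo$grid, holo$z_record)
}
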