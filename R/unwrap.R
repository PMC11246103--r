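#' Two-dimensional phase unwrapping
#'
#' Recovers a continuous phase surface from values wrapped into
#' `(-pi, pi]` by adding integer multiples of `2*pi` per pixel.  The
#' algorithm is reliability-sorted region merging: pixels are scored by
#' wrapped second differences, neighbour edges are processed in order of
#' decreasing joint reliability, and groups of pixels are merged with
#' the period offset that makes the shared edge continuous.  The most
#' reliable (smoothest) regions are therefore unwrapped first and noisy
#' pixels join last, which confines unwrapping errors to low-quality
#' areas.
#'
#' The result is normalized so the image median lies within `(-pi, pi]`
#' (the background of a mostly-empty field keeps its wrapped value).
#' By construction `output - input` is an exact integer multiple of
#' `2*pi` at every pixel, whichever algorithm details change.
#'
#' @param phase A wrapped [phase_map()] or matrix.
#' @return An unwrapped [phase_map()] (`wrapped = FALSE`).
#' @export
unwrap_phase <- function(phase) {
  phi <- phase_values(phase)
  out <- .unwrap2d(phi)
  out <- out - 2 * pi * round(stats::median(out) / (2 * pi))
  phase_map(out, wrapped = FALSE)
}
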