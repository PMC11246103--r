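#' Pure-phase specimen
#'
#' Ground-truth phase map (radians, nonnegative) of a simulated
#' pure-phase object on a sampling grid.
#'
#' @param phase Real matrix (`ny` by `nx`) of phase delays in radians.
#' @param grid A [grid_spec()].
#' @param ground_truth_max Peak phase of the design, in radians.
#' @return An object of class `phase_object`.
#' @export
phase_object <- function(phase, grid, ground_truth_max = max(phase)) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(phase))
  if (any(!is.finite(phase)))
    stop("phase_object: phase must be finite", call. = FALSE)
  if (nrow(phase) != grid$ny || ncol(phase) != grid$nx)
    stop("phase_object: phase must be ny x nx", call. = FALSE)
  structure(list(phase = phase, grid = grid,
                 ground_truth_max = ground_truth_max),
            class = "phase_object")
}

#' @export
print.phase_object <- function(x, ...) {
  cat(sprintf("<phase_object> %d x %d px, peak %.4g rad, %.2f%% coverage\n",
              x$grid$ny, x$grid$nx, x$ground_truth_max,
              100 * mean(x$phase > 0)))
  invisible(x)
}

#' Specification of a microsphere bead phantom
#'
#' @param n_beads Number of beads to place.
#' @param diameter Bead diameter in meters.
#' @param peak_phase Phase delay at bead center, radians.
#' @param profile `"spherical-cap"` (phase falls off as the chord length
#'   of a sphere, reaching `peak_phase` only at the center) or
#'   `"top-hat"` (uniform `peak_phase` over the disc).
#' @param seed Integer seed for reproducible placement.
#' @param min_separation Minimum center-to-center distance in meters;
#'   defaults to one diameter (beads touch at most).
#' @return An object of class `bead_phantom_spec`.
#' @export
bead_phantom_spec <- function(n_beads = 150L, diameter = 30e-6,
                              peak_phase = 2 * pi,
                              profile = c("spherical-cap", "top-hat"),
                              seed = 1L, min_separation = diameter) {
  profile <- match.arg(profile)
  if (!is.finite(diameter) || diameter <= 0)
    stop("bead_phantom_spec: diameter must be positive", call. = FALSE)
  n_beads <- as.integer(n_beads)
  if (is.na(n_beads) || n_beads < 0L)
    stop("bead_phantom_spec: n_beads must be >= 0", call. = FALSE)
  structure(list(n_beads = n_beads, diameter = diameter,
                 peak_phase = peak_phase, profile = profile,
                 seed = as.integer(seed), min_separation = min_separation),
            class = "bead_phantom_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a microsphere bead phantom
#'
#' Places `n_beads` non-overlapping beads uniformly at random (rejection
#' sampling, bounded retries) with centers snapped to pixel positions, so
#' the design peak phase is attained exactly at each bead center.  The
#' spherical-cap profile is
#' `phi(r) = peak_phase * sqrt(1 - (2 r / d)^2)` inside radius `d/2`.
#'
#' @param spec A [bead_phantom_spec()].
#' @param grid A [grid_spec()].
#' @param max_tries Total rejection-sampling attempts before giving up.
#' @return A [phase_object()].
#' @export
make_bead_phantom <- function(spec, grid, max_tries = 1e4) {
  stopifnot(inherits(spec, "bead_phantom_spec"), inherits(grid, "grid_spec"))
  rp <- spec$diameter / 2 / grid$pitch       # bead radius in pixels
  # minimum center distance in pixels, plus a one-pixel rasterization
  # guard so that touching discs stay 4-disconnected on the pixel grid
  sep <- spec$min_separation / grid$pitch + 1
  phase <- matrix(0, grid$ny, grid$nx)
  if (spec$n_beads == 0L)
    return(phase_object(phase, grid, ground_truth_max = 0))
  if (2 * rp + 2 > min(grid$nx, grid$ny))
    stop("make_bead_phantom: bead does not fit in the field of view",
         call. = FALSE)
  centers <- with_seed(spec$seed, {
    cx <- numeric(0); cy <- numeric(0); tries <- 0L
    while (length(cx) < spec$n_beads && tries < max_tries) {
      tries <- tries + 1L
      x <- sample(ceiling(rp + 1):floor(grid$nx - rp), 1L)
      y <- sample(ceiling(rp + 1):floor(grid$ny - rp), 1L)
      if (length(cx) == 0L || min((cx - x)^2 + (cy - y)^2) >= sep^2) {
        cx <- c(cx, x); cy <- c(cy, y)
      }
    }
    if (length(cx) < spec$n_beads)
      stop("make_bead_phantom: could not place ", spec$n_beads,
           " beads without overlap after ", max_tries, " attempts",
           call. = FALSE)
    cbind(cx, cy)
  })
  ri <- ceiling(rp)
  for (b in seq_len(nrow(centers))) {
    x0 <- centers[b, 1]; y0 <- centers[b, 2]
    cols <- max(1L, x0 - ri):min(grid$nx, x0 + ri)
    rows <- max(1L, y0 - ri):min(grid$ny, y0 + ri)
    r2 <- outer((rows - y0)^2, (cols - x0)^2, `+`)
    u <- 1 - r2 / rp^2
    bead <- if (spec$profile == "spherical-cap") {
      spec$peak_phase * sqrt(pmax(u, 0))
    } else {
      spec$peak_phase * (u > 0)
    }
    phase[rows, cols] <- pmax(phase[rows, cols], bead)
  }
  phase_object(phase, grid, ground_truth_max = spec$peak_phase)
}

#' Generate an Archimedean-spiral extended phantom
#'
#' A non-centrosymmetric ribbon of constant phase on a zero background:
#' the set of pixels within `arm_width/2` of the curve
#' `r = a * theta`, `theta` in `[0, 2*pi*turns]`, with `a` chosen so the
#' spiral fills `fill` of the half-field.
#'
#' @param grid A [grid_spec()].
#' @param peak_phase Ribbon phase in radians.  The default is `pi/2`: a
#'   ribbon at exactly `pi` would make the ground truth unidentifiable,
#'   since a pure-phase transmission cannot distinguish a `+pi` step
#'   from a `-pi` step (`exp(i*pi) == exp(-i*pi)`).
#' @param turns Number of spiral turns (0 gives an empty phantom).
#' @param arm_width Ribbon width in pixels (>= 2).
#' @param fill Fraction of the half-field spanned by the outer turn.
#' @return A [phase_object()] with values in `{0, peak_phase}`.
#' @export
make_spiral_phantom <- function(grid, peak_phase = pi / 2, turns = 3,
                                arm_width = 8, fill = 0.8) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(turns) || turns < 0)
    stop("make_spiral_phantom: turns must be >= 0", call. = FALSE)
  if (arm_width < 2)
    stop("make_spiral_phantom: arm_width must be >= 2 pixels", call. = FALSE)
  phase <- matrix(0, grid$ny, grid$nx)
  if (turns == 0)
    return(phase_object(phase, grid, ground_truth_max = 0))
  cx <- (grid$nx + 1) / 2
  cy <- (grid$ny + 1) / 2
  x <- matrix(seq_len(grid$nx) - cx, grid$ny, grid$nx, byrow = TRUE)
  y <- matrix(seq_len(grid$ny) - cy, grid$ny, grid$nx)
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) %% (2 * pi)
  a <- fill * min(grid$nx, grid$ny) / 2 / (2 * pi * turns)
  k <- round((r / a - theta) / (2 * pi))
  s <- theta + 2 * pi * k                 # arc parameter of nearest arm
  hit <- abs(r - a * s) <= arm_width / 2 & s >= 0 & s <= 2 * pi * turns
  phase[hit] <- peak_phase
  phase_object(phase, grid, ground_truth_max = peak_phase)
}

#' Generate a glyph phantom
#'
#' A built-in binary stencil scaled by `peak_phase`.  The only glyph
#' shipped is `"psi"`: a vertical stem flanked by a U-shaped cup, the
#' classic test object for step-phase reconstruction.
#'
#' @param grid A [grid_spec()].
#' @param glyph Glyph name; only `"psi"` is available.
#' @param peak_phase Phase of the stencil in radians.
#' @return A [phase_object()] with values in `{0, peak_phase}`.
#' @export
make_glyph_phantom <- function(grid, glyph = "psi", peak_phase = pi) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(glyph, "psi"))
    stop("make_glyph_phantom: unknown glyph '", glyph, "'", call. = FALSE)
  # normalized coordinates in [-1, 1], y up
  x <- matrix(seq(-1, 1, length.out = grid$nx), grid$ny, grid$nx, byrow = TRUE)
  y <- matrix(seq(1, -1, length.out = grid$ny), grid$ny, grid$nx)
  t <- 0.07   # stroke half-width
  R <- 0.45   # cup radius
  stem <- abs(x) <= t & y >= -0.75 & y <= 0.6
  r <- sqrt(x^2 + y^2)
  cup_arc <- abs(r - R) <= t & y <= 0 & y >= -0.75
  cup_sides <- (abs(x - R) <= t | abs(x + R) <= t) & y >= 0 & y <= 0.6
  base <- abs(y + 0.75) <= t & abs(x) <= 0.25
  stencil <- stem | cup_arc | cup_sides | base
  phase_object(stencil * peak_phase, grid,
               ground_truth_max = if (any(stencil)) peak_phase else 0)
}
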