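# Independent oracles used by the tests.  All of these deliberately
# avoid the package's FFT/filtering code paths.

# Dense DFT matrices: W[k, j] = exp(-2*pi*i*k*j/n), unnormalized forward,
# 1/n on the inverse — the same convention as stats::fft, evaluated by
# plain matrix products.
dft_matrix <- function(n, inverse = FALSE) {
  s <- if (inverse) 2i else -2i
  outer(0:(n - 1), 0:(n - 1), function(k, j) exp(s * pi * k * j / n))
}

dft2_direct <- function(x) dft_matrix(nrow(x)) %*% x %*% dft_matrix(ncol(x))

idft2_direct <- function(x)
  (dft_matrix(nrow(x), TRUE) %*% x %*% dft_matrix(ncol(x), TRUE)) / length(x)

# Direct evaluation of the angular-spectrum diagonal operator.
propagate_direct <- function(values, grid, cfg) {
  H <- angular_spectrum_tf(frequency_grid(grid), cfg)
  idft2_direct(dft2_direct(values) * H)
}

# 4-connected component count by explicit BFS flood fill.
count_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  todo <- mask > 0
  count <- 0L
  while (any(todo)) {
    count <- count + 1L
    frontier <- which(todo)[1]
    todo[frontier] <- FALSE
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[i > 1L] - 1L, frontier[i < nr] + 1L,
              frontier[j > 1L] - nr, frontier[j < nc] + nr)
      nb <- unique(nb[todo[nb]])
      todo[nb] <- FALSE
      frontier <- nb
    }
  }
  count
}

# Itoh's 1D unwrapping: integrate wrapped first differences.
itoh_unwrap_1d <- function(v) {
  d <- diff(v)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(v[1], d))
}

# Direct windowed evaluation of the as-printed local statistic
# V = mean[(phi^2 - mean(phi))^2] with symmetric edge padding.
variance_direct <- function(phi, m, mode = "as-printed") {
  r <- (m - 1) %/% 2
  idx <- function(k, n) {  # symmetric (edge-including) reflection
    k <- ifelse(k < 1L, 1L - k, k)
    ifelse(k > n, 2L * n + 1L - k, k)
  }
  out <- matrix(0, nrow(phi), ncol(phi))
  for (i in seq_len(nrow(phi))) for (j in seq_len(ncol(phi))) {
    w <- phi[idx(i + (-r:r), nrow(phi)), idx(j + (-r:r), ncol(phi))]
    mu <- mean(w)
    out[i, j] <- if (mode == "as-printed") mean((w^2 - mu)^2)
                 else mean(w^2) - mu^2
  }
  out
}

# Small grid whose whole frequency band propagates (pitch >> lambda),
# so random fields are band-limited by construction.
test_grid <- function(n = 32, pitch = 1.55e-6, wavelength = 525e-9)
  grid_spec(n, n, pitch, wavelength)

random_field <- function(grid, seed = 1) {
  set.seed(seed)
  complex_field(matrix(complex(real = rnorm(grid$nx * grid$ny),
                               imaginary = rnorm(grid$nx * grid$ny)),
                       grid$ny, grid$nx), grid)
}

rel_err <- function(a, b) max(Mod(a - b)) / max(Mod(b))
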