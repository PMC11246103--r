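test_that("frequency grids follow the DFT sampling convention", {
  expect_equal(pcof:::fft_freq(4, 1), c(0, 0.25, -0.5, -0.25))
  expect_equal(pcof:::fft_freq(2, 0.5), c(0, -1))
  fg <- frequency_grid(grid_spec(32, 16, pitch = 2e-6))
  expect_identical(fg$fx[1, 1], 0)
  expect_identical(fg$fy[1, 1], 0)
  expect_equal(dim(fg$fx), c(16L, 32L))
  expect_equal(max(abs(fg$fx)), 1 / (2 * 2e-6))
  expect_error(grid_spec(32, 32, pitch = 0), "pitch")
})

test_that("angular-spectrum kernel: unit modulus on the band, zero beyond", {
  g <- test_grid(32)
  fg <- frequency_grid(g)
  expect_equal(angular_spectrum_tf(fg, prop_config(0, "forward")),
               matrix(1 + 0i, 32, 32))
  z <- 1e-3
  H <- angular_spectrum_tf(fg, prop_config(z, "forward"))
  expect_equal(H[1, 1], exp(2i * pi * z / g$wavelength))
  expect_equal(Mod(H), matrix(1, 32, 32), tolerance = 1e-12)
  # a coarse wavelength-scale grid has an evanescent corner
  ge <- grid_spec(16, 16, pitch = 300e-9, wavelength = 525e-9)
  fe <- frequency_grid(ge)
  He <- angular_spectrum_tf(fe, prop_config(z, "forward"))
  ev <- (ge$wavelength * fe$fx)^2 + (ge$wavelength * fe$fy)^2 > 1
  expect_true(any(ev))
  expect_true(all(He[ev] == 0))
  expect_equal(Mod(He[!ev]), rep(1, sum(!ev)), tolerance = 1e-12)
  # backward direction conjugates the forward kernel on the band
  Hb <- angular_spectrum_tf(fg, prop_config(z, "backward"))
  expect_equal(Hb, Conj(H), tolerance = 1e-12)
})

test_that("propagation is the identity at z = 0 and invertible in z", {
  g <- test_grid(32)
  f <- random_field(g)
  expect_lt(rel_err(propagate(f, prop_config(0, "forward"))$values,
                    f$values), 1e-10)
  roundtrip <- propagate(propagate(f, prop_config(2e-3, "forward")),
                         prop_config(2e-3, "backward"))
  expect_lt(rel_err(roundtrip$values, f$values), 1e-8)
  expect_equal(roundtrip$plane_z, 0)
})

test_that("a uniform field stays uniform with unit modulus", {
  g <- test_grid(16)
  f <- complex_field(matrix(1 + 0i, 16, 16), g)
  out <- propagate(f, prop_config(5e-4, "forward"))
  expect_equal(Mod(out$values), matrix(1, 16, 16), tolerance = 1e-12)
  expect_lt(max(Mod(out$values - mean(out$values))), 1e-10)
})

test_that("propagation conserves energy for band-limited fields", {
  for (seed in 1:5) {
    g <- test_grid(32)
    f <- random_field(g, seed)
    out <- propagate(f, prop_config(1e-3, "forward"))
    expect_equal(sum(Mod(out$values)^2), sum(Mod(f$values)^2),
                 tolerance = 1e-6)
  }
})

test_that("FFT propagation matches the dense DFT oracle on an 8x8 grid", {
  g <- test_grid(8)
  f <- random_field(g, 7)
  cfg <- prop_config(1e-3, "backward")
  expect_lt(rel_err(propagate(f, cfg)$values,
                    propagate_direct(f$values, g, cfg)), 1e-10)
})

test_that("phase extraction is the four-quadrant arctangent", {
  g <- test_grid(16)
  one <- matrix(1 + 0i, 16, 16)
  expect_equal(extract_phase(complex_field(one, g))$values,
               matrix(0, 16, 16))
  expect_equal(extract_phase(complex_field(1i * one, g))$values,
               matrix(pi / 2, 16, 16))
  expect_equal(extract_phase(complex_field((-1 - 1i) * one, g))$values,
               matrix(-3 * pi / 4, 16, 16))
  z <- one; z[3, 4] <- 0 + 0i
  p <- extract_phase(complex_field(z, g))
  expect_identical(p$values[3, 4], 0)
  expect_true(p$wrapped)
})

test_that("phase-only reduction has unit modulus everywhere", {
  g <- test_grid(16)
  f <- random_field(g, 3)
  f$values[2, 2] <- 0 + 0i
  po <- phase_only(f)
  expect_equal(Mod(po$values), matrix(1, 16, 16), tolerance = 1e-14)
  expect_identical(po$values[2, 2], 1 + 0i)
  v <- matrix(3 * exp(1i * pi / 4), 16, 16)
  expect_equal(phase_only(complex_field(v, g))$values,
               matrix(exp(1i * pi / 4), 16, 16), tolerance = 1e-14)
})
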