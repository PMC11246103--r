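holo_of <- function(obj, z = 1e-3) render_hologram(obj, z)

test_that("ASM reconstruction of an empty field is exactly empty", {
  g <- grid_spec(64, 64, 1.55e-6, 525e-9)
  h <- holo_of(phase_object(matrix(0, 64, 64), g))
  r <- reconstruct_asm(h)
  expect_lt(max(abs(r$phase$values)), 1e-6)
  # z = 0: the phase of a real nonnegative intensity image is zero
  r0 <- reconstruct_asm(h, z = 0)
  expect_true(all(r0$phase$values == 0))
  expect_error(reconstruct_asm(h, z = -1), ">= 0")
})

test_that("ASM localizes a bead at its true position", {
  g <- grid_spec(256, 256, 1.55e-6, 525e-9)
  obj <- make_bead_phantom(bead_phantom_spec(n_beads = 1, seed = 6), g)
  h <- holo_of(obj)
  r <- reconstruct_asm(h)
  truth_c <- which(obj$phase == max(obj$phase), arr.ind = TRUE)[1, ]
  w <- r$phase_unwrapped$values
  sel <- w > 0.5 * max(w)
  rec_c <- c(mean(row(w)[sel]), mean(col(w)[sel]))
  expect_lt(max(abs(rec_c - truth_c)), 1)
})

test_that("DC filtering divides by the squared reference modulus", {
  g <- grid_spec(32, 32, 1.55e-6, 525e-9)
  h <- hologram(matrix(2, 32, 32), g, 1e-3)
  expect_identical(dc_filter(h), h)
  ref2 <- matrix(2 + 0i, 32, 32)
  expect_equal(dc_filter(h, ref2)$intensity, matrix(0.5, 32, 32))
  # flooring keeps the quotient finite for vanishing references
  ref0 <- matrix(1 + 0i, 32, 32); ref0[1, 1] <- 0
  expect_true(all(is.finite(dc_filter(h, ref0)$intensity)))
  est <- estimate_reference(h, sigma = 3)
  expect_equal(Mod(est), matrix(sqrt(2), 32, 32), tolerance = 1e-9)
})

test_that("recombination keeps the record as modulus, the field as phase", {
  g <- grid_spec(32, 32, 1.55e-6, 525e-9)
  rec <- matrix(runif(32 * 32) + 0.5, 32, 32)
  h <- hologram(rec, g, 1e-3)
  set.seed(2)
  ph <- matrix(runif(32 * 32, -pi, pi), 32, 32)
  fwd <- complex_field((1 + rec) * exp(1i * ph), g, 1e-3)
  out_i <- recombine(h, fwd, use = "intensity")
  expect_equal(Mod(out_i$values), rec, tolerance = 1e-12)
  expect_equal(Arg(out_i$values), ph, tolerance = 1e-12)
  out_a <- recombine(h, fwd, use = "amplitude")
  expect_equal(Mod(out_a$values), sqrt(rec), tolerance = 1e-12)
  # real-positive forward field contributes zero phase
  fwd1 <- complex_field(matrix(2 + 0i, 32, 32), g, 1e-3)
  expect_equal(recombine(h, fwd1, use = "intensity")$values, rec + 0i,
               tolerance = 1e-12)
})

test_that("PCOF on an empty hologram reconstructs zero phase", {
  g <- grid_spec(64, 64, 1.55e-6, 525e-9)
  h <- holo_of(phase_object(matrix(0, 64, 64), g))
  r <- pcof_reconstruct(h)
  expect_lt(max(abs(r$phase_unwrapped$values)), 1e-3)
  expect_error(pcof_reconstruct(h, z = 0), "positive")
})

test_that("an all-ones support with no blur leaves the phase untouched", {
  g <- grid_spec(128, 128, 1.55e-6, 525e-9)
  obj <- make_bead_phantom(
    bead_phantom_spec(n_beads = 2, seed = 5, peak_phase = 1), g)
  h <- holo_of(obj)
  r <- pcof_reconstruct(
    h, params = pcof_params(mask_override = matrix(1, 128, 128),
                            blur_sigma = 0),
    keep_stages = TRUE)
  expect_identical(r$stages$constrained_phase$values,
                   r$stages$initial_phase$values)
})

test_that("PCOF is the single pass it claims to be", {
  # the parameter record of a reconstruction carries no iteration count
  g <- grid_spec(64, 64, 1.55e-6, 525e-9)
  h <- holo_of(make_bead_phantom(
    bead_phantom_spec(n_beads = 1, seed = 2, diameter = 20e-6), g))
  r <- pcof_reconstruct(h)
  expect_false("n_iter" %in% names(r$params))
  expect_identical(r$method, "pcof")
  expect_equal(r$amplitude, Mod(r$field$values))
})

test_that("PCOF suppresses background ringing relative to ASM", {
  g <- grid_spec(512, 512, 1.55e-6, 525e-9)
  obj <- make_bead_phantom(bead_phantom_spec(n_beads = 15, seed = 3), g)
  h <- holo_of(obj)
  bg <- gaussian_blur((obj$phase > 0) * 1, 8) <= 1e-3
  sd_asm <- sd(reconstruct_asm(h)$phase_unwrapped$values[bg])
  sd_pcof <- sd(pcof_reconstruct(h)$phase_unwrapped$values[bg])
  expect_lt(sd_pcof, sd_asm)
})

test_that("one ItPR iteration equals the hand-composed projection pair", {
  g <- grid_spec(128, 128, 1.55e-6, 525e-9)
  obj <- make_bead_phantom(bead_phantom_spec(n_beads = 2, seed = 7), g)
  h <- holo_of(obj)
  z <- h$z_record
  r1 <- itpr_reconstruct(h, n_iter = 1)
  # manual composition of the two stages
  amp <- sqrt(h$intensity / mean(h$intensity))
  carrier <- exp(2i * pi * z / g$wavelength)
  back <- function(v) propagate(complex_field(v, g), prop_config(z, "backward"))$values * carrier
  fwd <- function(v) propagate(complex_field(v, g), prop_config(z, "forward"))$values / carrier
  Uo <- back(amp + 0i)
  m <- Mod(Uo); Uc <- ifelse(m > 1, Uo / m, Uo)
  Ud <- amp * exp(1i * Arg(fwd(Uc)))
  expect_lt(rel_err(r1$field$values, back(Ud)), 1e-10)
})

test_that("ItPR residuals vanish on empty data and never increase", {
  g <- grid_spec(64, 64, 1.55e-6, 525e-9)
  h0 <- holo_of(phase_object(matrix(0, 64, 64), g))
  r0 <- itpr_reconstruct(h0, n_iter = 3)
  expect_lt(r0$params$residuals[1], 1e-10)

  g2 <- grid_spec(256, 256, 1.55e-6, 525e-9)
  obj <- make_bead_phantom(bead_phantom_spec(n_beads = 5, seed = 9), g2)
  r <- itpr_reconstruct(holo_of(obj), n_iter = 20)
  expect_true(all(diff(r$params$residuals) <= 1e-8))
  expect_error(itpr_reconstruct(holo_of(obj), n_iter = 0), "n_iter")
})
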