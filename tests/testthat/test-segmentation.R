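test_that("as-printed window statistic reproduces the worked 5x5 example", {
  phi <- matrix(0, 5, 5); phi[3, 3] <- 1
  V <- variance_map(phi, m = 5)
  # center window: mu = 1/25, V = (1/25) [24 (0 - 1/25)^2 + (1 - 1/25)^2]
  expect_equal(V$values[3, 3], 0.038400, tolerance = 1e-12)
  expect_equal(V$values, variance_direct(phi, 5), tolerance = 1e-12)
})

test_that("window statistics match direct evaluation and are nonnegative", {
  set.seed(5)
  phi <- matrix(rnorm(15 * 12), 15, 12)
  for (mode in c("as-printed", "standard")) {
    V <- variance_map(phi, m = 3, mode = mode)
    expect_equal(V$values, variance_direct(phi, 3, mode), tolerance = 1e-10)
    expect_true(all(V$values >= 0))
  }
  # constants: the as-printed statistic is (c^2 - c)^2, zero only at 0;
  # the standard variance vanishes for every constant
  expect_equal(variance_map(matrix(2, 8, 8), 3)$values,
               matrix(4, 8, 8), tolerance = 1e-12)
  expect_true(all(variance_map(matrix(0, 8, 8), 3)$values == 0))
  expect_lt(max(variance_map(matrix(2, 8, 8), 3, "standard")$values), 1e-12)
  expect_error(variance_map(phi, m = 4), "odd")
  expect_error(variance_map(phi, m = 21), "larger")
})

test_that("thresholding yields a strict, binary, idempotent mask", {
  V <- matrix(c(0.1, 0.6, 0.9), 3, 3)
  m <- threshold_mask(V, fraction = 0.45)
  expect_equal(m$values[, 1], c(0, 1, 1))
  expect_true(all(m$values %in% c(0, 1)))
  # uniform positive map: tau = fraction * max falls below every value
  expect_true(all(threshold_mask(matrix(2, 4, 4))$values == 1))
  expect_true(all(threshold_mask(matrix(0, 4, 4))$values == 0))
  # ties at exactly tau fall outside (strict inequality)
  tie <- matrix(c(1, 2), 4, 4)
  expect_equal(sort(unique(as.vector(
    threshold_mask(tie, fraction = 0.5)$values))), c(0, 1))
  expect_true(all(threshold_mask(tie, fraction = 0.5)$values[tie == 1] == 0))
  # masking a mask changes nothing
  m2 <- threshold_mask(m$values)
  expect_identical(m2$values, m$values)
  # phase-max mode takes the threshold from the phase map
  phi <- matrix(1.2, 3, 3)
  mp <- threshold_mask(V, phase = phi, mode = "phase-max")
  expect_equal(mp$tau, 0.6)
  expect_equal(mp$values[, 1], c(0, 0, 1))
  expect_error(threshold_mask(V, mode = "phase-max"), "phase")
  expect_error(threshold_mask(V, fraction = 1.2), "fraction")
})

test_that("support application masks, blurs and conserves totals", {
  set.seed(8)
  phi <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  expect_identical(apply_support(phi, matrix(1, 32, 32), 0)$values, phi)
  expect_true(all(apply_support(phi, matrix(0, 32, 32), 1)$values == 0))
  blurred <- apply_support(phi, mask, blur_sigma = 1.5)
  expect_equal(sum(blurred$values), sum(phi * mask), tolerance = 1e-6)
  expect_error(apply_support(phi, matrix(1, 8, 8)), "mismatch")
})

test_that("phasor-domain blur does not average across the 2*pi wrap", {
  # two half-planes at -pi+0.1 and pi-0.1: on the circle they are only
  # 0.2 rad apart, but their values differ by almost 2*pi
  phi <- cbind(matrix(-pi + 0.1, 16, 8), matrix(pi - 0.1, 16, 8))
  ones <- matrix(1, 16, 16)
  val <- apply_support(phi, ones, blur_sigma = 1, blur_domain = "value")
  pha <- apply_support(phi, ones, blur_sigma = 1, blur_domain = "phasor")
  mid <- abs(col(phi) - 8.5) < 1
  expect_lt(min(abs(val$values[mid])), 2)  # value blur pulled toward zero
  expect_gt(min(abs(pha$values[mid])), 3)  # phasor blur stays near +-pi
  expect_true(all(pha$values > -pi & pha$values <= pi))
})
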