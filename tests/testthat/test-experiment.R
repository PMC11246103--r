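small_cfg <- function(dir, ...) {
  experiment_config(modifyList(list(
    optics = list(nx = 128L, ny = 128L, pitch = 1.55e-6,
                  wavelength = 525e-9, z = 1e-3),
    phantom = list(type = "beads", n_beads = 4L, diameter = 20e-6),
    itpr = list(n_iter = 3L),
    seed = 5L,
    out_dir = dir), list(...)))
}

test_that("configurations validate methods and phantom types", {
  cfg <- experiment_config(list())
  expect_equal(cfg$optics$nx, 1024L)
  expect_equal(cfg$methods, c("asm", "itpr", "pcof"))
  expect_equal(cfg$pcof$threshold_fraction, 0.5)
  expect_error(experiment_config(list(methods = c("asm", "wavelet"))),
               "wavelet")
  expect_error(experiment_config(list(phantom = list(type = "donut"))),
               "donut")
})

test_that("simulate -> reconstruct -> evaluate round-trips on disk", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(dir)
  paths <- cmd_simulate(cfg)
  expect_true(file.exists(paths$hologram))
  expect_true(file.exists(paths$ground_truth))
  res <- cmd_reconstruct(cfg)
  expect_named(res, c("asm", "itpr", "pcof"))
  for (m in cfg$methods)
    expect_true(file.exists(file.path(dir, paste0("phase_", m, ".tif"))))
  expect_true(file.exists(file.path(dir, "run_record.json")))
  rec <- jsonlite::read_json(file.path(dir, "run_record.json"))
  expect_equal(rec$config$itpr$n_iter, 3L)

  tab <- cmd_evaluate(cfg)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$method, c("asm", "itpr", "pcof"))
  # per-row PSNR/MSE consistency on the 255 scale
  expect_equal(tab$psnr, 10 * log10(255^2 / tab$mse), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
})

test_that("simulation outputs are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cmd_simulate(small_cfg(d1))
  cmd_simulate(small_cfg(d2))
  for (f in c("hologram.tif", "ground_truth.tif"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("evaluation degrades gracefully without ground truth", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(dir, methods = "asm")
  cmd_simulate(cfg)
  file.remove(file.path(dir, "ground_truth.tif"))
  cmd_reconstruct(cfg)
  expect_message(out <- cmd_evaluate(cfg), "experimental mode")
  expect_null(out)
})

test_that("reconstruction requires the hologram and its calibration", {
  dir <- withr::local_tempdir()
  expect_error(cmd_reconstruct(small_cfg(dir)), "not found")
  cfg <- small_cfg(dir)
  cmd_simulate(cfg)
  file.remove(file.path(dir, "hologram.tif.yaml"))
  expect_error(cmd_reconstruct(cfg), "sidecar")
})

test_that("the comparison driver emits per-seed and aggregate rows", {
  g <- grid_spec(128, 128, 1.55e-6, 525e-9)
  tab <- reproduce_table1(seeds = 1:2, grid = g, n_beads = 3L,
                          diameter = 20e-6, itpr_n_iter = 2L,
                          quiet = TRUE)
  expect_equal(nrow(tab), 3 * 2 + 3 * 2)   # seed rows + mean/sd rows
  expect_equal(sum(tab$stat == "seed"), 6L)
  expect_equal(sum(tab$stat == "mean"), 3L)
  tab2 <- reproduce_table1(seeds = 1:2, grid = g, n_beads = 3L,
                           diameter = 20e-6, itpr_n_iter = 2L,
                           quiet = TRUE)
  expect_identical(tab, tab2)
})
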