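test_that("analytic surface kinds match their closed forms", {
  hm <- generate_surface(surface_spec("constant", n_px = 16, amplitude_um = 0.3))
  expect_true(all(hm$z == 0.3))

  a <- 0.05
  hm <- generate_surface(surface_spec("plane", n_px = 16, amplitude_um = a))
  x0 <- matrix(rep(0:15, each = 16), 16, 16)
  expect_identical(hm$z, a * x0)

  hm <- generate_surface(surface_spec("sine", n_px = 64, amplitude_um = 0.2,
                                      wavelength_px = 16))
  expect_equal(hm$z[1, ], 0.2 * sin(2 * pi * (0:63) / 16))
  expect_equal(hm$z[1, ], hm$z[30, ])  # ridge constant along y
})

test_that("generation is seed-deterministic and metadata is consistent", {
  spec <- surface_spec("phantom_rough", n_px = 64, scan_size_um = 50, seed = 9)
  a <- generate_surface(spec)
  b <- generate_surface(spec)
  expect_identical(a$z, b$z)
  expect_equal(a$pixel_size_um, 50 / 64)

  spec2 <- surface_spec("phantom_rough", n_px = 64, seed = 10)
  expect_false(identical(generate_surface(spec2)$z, a$z))
})

test_that("invalid surface specs name the offending field", {
  expect_error(surface_spec("plane", n_px = 4), "n_px")
  expect_error(surface_spec("fbm", hurst = 1.2), "hurst")
  expect_error(surface_spec("fbm"), "hurst")
  expect_error(surface_spec("plane", scan_size_um = -1), "scan_size_um")
  expect_error(surface_spec("nonsense"))
})

test_that("fbm surfaces carry the requested spectral Hurst exponent", {
  est <- vapply(1:3, function(s) {
    hm <- generate_surface(surface_spec("fbm", n_px = 256, hurst = 0.5,
                                        seed = s))
    estimate_hurst_psd(hm)$hurst
  }, numeric(1))
  expect_true(all(abs(est - 0.5) < 0.1))
  hm <- generate_surface(surface_spec("fbm", n_px = 256, hurst = 0.8, seed = 1))
  expect_lt(abs(estimate_hurst_psd(hm)$hurst - 0.8), 0.1)
})

test_that("cohorts have the requested composition, ids and determinism", {
  spec <- surface_spec("phantom_rough", n_px = 32)
  co <- generate_cohort(11, 7, spec, seed = 1)
  expect_equal(nrow(co), 18)
  expect_equal(sum(co$label == "metastatic"), 11)
  expect_equal(co$sample_id[1:5], c("m1.1", "m1.2", "m1.3", "m1.4", "m2.1"))
  expect_equal(co$sample_id[12], "nm1.1")

  co2 <- generate_cohort(1, 1, spec, seed = 4)
  co3 <- generate_cohort(1, 1, spec, seed = 4)
  expect_identical(co2$map[[1]]$z, co3$map[[1]]$z)
  expect_identical(co2$map[[2]]$z, co3$map[[2]]$z)

  expect_error(generate_cohort(0, 3, spec, seed = 1), ">= 1")
})

test_that("phantom classes share large-scale relief but differ in fine texture", {
  n <- 128
  rough <- generate_surface(surface_spec("phantom_rough", n_px = n, seed = 5))
  smooth <- generate_surface(surface_spec("phantom_smooth", n_px = n, seed = 5))
  fs <- filter_spec(sigma_um = 1, pixel_size_um = rough$pixel_size_um)
  lo_r <- gaussian_smooth(rough, fs)$z
  lo_s <- gaussian_smooth(smooth, fs)$z
  # same seed -> same relief realization underneath
  expect_gt(stats::cor(as.vector(lo_r), as.vector(lo_s)), 0.99)
  expect_lt(abs(sd(lo_r) - sd(lo_s)) / sd(lo_r), 0.05)
  # fine-scale residual RMS differs by about the contrast factor
  hi_r <- sd(gaussian_residual(rough, fs)$z)
  hi_s <- sd(gaussian_residual(smooth, fs)$z)
  expect_gt(hi_r / hi_s, 1.5)
})

test_that("rough cohorts carry higher residual sills than smooth ones", {
  co <- generate_cohort(5, 5, surface_spec("phantom_rough", n_px = 128),
                        seed = 2)
  sills <- cohort_sills(co, vario_config(q_list = 1, baselines = FALSE))
  m <- tapply(sills$sill, sills$label, mean)
  expect_gt(m[["non_metastatic"]], m[["metastatic"]])
})
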