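test_that("surface statistics match closed forms and a direct oracle", {
  const <- heightmap(matrix(0.3, 16, 16), scan_size_um = 10)
  ss <- surface_stats(const)
  expect_equal(ss$mean_z, 0.3)
  expect_equal(ss$rms_roughness, 0)

  two <- heightmap(matrix(rep(c(0, 1), 128), 16, 16), scan_size_um = 10)
  ss <- surface_stats(two)
  expect_equal(ss$mean_z, 0.5)
  expect_equal(ss$rms_roughness, 0.5)
  expect_equal(ss$z_skewness, 0)

  hm <- generate_surface(surface_spec("phantom_rough", n_px = 32, seed = 5))
  ss <- surface_stats(hm)
  z <- as.vector(hm$z)
  expect_lt(abs(ss$z_skewness -
                  mean((z - mean(z))^3) / mean((z - mean(z))^2)^1.5), 1e-12)
  expect_equal(ss$z_min, min(z))
  expect_equal(ss$z_max, max(z))

  ph <- heightmap(hm$z, scan_size_um = 50, channel = "phase")
  expect_equal(surface_stats(ph)$channel, "phase")
})

test_that("R/S recovers the known exponents of reference series", {
  set.seed(101)
  h_white <- vapply(1:3, function(s) hurst_rescaled_range(rnorm(32768))$H,
                    numeric(1))
  expect_true(all(abs(h_white - 0.5) < 0.07))

  ramp <- hurst_rescaled_range(seq_len(4096) + rnorm(4096, sd = 1e-3))
  expect_gte(ramp$H, 0.9)

  fit <- hurst_rescaled_range(rnorm(4096))
  expect_gte(length(fit$window_sizes), 4)
  expect_error(hurst_rescaled_range(rep(1, 4096)), "usable")
  expect_error(hurst_rescaled_range(rnorm(32)), "length >= 64")
})

test_that("R/S agrees with an independent implementation and is affine-invariant", {
  skip_if_not_installed("pracma")
  set.seed(7)
  x <- rnorm(8192)
  ours <- hurst_rescaled_range(x)$H
  theirs <- pracma::hurstexp(x, display = FALSE)$Hs
  expect_lt(abs(ours - theirs), 0.1)

  expect_equal(hurst_rescaled_range(3 * x + 10)$H, ours, tolerance = 1e-12)
})

test_that("persistent increment series keep their Hurst exponent", {
  # 1D fGn oracle: spectral synthesis with amplitude f^-(H + 1/2), differenced
  fgn1d <- function(n, H, seed) {
    set.seed(seed)
    fx <- c(0:(n / 2), -((n / 2 - 1):1)) / n
    amp <- c(0, abs(fx[-1])^(-(H + 0.5)))
    w <- complex(real = rnorm(n), imaginary = rnorm(n))
    z <- Re(stats::fft(w * amp, inverse = TRUE)) / n
    diff(z / sd(z))
  }
  hs <- vapply(1:3, function(s) {
    hurst_rescaled_range(fgn1d(65536, 0.8, s))$H
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.8), 0.1)
})

test_that("image-level Hurst variants behave per construction", {
  hm <- generate_surface(surface_spec("fbm", n_px = 256, hurst = 0.5, seed = 3))
  per <- hurst_image(hm, "per_line")
  expect_length(per$per_line_H, 256)
  expect_lt(abs(per$H - 0.5), 0.12)
  con <- hurst_image(hm, "concatenated")
  expect_false(identical(con$H, per$H))  # two algorithms, no forced equality

  # identical rows: build map whose rows are all the same series
  z <- matrix(rep(rnorm(256), times = 256), 256, 256, byrow = TRUE)
  same <- hurst_image(heightmap(z, scan_size_um = 50), "per_line")
  expect_equal(length(unique(round(same$per_line_H, 12))), 1)
})

test_that("fractal estimators honour exact limits and invariances", {
  pm <- plane_map(128, 0.4)
  tri <- fractal_dimension(pm, "triangulation")
  expect_equal(tri$d_f, 2, tolerance = 0.02)

  const <- heightmap(matrix(1, 128, 128), scan_size_um = 50)
  expect_equal(fractal_dimension(const, "triangulation")$d_f, 2)
  expect_equal(fractal_dimension(const, "cube_counting")$d_f, 2)
  expect_equal(fractal_dimension(const, "partition")$d_f, 2)
  expect_error(fractal_dimension(const, "power_spectrum"), "spectral slope")

  hm <- generate_surface(surface_spec("fbm", n_px = 128, hurst = 0.5, seed = 2))
  shifted <- hm; shifted$z <- hm$z + 100
  for (m in c("cube_counting", "triangulation", "power_spectrum", "partition")) {
    expect_equal(fractal_dimension(shifted, m)$d_f,
                 fractal_dimension(hm, m)$d_f, tolerance = 1e-9)
  }
})

test_that("estimated dimension decreases with the Hurst exponent", {
  d_of <- function(h, m) {
    mean(vapply(1:2, function(s) {
      hm <- generate_surface(surface_spec("fbm", n_px = 128, hurst = h,
                                          seed = s + 20))
      fractal_dimension(hm, m)$d_f
    }, numeric(1)))
  }
  for (m in c("cube_counting", "triangulation", "power_spectrum", "partition")) {
    expect_lt(d_of(0.8, m), d_of(0.3, m))
  }
})

test_that("the baseline feature row has the advertised shape", {
  hm <- generate_surface(surface_spec("phantom_rough", n_px = 256, seed = 1))
  bf <- baseline_features(hm)
  expect_equal(names(bf),
               c("mean_z", "rms_roughness", "z_skew", "z_kurt", "h_concat",
                 "h_perline_mean", "df_cube", "df_tri", "df_psd", "df_part"))
  expect_true(all(vapply(bf, is.finite, logical(1))))
  expect_true(all(bf[, c("df_cube", "df_tri", "df_psd", "df_part")] >= 2))
  expect_true(all(bf[, c("df_cube", "df_tri", "df_psd", "df_part")] <= 3))
})
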