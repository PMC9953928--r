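#' Synthetic surface specification
#'
#' Describes one synthetic test surface. Supported kinds:
#'
#' * `constant` — every z equals `amplitude_um`.
#' * `plane` — `z = amplitude_um * x`, with x the 0-based column index, i.e.
#'   a ramp of `amplitude_um` per pixel along the fast-scan axis.
#' * `sine` — ridge `z = amplitude_um * sin(2 * pi * x / wavelength_px)`.
#' * `white_noise` — iid Gaussian z with standard deviation `amplitude_um`.
#' * `fbm` — fractional Brownian surface of Hurst exponent `hurst`,
#'   synthesized spectrally (power spectral density proportional to
#'   `f^-(2 * hurst + 2)`) and rescaled to RMS `amplitude_um`.
#' * `phantom_rough` / `phantom_smooth` — two-class tissue phantoms: a shared
#'   large-scale random relief (Gaussian-correlated, 10 um correlation length,
#'   RMS `amplitude_um`) plus fine-scale texture of RMS `fine_texture_rms_um`
#'   (rough class) or `fine_texture_rms_um / contrast` (smooth class). The
#'   fine texture is 95% (by variance) Gaussian speckle of 0.6 um correlation
#'   and 5% white noise, i.e. it lives below the ~3 um cut-off that the
#'   residual of Gaussian filtering isolates. The rough class emulates
#'   non-metastatic-like tissue (higher residual sill), the smooth class
#'   metastatic-like tissue (lower sill).
#'
#' @param kind surface kind, see above.
#' @param n_px points per axis (>= 8); default 512.
#' @param scan_size_um physical scan size in um; default 50.
#' @param amplitude_um amplitude parameter in um (meaning depends on kind);
#'   default 1.
#' @param hurst Hurst exponent in (0, 1); required for `kind = "fbm"`.
#' @param fine_texture_rms_um RMS of the rough-class fine texture in um
#'   (phantoms only); default 0.5.
#' @param contrast rough/smooth ratio of fine-texture RMS (phantoms only);
#'   default 2.
#' @param wavelength_px sine wavelength in pixels (sine only); default 64.
#' @param seed integer seed; identical specs (including seed) reproduce
#'   bit-identical surfaces.
#' @return An object of class `surface_spec`.
#' @examples
#' spec <- surface_spec("fbm", n_px = 256, hurst = 0.5, seed = 1)
#' hm <- generate_surface(spec)
#' @export
surface_spec <- function(kind, n_px = 512, scan_size_um = 50, amplitude_um = 1,
                         hurst = NULL, fine_texture_rms_um = 0.5, contrast = 2,
                         wavelength_px = 64, seed = 1) {
  kind <- match.arg(kind, c("constant", "plane", "sine", "white_noise", "fbm",
                            "phantom_rough", "phantom_smooth"))
  check_scalar <- function(x, name, positive = TRUE, integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (positive && x <= 0) || (integer && x != round(x))) {
      stop(sprintf("invalid `%s`: %s", name, format(x)), call. = FALSE)
    }
  }
  check_scalar(n_px, "n_px", integer = TRUE)
  if (n_px < 8) stop("invalid `n_px`: must be >= 8", call. = FALSE)
  check_scalar(scan_size_um, "scan_size_um")
  if (!is.numeric(amplitude_um) || length(amplitude_um) != 1 || amplitude_um < 0) {
    stop("invalid `amplitude_um`: must be >= 0", call. = FALSE)
  }
  if (kind == "fbm") {
    if (is.null(hurst) || !is.numeric(hurst) || length(hurst) != 1 ||
        hurst <= 0 || hurst >= 1) {
      stop("invalid `hurst`: must be in (0, 1) for kind = \"fbm\"",
           call. = FALSE)
    }
  }
  if (kind %in% c("phantom_rough", "phantom_smooth")) {
    check_scalar(fine_texture_rms_um, "fine_texture_rms_um")
    check_scalar(contrast, "contrast")
  }
  check_scalar(wavelength_px, "wavelength_px")
  check_scalar(seed, "seed", positive = FALSE, integer = TRUE)
  structure(
    list(kind = kind, n_px = as.integer(n_px), scan_size_um = scan_size_um,
         amplitude_um = amplitude_um, hurst = hurst,
         fine_texture_rms_um = fine_texture_rms_um, contrast = contrast,
         wavelength_px = wavelength_px, seed = as.integer(seed)),
    class = "surface_spec"
  )
}

# Spectral synthesis of a real unit-variance Gaussian field with amplitude
# filter amp(f) applied to a complex white spectrum (periodic, seed-driven).
spectral_field <- function(n, amp_fun) {
  fx <- c(0:(n %/% 2), -((n %/% 2 - 1):1)) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  amp <- amp_fun(f)
  amp[1, 1] <- 0  # no DC power
  w <- matrix(complex(real = stats::rnorm(n * n),
                      imaginary = stats::rnorm(n * n)), n, n)
  z <- Re(stats::fft(w * amp, inverse = TRUE)) / (n * n)
  z / stats::sd(z)
}

# fBm surface: P(f) ~ f^-(2H+2), i.e. amplitude f^-(H+1).
fbm_field <- function(n, hurst) {
  spectral_field(n, function(f) f^(-(hurst + 1)))
}

# Gaussian-correlated unit-variance field (white noise convolved with a
# Gaussian of sd sigma_px; transfer amplitude exp(-2 pi^2 sigma^2 f^2)).
speckle_field <- function(n, sigma_px) {
  spectral_field(n, function(f) exp(-2 * pi^2 * sigma_px^2 * f^2))
}

phantom_field <- function(n, pixel_size_um, relief_rms_um, fine_rms_um) {
  relief_sigma_um <- 10    # large-scale relief correlation length
  speckle_sigma_um <- 0.6  # fine-texture correlation length
  white_frac <- 0.05       # white share of fine-texture variance
  relief <- speckle_field(n, relief_sigma_um / pixel_size_um) * relief_rms_um
  spk <- speckle_field(n, speckle_sigma_um / pixel_size_um)
  fine <- spk * sqrt(1 - white_frac) +
    matrix(stats::rnorm(n * n, sd = sqrt(white_frac)), n, n)
  relief + fine * fine_rms_um
}

#' Generate a synthetic surface
#'
#' Deterministic for a fixed [surface_spec()] (including its seed).
#'
#' @param spec a [surface_spec()].
#' @return A [heightmap()] with `pixel_size_um = scan_size_um / n_px`.
#' @examples
#' hm <- generate_surface(surface_spec("constant", n_px = 64, amplitude_um = 0.3))
#' all(hm$z == 0.3)
#' @export
generate_surface <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- spec$n_px
  a <- spec$amplitude_um
  px <- spec$scan_size_um / n
  x0 <- matrix(rep(0:(n - 1), each = n), n, n)  # 0-based column index
  set.seed(spec$seed)
  z <- switch(spec$kind,
    constant = matrix(a, n, n),
    plane = a * x0,
    sine = a * sin(2 * pi * x0 / spec$wavelength_px),
    white_noise = matrix(stats::rnorm(n * n, sd = a), n, n),
    fbm = fbm_field(n, spec$hurst) * a,
    phantom_rough = phantom_field(n, px, a, spec$fine_texture_rms_um),
    phantom_smooth = phantom_field(n, px, a,
                                   spec$fine_texture_rms_um / spec$contrast)
  )
  heightmap(z, scan_size_um = spec$scan_size_um)
}

#' Generate a labelled two-class phantom cohort
#'
#' Emulates a metastatic / non-metastatic AFM cohort: metastatic-labelled
#' samples are `phantom_smooth` surfaces (lower residual sill),
#' non-metastatic-labelled samples `phantom_rough` (higher sill). Sample ids
#' follow the `m{i}.{j}` / `nm{i}.{j}` convention (four samples per nominal
#' patient). Each sample draws its own realization of relief and texture, and
#' its fine-texture RMS carries a 10% lognormal between-sample jitter.
#'
#' @param n_met number of metastatic-labelled samples (>= 1).
#' @param n_nonmet number of non-metastatic-labelled samples (>= 1).
#' @param base_spec a [surface_spec()] providing geometry, amplitude, fine
#'   texture and contrast; its `kind` is ignored.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param jitter_sd lognormal sd of the per-sample fine-texture RMS jitter;
#'   default 0.1.
#' @return A tibble with columns `sample_id`, `label`
#'   (`"metastatic"`/`"non_metastatic"`) and `map` (list-column of
#'   [heightmap()]s).
#' @examples
#' co <- generate_cohort(2, 2, surface_spec("phantom_rough", n_px = 64), seed = 1)
#' co$sample_id
#' @export
generate_cohort <- function(n_met, n_nonmet, base_spec, seed,
                            jitter_sd = 0.1) {
  stopifnot(inherits(base_spec, "surface_spec"))
  if (!is.numeric(n_met) || n_met < 1 || !is.numeric(n_nonmet) || n_nonmet < 1) {
    stop("`n_met` and `n_nonmet` must be >= 1", call. = FALSE)
  }
  ids <- function(prefix, k) {
    sprintf("%s%d.%d", prefix, (seq_len(k) - 1) %/% 4 + 1,
            (seq_len(k) - 1) %% 4 + 1)
  }
  lab <- c(rep("metastatic", n_met), rep("non_metastatic", n_nonmet))
  id <- c(ids("m", n_met), ids("nm", n_nonmet))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_met + n_nonmet)
  jit <- exp(stats::rnorm(n_met + n_nonmet, sd = jitter_sd))
  maps <- purrr::pmap(list(lab, sub_seeds, jit), function(l, s, j) {
    sp <- base_spec
    sp$kind <- if (l == "metastatic") "phantom_smooth" else "phantom_rough"
    sp$fine_texture_rms_um <- base_spec$fine_texture_rms_um * j
    sp$seed <- s
    generate_surface(sp)
  })
  maps <- purrr::map2(maps, id, function(m, i) { m$sample_id <- i; m })
  tibble::tibble(sample_id = id, label = lab, map = maps)
}

#' Hurst exponent from the radially averaged periodogram
#'
#' Estimates the Hurst exponent of a self-affine surface from the log-log
#' slope of its radially averaged power spectral density,
#' `H = (beta - 2) / 2` for `P(f) ~ f^-beta`. Serves as ground-truth check
#' for spectrally synthesized fBm surfaces and as the slope engine of the
#' power-spectrum fractal dimension.
#'
#' @param map a [heightmap()].
#' @param n_bins number of logarithmic frequency bins; default 20.
#' @return A one-row tibble with `hurst`, `beta` and `fit_r2`.
#' @export
estimate_hurst_psd <- function(map, n_bins = 20) {
  stopifnot(inherits(map, "heightmap"))
  n <- nrow(map$z)
  P <- Mod(stats::fft(map$z))^2
  fx <- c(0:(n %/% 2), -((n %/% 2 - 1):1)) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  sel <- f > 1 / n & f < 0.25
  lb <- cut(log(f[sel]), n_bins)
  mp <- tapply(P[sel], lb, mean)
  mf <- tapply(f[sel], lb, function(x) exp(mean(log(x))))
  ok <- !is.na(mp) & mp > 0
  if (sum(ok) < 4) stop("too few populated frequency bins", call. = FALSE)
  fit <- stats::lm(log(mp[ok]) ~ log(mf[ok]))
  beta <- -unname(stats::coef(fit)[2])
  tibble::tibble(hurst = (beta - 2) / 2, beta = beta,
                 fit_r2 = summary(fit)$r.squared)
}
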