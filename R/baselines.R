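#' Standard surface statistics of a raster
#'
#' Channel-agnostic moments of the z-sample: mean, RMS roughness (standard
#' deviation about the mean, population convention), skewness, excess
#' kurtosis, min and max. On a phase map the same statistics describe the
#' phase signal (degrees).
#'
#' @param map a [heightmap()].
#' @return A one-row tibble: `mean_z`, `rms_roughness`, `z_skewness`,
#'   `z_kurtosis`, `z_min`, `z_max`, `channel`.
#' @examples
#' surface_stats(heightmap(matrix(0.3, 16, 16), scan_size_um = 10))
#' @export
surface_stats <- function(map) {
  stopifnot(inherits(map, "heightmap"))
  z <- as.vector(map$z)
  m <- mean(z)
  s <- sqrt(mean((z - m)^2))
  tibble::tibble(
    mean_z = m,
    rms_roughness = s,
    z_skewness = if (s > 0) mean((z - m)^3) / s^3 else NA_real_,
    z_kurtosis = if (s > 0) mean((z - m)^4) / s^4 - 3 else NA_real_,
    z_min = min(z),
    z_max = max(z),
    channel = map$channel
  )
}

#' Rescaled-range (R/S) Hurst exponent of a series
#'
#' Classic R/S: for each window size w, the series is cut into disjoint
#' windows; in each, the range of the cumulative mean-adjusted sums is
#' divided by the window standard deviation, and the per-size statistic is
#' the mean over windows. H is the least-squares slope of log2(R/S) against
#' log2(w). H near 0.5 indicates an uncorrelated increment series, H > 0.5
#' persistence. Zero-variance windows are skipped; if a whole size has no
#' usable window it is dropped.
#'
#' For short series the raw R/S slope is biased upward; the
#' `"anis_lloyd"` correction fits the excess `log(R/S) - log(E[R/S])` over
#' the iid expectation (Anis-Lloyd with the Peters finite-sample factor)
#' and adds it to 0.5. The default is the uncorrected classic statistic.
#'
#' @param series numeric vector, length >= 64.
#' @param window_sizes window ladder; default dyadic from 8 to `length / 4`.
#' @param correction `"none"` (classic, default) or `"anis_lloyd"`.
#' @return An object of class `hurst_fit`: list with `H`, `fit_r2`,
#'   `window_sizes`, `rs` (tibble of per-size mean R/S), `method`.
#' @examples
#' set.seed(1)
#' hurst_rescaled_range(rnorm(4096))$H  # about 0.5
#' @export
hurst_rescaled_range <- function(series, window_sizes = NULL,
                                 correction = c("none", "anis_lloyd")) {
  correction <- match.arg(correction)
  x <- as.numeric(series)
  if (length(x) < 64) stop("series must have length >= 64", call. = FALSE)
  if (is.null(window_sizes)) {
    window_sizes <- 2^(3:floor(log2(length(x) / 4)))
  }
  window_sizes <- window_sizes[window_sizes >= 8 &
                                 window_sizes <= length(x) %/% 2]
  rs <- vapply(window_sizes, function(w) {
    k <- length(x) %/% w
    vals <- vapply(seq_len(k), function(i) {
      s <- x[((i - 1) * w + 1):(i * w)]
      sdv <- stats::sd(s)
      if (!is.finite(sdv) || sdv == 0) return(NA_real_)
      y <- cumsum(s - mean(s))
      (max(y) - min(y)) / sdv
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 4) {
    stop("fewer than 4 usable window sizes (degenerate series?)",
         call. = FALSE)
  }
  y <- log2(rs[ok])
  if (correction == "anis_lloyd") {
    y <- y - log2(vapply(window_sizes[ok], rs_expected_iid, numeric(1)))
  }
  fit <- loglog_fit(log2(window_sizes[ok]), y)
  structure(
    list(
      H = fit$slope + if (correction == "anis_lloyd") 0.5 else 0,
      fit_r2 = fit$r2,
      window_sizes = window_sizes[ok],
      rs = tibble::tibble(window = window_sizes[ok], rs = rs[ok]),
      method = "rescaled_range"
    ),
    class = "hurst_fit"
  )
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("<hurst_fit> H = %.3f (R^2 = %.3f, %d window sizes, %s)\n",
              x$H, x$fit_r2, length(x$window_sizes), x$method))
  invisible(x)
}

#' Image-level Hurst exponent from scan lines
#'
#' Two row-based schemes: `"concatenated"` strings every row of the raster
#' one after another into a single series of n^2 points and fits one H;
#' `"per_line"` fits H row by row and reports the per-row values plus their
#' mean. Because R/S presumes a stationary increment series, each profile is
#' first differenced by default (`difference = TRUE`); applied to raw
#' self-affine height profiles R/S saturates near 1 regardless of the true
#' exponent.
#'
#' @param map a [heightmap()].
#' @param method `"concatenated"` or `"per_line"`.
#' @param difference difference each profile before R/S; default TRUE.
#' @param window_sizes passed to [hurst_rescaled_range()].
#' @param correction passed to [hurst_rescaled_range()]. Default: `"none"`
#'   for the concatenated series (n^2 points are long enough for the classic
#'   statistic), `"anis_lloyd"` per line (single rows are short series whose
#'   raw R/S slope is biased upward).
#' @return An object of class `hurst_fit`; for `"per_line"` it additionally
#'   carries `per_line_H` (one H per row) and `H` is their mean.
#' @export
hurst_image <- function(map, method = c("concatenated", "per_line"),
                        difference = TRUE, window_sizes = NULL,
                        correction = NULL) {
  stopifnot(inherits(map, "heightmap"))
  method <- match.arg(method)
  prep <- function(v) if (difference) diff(v) else v
  if (method == "concatenated") {
    series <- prep(as.vector(t(map$z)))  # row after row
    fit <- hurst_rescaled_range(series, window_sizes,
                                correction = correction %||% "none")
    fit$method <- "concatenated"
    return(fit)
  }
  if (is.null(correction)) correction <- "anis_lloyd"
  len <- ncol(map$z) - as.integer(difference)
  if (is.null(window_sizes)) {
    # rows are short series: extend the ladder to len/2 to keep >= 4 sizes
    window_sizes <- 2^(3:floor(log2(len / 2)))
  }
  hs <- apply(map$z, 1, function(row) {
    hurst_rescaled_range(prep(row), window_sizes, correction = correction)$H
  })
  fit <- list(
    H = mean(hs),
    fit_r2 = NA_real_,
    window_sizes = NULL,
    rs = NULL,
    per_line_H = hs,
    method = "per_line"
  )
  class(fit) <- "hurst_fit"
  fit
}

# least-squares line on already-logged coordinates; r2 robust to perfect fits
loglog_fit <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  resid <- y - yb - slope * (x - xb)
  ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  list(slope = slope, r2 = r2)
}

# Anis-Lloyd expected R/S of an iid series in a window of size n,
# with the Peters (n - 1/2)/n finite-sample factor.
rs_expected_iid <- function(n) {
  i <- seq_len(n - 1)
  s <- sum(sqrt((n - i) / i))
  pref <- if (n <= 340) {
    exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
  } else {
    1 / sqrt(n * pi / 2)
  }
  (n - 0.5) / n * pref * s
}

# dyadic scales between lo and hi (inclusive by power)
dyadic_scales <- function(lo, hi) {
  if (hi < lo) stop("degenerate scale range", call. = FALSE)
  2^(ceiling(log2(lo)):floor(log2(hi)))
}

# z-normalization convention for metric estimators: the height range is
# mapped to z_aspect times the lateral extent (in pixel units). Surface
# fractality of a physical raster depends on this z-scale convention; the
# expansion keeps the fit inside the slope-dominated regime.
normalize_aspect <- function(z, z_aspect) {
  rng <- diff(range(z))
  if (rng == 0) return(NULL)  # degenerate: caller decides
  (z - min(z)) / rng * nrow(z) * z_aspect
}

fd_cube_counting <- function(z, scales, z_aspect) {
  n <- nrow(z)
  if (is.null(scales)) scales <- dyadic_scales(max(2, n %/% 32), n %/% 4)
  zs <- normalize_aspect(z, z_aspect)
  if (is.null(zs)) {
    return(list(D = 2, fit_r2 = 1, scales = scales, degenerate = TRUE))
  }
  counts <- vapply(scales, function(s) {
    m <- n %/% s
    blk <- array(zs[seq_len(m * s), seq_len(m * s)], c(s, m, s, m))
    mx <- apply(blk, c(2, 4), max)
    mn <- apply(blk, c(2, 4), min)
    sum(floor(mx / s) - floor(mn / s) + 1)
  }, numeric(1))
  fit <- loglog_fit(log2(scales), log2(counts))
  list(D = -fit$slope, fit_r2 = fit$r2, scales = scales, degenerate = FALSE)
}

fd_triangulation <- function(z, scales, z_aspect) {
  n <- nrow(z)
  if (is.null(scales)) scales <- dyadic_scales(2, n %/% 4)
  rng <- diff(range(z))
  if (rng == 0) {
    return(list(D = 2, fit_r2 = 1, scales = scales, degenerate = TRUE))
  }
  zs <- normalize_aspect(z, z_aspect)
  area <- vapply(scales, function(s) {
    idx <- seq(1, n, by = s)
    m <- length(idx)
    zz <- zs[idx, idx]
    z00 <- zz[-m, -m]; z10 <- zz[-1, -m]; z01 <- zz[-m, -1]; z11 <- zz[-1, -1]
    a1 <- 0.5 * sqrt((s * (z01 - z00))^2 + (s * (z10 - z00))^2 + (s * s)^2)
    a2 <- 0.5 * sqrt((s * (z10 - z11))^2 + (s * (z01 - z11))^2 + (s * s)^2)
    sum(a1 + a2) / ((m - 1) * s)^2  # area per unit projected area
  }, numeric(1))
  fit <- loglog_fit(log2(scales), log2(area))
  list(D = 2 - fit$slope, fit_r2 = fit$r2, scales = scales,
       degenerate = FALSE)
}

fd_power_spectrum <- function(z, map) {
  if (diff(range(z)) == 0) {
    stop("constant surface has no spectral slope", call. = FALSE)
  }
  est <- estimate_hurst_psd(map)
  list(D = 3 - est$hurst, fit_r2 = est$fit_r2, scales = NULL,
       degenerate = FALSE)
}

fd_partition <- function(z, scales) {
  n <- nrow(z)
  if (is.null(scales)) scales <- dyadic_scales(2, n %/% 4)
  if (diff(range(z)) == 0) {
    return(list(D = 2, fit_r2 = 1, scales = scales, degenerate = TRUE))
  }
  v <- vapply(scales, function(s) {
    m <- n %/% s
    blk <- array(z[seq_len(m * s), seq_len(m * s)], c(s, m, s, m))
    mean(apply(blk, c(2, 4), stats::var))
  }, numeric(1))
  fit <- loglog_fit(log2(scales), log2(v))  # slope = 2H
  list(D = 3 - fit$slope / 2, fit_r2 = fit$r2, scales = scales,
       degenerate = FALSE)
}

#' Monofractal dimension of a surface
#'
#' Four standard estimators of the surface fractal dimension `D_f` in
#' `[2, 3]`, each a log-log fit of its scaling law over dyadic scales:
#'
#' * `cube_counting` — occupied-box count `N(l) ~ l^-D` on the z-expanded
#'   surface; default scales `max(2, n/32)..n/4` px (the smallest scales are
#'   excluded because extreme-value inflation of block relief flattens the
#'   count there).
#' * `triangulation` — triangulated area per unit projected area
#'   `A(l) ~ l^(2 - D)`; scales `2..n/4` px.
#' * `power_spectrum` — radial PSD slope, `D = 3 - H` with
#'   `H = (beta - 2)/2`.
#' * `partition` — mean within-block variance `V(l) ~ l^(2H)`, `D = 3 - H`;
#'   scales `2..n/4` px.
#'
#' Metric estimators (cube counting, triangulation) depend on the z-scale
#' convention; the height range is mapped to `z_aspect` times the lateral
#' extent (default 8) before counting. All estimators are invariant to adding
#' a constant to z. Estimates outside `[2, 3]` are clamped and flagged.
#' A constant surface gives exactly D = 2 for the metric estimators and an
#' error for the power spectrum (no slope).
#'
#' @param map a [heightmap()]; n >= 64 recommended for stable fits.
#' @param method one of `"cube_counting"`, `"triangulation"`,
#'   `"power_spectrum"`, `"partition"`.
#' @param scales optional vector of scales in px (metric/partition methods).
#' @param z_aspect z-expansion factor of the normalization; default 8.
#' @return A one-row tibble: `method`, `d_f`, `fit_r2`, `scale_lo_px`,
#'   `scale_hi_px`, `clamped`.
#' @examples
#' hm <- generate_surface(surface_spec("fbm", n_px = 128, hurst = 0.5))
#' fractal_dimension(hm, "triangulation")  # about 2.5
#' @export
fractal_dimension <- function(map,
                              method = c("cube_counting", "triangulation",
                                         "power_spectrum", "partition"),
                              scales = NULL, z_aspect = 8) {
  stopifnot(inherits(map, "heightmap"))
  method <- match.arg(method)
  z <- map$z
  res <- switch(method,
    cube_counting = fd_cube_counting(z, scales, z_aspect),
    triangulation = fd_triangulation(z, scales, z_aspect),
    power_spectrum = fd_power_spectrum(z, map),
    partition = fd_partition(z, scales)
  )
  clamped <- res$D < 2 || res$D > 3
  tibble::tibble(
    method = method,
    d_f = min(max(res$D, 2), 3),
    fit_r2 = res$fit_r2,
    scale_lo_px = if (is.null(res$scales)) NA_real_ else min(res$scales),
    scale_hi_px = if (is.null(res$scales)) NA_real_ else max(res$scales),
    clamped = clamped
  )
}

#' Baseline feature vector for one sample
#'
#' The comparison battery: surface statistics, both R/S Hurst variants and
#' the four fractal dimensions, as one row suitable for a per-sample feature
#' table.
#'
#' @param map a [heightmap()].
#' @return A one-row tibble with columns `mean_z`, `rms_roughness`, `z_skew`,
#'   `z_kurt`, `h_concat`, `h_perline_mean`, `df_cube`, `df_tri`, `df_psd`,
#'   `df_part`.
#' @export
baseline_features <- function(map) {
  ss <- surface_stats(map)
  tibble::tibble(
    mean_z = ss$mean_z,
    rms_roughness = ss$rms_roughness,
    z_skew = ss$z_skewness,
    z_kurt = ss$z_kurtosis,
    h_concat = hurst_image(map, "concatenated")$H,
    h_perline_mean = hurst_image(map, "per_line")$H,
    df_cube = fractal_dimension(map, "cube_counting")$d_f,
    df_tri = fractal_dimension(map, "triangulation")$d_f,
    df_psd = fractal_dimension(map, "power_spectrum")$d_f,
    df_part = fractal_dimension(map, "partition")$d_f
  )
}
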