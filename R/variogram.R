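#' @title Directional and radial RMS-deviation variograms
#' @description Core operations: per-lag sums of squared height differences
#'   over all in-bounds pixel pairs, computed either by FFT cross-correlation
#'   (default, exact up to floating roundoff) or by direct shifted-slice
#'   accumulation. All downstream quantities (2D maps, radial curves, moment
#'   variograms, sills) derive from these sums.
#' @name variogram
NULL

# Per-lag sums of squared differences and pair counts over the half-plane
# p > 0, or p == 0 & v > 0 (the other half follows by centrosymmetry).
# Returns a data frame with v, p, sq_sum, n_pairs.
lag_sq_diff_sums <- function(z, max_lag, method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- nrow(z)
  L <- as.integer(max_lag)
  if (L < 1 || L >= n) {
    stop(sprintf("`max_lag_px` (%d) must satisfy 1 <= max_lag < n = %d", L, n),
         call. = FALSE)
  }
  p <- rep(0:L, each = 2 * L + 1)
  v <- rep(-L:L, times = L + 1)
  keep <- p > 0 | v > 0
  p <- p[keep]; v <- v[keep]
  n_pairs <- (n - abs(p)) * (n - abs(v))

  if (method == "direct") {
    sq_sum <- mapply(function(pp, vv) {
      r1 <- max(1, 1 - pp); r2 <- min(n, n - pp)
      c1 <- max(1, 1 - vv); c2 <- min(n, n - vv)
      sum((z[r1:r2, c1:c2] - z[(r1 + pp):(r2 + pp), (c1 + vv):(c2 + vv)])^2)
    }, p, v)
  } else {
    z <- z - mean(z)  # differences are shift-invariant; centring tames
                      # the DC term that dominates FFT roundoff
    m <- stats::nextn(n + L, 2)
    Zp <- matrix(0, m, m)
    Zp[seq_len(n), seq_len(n)] <- z
    FZ <- stats::fft(Zp)
    cc <- Re(stats::fft(FZ * Conj(FZ), inverse = TRUE)) / (m * m)
    # padded prefix sums of z^2: cz2[i+1, j+1] = sum(z[1:i, 1:j]^2)
    cz2 <- matrix(0, n + 1, n + 1)
    cz2[-1, -1] <- t(apply(apply(z^2, 2, cumsum), 1, cumsum))
    rect <- function(r1, r2, c1, c2) {
      cz2[cbind(r2 + 1, c2 + 1)] - cz2[cbind(r1, c2 + 1)] -
        cz2[cbind(r2 + 1, c1)] + cz2[cbind(r1, c1)]
    }
    r1 <- pmax(1, 1 - p); r2 <- pmin(n, n - p)
    c1 <- pmax(1, 1 - v); c2 <- pmin(n, n - v)
    Sa <- rect(r1, r2, c1, c2)
    Sb <- rect(r1 + p, r2 + p, c1 + v, c2 + v)
    C <- cc[cbind((p %% m) + 1, (v %% m) + 1)]
    sq_sum <- pmax(Sa + Sb - 2 * C, 0)
  }
  data.frame(v = v, p = p, sq_sum = sq_sum, n_pairs = n_pairs)
}

#' 2D RMS-deviation map over signed lag vectors
#'
#' For each lag vector `h = (v, p)` with `0 < max(|v|, |p|) <= max_lag_px`,
#' the RMS deviation `D(h) = sqrt(mean((z(x, y) - z(x + v, y + p))^2))` over
#' all in-bounds pixel pairs (all four sign quadrants). The pair set of
#' `(v, p)` and `(-v, -p)` is identical, so the map is exactly centrosymmetric,
#' and the pair count is `(n - |v|) * (n - |p|)`. The zero lag is reported
#' with `d = NA` (undefined by convention).
#'
#' @param map a [heightmap()], typically a [gaussian_residual()].
#' @param max_lag_px largest |v|, |p| in pixels (`1 <= max_lag_px < n`).
#' @param method `"fft"` (default; cross-correlation by FFT plus exact prefix
#'   sums) or `"direct"` (shifted-slice sums; slower, exact).
#' @return A tibble of class `vgram_map` with columns `v`, `p`, `lag_px`,
#'   `lag_um`, `d` (RMS deviation, units of z) and `n_pairs`; attributes
#'   `pixel_size_um` and `value_units`.
#' @examples
#' hm <- heightmap(matrix(rnorm(32^2), 32), scan_size_um = 50)
#' vm <- rms_deviation_map(hm, max_lag_px = 4)
#' @export
rms_deviation_map <- function(map, max_lag_px, method = c("fft", "direct")) {
  stopifnot(inherits(map, "heightmap"))
  half <- lag_sq_diff_sums(map$z, max_lag_px, method)
  full <- rbind(
    half,
    data.frame(v = -half$v, p = -half$p, sq_sum = half$sq_sum,
               n_pairs = half$n_pairs),
    data.frame(v = 0L, p = 0L, sq_sum = NA_real_,
               n_pairs = nrow(map$z)^2)
  )
  out <- tibble::tibble(
    v = full$v, p = full$p,
    lag_px = sqrt(full$v^2 + full$p^2),
    lag_um = sqrt(full$v^2 + full$p^2) * map$pixel_size_um,
    d = sqrt(full$sq_sum / full$n_pairs),
    n_pairs = full$n_pairs
  )
  out <- dplyr::arrange(out, .data$p, .data$v)
  class(out) <- c("vgram_map", class(out))
  attr(out, "pixel_size_um") <- map$pixel_size_um
  attr(out, "value_units") <- map$value_units
  out
}

#' Radially binned empirical variogram (generalized q-moment)
#'
#' Pools squared differences from all lag vectors whose magnitude
#' `|h| = sqrt(v^2 + p^2)` falls in each radial bin, weighting by pair count
#' so each bin's base value `B(h)` is the grand mean squared difference of
#' all pairs in the bin. The reported curve is `gamma(h, q) = B(h)^q`:
#' `q = 0.5` gives exactly the RMS deviation `D(h)` (length units), `q = 1`
#' the plain empirical variogram (squared units), and higher q emphasize the
#' tail of the height-difference distribution.
#'
#' Bins are `bin_width_px` wide, centred on integer lag radii (first edge at
#' 0.5 px, the 1 px nugget limit). Empty bins are kept with `n_pairs = 0` and
#' `gamma = NA` and are ignored by [estimate_sill()].
#'
#' @inheritParams rms_deviation_map
#' @param max_lag_px largest lag magnitude in px; default `n / 4`.
#' @param bin_width_px radial bin width in px; default 1.
#' @param moment_q moment exponent q > 0; default 0.5.
#' @return A tibble of class `vgram_1d` with columns `bin_lo_um`, `bin_hi_um`,
#'   `lag_um` (pair-weighted mean lag), `base_msd` (B, squared units),
#'   `gamma` (`B^q`) and `n_pairs`; attributes `moment_q`, `pixel_size_um`,
#'   `value_units`, `max_lag_px`.
#' @examples
#' hm <- heightmap(matrix(rnorm(64^2), 64), scan_size_um = 50)
#' vg <- radial_variogram(hm)  # ~ sqrt(2) at every lag for unit white noise
#' @export
radial_variogram <- function(map, max_lag_px = NULL, bin_width_px = 1,
                             moment_q = 0.5, method = c("fft", "direct")) {
  stopifnot(inherits(map, "heightmap"))
  if (!is.numeric(moment_q) || length(moment_q) != 1 || moment_q <= 0) {
    stop("`moment_q` must be a single positive number", call. = FALSE)
  }
  n <- nrow(map$z)
  if (is.null(max_lag_px)) max_lag_px <- max(n %/% 4, 2)
  half <- lag_sq_diff_sums(map$z, max_lag_px, method)
  base <- bin_lag_sums(half, max_lag_px, bin_width_px, map$pixel_size_um)
  out <- dplyr::mutate(base, gamma = .data$base_msd^moment_q)
  class(out) <- c("vgram_1d", class(out))
  attr(out, "moment_q") <- moment_q
  attr(out, "pixel_size_um") <- map$pixel_size_um
  attr(out, "value_units") <- map$value_units
  attr(out, "max_lag_px") <- max_lag_px
  out
}

# Radial binning of half-plane lag sums; magnitude-filtered at max_lag_px.
bin_lag_sums <- function(half, max_lag_px, bin_width_px, pixel_size_um) {
  lag <- sqrt(half$v^2 + half$p^2)
  sel <- lag <= max_lag_px + 1e-9
  lag <- lag[sel]
  sq_sum <- half$sq_sum[sel]
  n_pairs <- half$n_pairs[sel]
  edges <- seq(0.5, max_lag_px + bin_width_px, by = bin_width_px)
  idx <- findInterval(lag, edges)
  nb <- length(edges) - 1
  agg <- function(x) {
    out <- rep(0, nb)
    s <- tapply(x, idx, sum)
    out[as.integer(names(s))] <- s
    out
  }
  ssum <- agg(sq_sum)
  np <- agg(n_pairs)
  wlag <- agg(lag * n_pairs)
  tibble::tibble(
    bin_lo_um = edges[seq_len(nb)] * pixel_size_um,
    bin_hi_um = edges[-1] * pixel_size_um,
    lag_um = ifelse(np > 0, wlag / np * pixel_size_um, NA_real_),
    base_msd = ifelse(np > 0, ssum / np, NA_real_),
    n_pairs = np
  )
}

#' Plateau sill estimate of a 1D variogram
#'
#' The sill is the plateau a variogram flattens to (zero spatial correlation
#' beyond that lag). It is estimated as the pair-count-weighted mean of
#' `gamma` over the trailing `plateau_fraction` of the lag domain. A
#' weighted-least-squares slope is fitted over the same window; if the
#' relative change across the window (`slope * window / sill`) exceeds
#' `slope_cap`, the estimate is flagged as still rising (e.g. unbounded
#' drift, as for a tilted plane), not an error.
#'
#' @param vgram a `vgram_1d` from [radial_variogram()].
#' @param plateau_fraction trailing fraction of the lag domain to average
#'   over (0 < f < 1); default 0.3.
#' @param slope_cap relative-change cap above which the plateau is flagged
#'   as rising; default 0.25.
#' @return A one-row tibble: `sill`, `lag_lo_um`, `lag_hi_um`, `method`
#'   (`"plateau_mean"`), `moment_q`, `rising` (logical flag).
#' @examples
#' hm <- heightmap(matrix(rnorm(64^2), 64), scan_size_um = 50)
#' estimate_sill(radial_variogram(hm))
#' @export
estimate_sill <- function(vgram, plateau_fraction = 0.3, slope_cap = 0.25) {
  stopifnot(inherits(vgram, "vgram_1d"))
  if (!is.numeric(plateau_fraction) || plateau_fraction <= 0 ||
      plateau_fraction >= 1) {
    stop("`plateau_fraction` must be in (0, 1)", call. = FALSE)
  }
  ok <- vgram$n_pairs > 0 & !is.na(vgram$gamma)
  if (sum(ok) < 5) {
    stop("need at least 5 non-empty bins for a sill estimate", call. = FALSE)
  }
  vg <- vgram[ok, ]
  lag_max <- max(vg$lag_um)
  lag_lo <- lag_max * (1 - plateau_fraction)
  win <- vg$lag_um >= lag_lo
  if (sum(win) < 2) win <- seq_len(nrow(vg)) > nrow(vg) - 2
  g <- vg$gamma[win]
  w <- vg$n_pairs[win]
  l <- vg$lag_um[win]
  sill <- sum(g * w) / sum(w)
  slope <- if (length(unique(l)) > 1) {
    unname(stats::coef(stats::lm(g ~ l, weights = w))[2])
  } else 0
  rel_change <- if (sill > 0) abs(slope) * (max(l) - min(l)) / sill else 0
  tibble::tibble(
    sill = sill,
    lag_lo_um = min(l),
    lag_hi_um = max(l),
    method = "plateau_mean",
    moment_q = attr(vgram, "moment_q") %||% NA_real_,
    rising = rel_change > slope_cap
  )
}

#' Generalized variogram curves for several moments
#'
#' Computes the binned base curve `B(h)` once and returns
#' `gamma(h, q) = B(h)^q` for every requested q as a long tibble. By the
#' power identity the per-lag curves carry no new information across q;
#' moments matter through the nonlinear interaction of the power transform
#' with plateau averaging and group thresholds.
#'
#' @inheritParams radial_variogram
#' @param q_list moments to evaluate; default `c(0.5, 1, 2, 3, 4, 5)`.
#' @return A tibble with columns `moment_q`, `bin_lo_um`, `bin_hi_um`,
#'   `lag_um`, `base_msd`, `gamma`, `n_pairs`.
#' @export
generalized_variogram <- function(map, q_list = c(0.5, 1, 2, 3, 4, 5),
                                  max_lag_px = NULL, bin_width_px = 1,
                                  method = c("fft", "direct")) {
  stopifnot(inherits(map, "heightmap"))
  if (any(q_list <= 0)) stop("all moments must be > 0", call. = FALSE)
  n <- nrow(map$z)
  if (is.null(max_lag_px)) max_lag_px <- max(n %/% 4, 2)
  half <- lag_sq_diff_sums(map$z, max_lag_px, method)
  base <- bin_lag_sums(half, max_lag_px, bin_width_px, map$pixel_size_um)
  purrr::map_dfr(q_list, function(q) {
    dplyr::mutate(base, moment_q = q, gamma = .data$base_msd^q,
                  .before = 1)
  })
}

#' Sill per moment from a shared base curve
#'
#' One plateau sill estimate per q, all derived from the same binned base
#' mean-squared-difference curve.
#'
#' @inheritParams generalized_variogram
#' @inheritParams estimate_sill
#' @return A tibble with one row per q: `moment_q`, `sill`, `lag_lo_um`,
#'   `lag_hi_um`, `rising`.
#' @export
moment_sill_profile <- function(map, q_list = c(0.5, 1, 2, 3, 4, 5),
                                max_lag_px = NULL, bin_width_px = 1,
                                plateau_fraction = 0.3, slope_cap = 0.25,
                                method = c("fft", "direct")) {
  gv <- generalized_variogram(map, q_list, max_lag_px, bin_width_px, method)
  purrr::map_dfr(q_list, function(q) {
    vg <- dplyr::filter(gv, .data$moment_q == q)
    vg$moment_q <- NULL
    class(vg) <- c("vgram_1d", class(vg))
    attr(vg, "moment_q") <- q
    est <- estimate_sill(vg, plateau_fraction, slope_cap)
    est$method <- NULL
    est
  })
}
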