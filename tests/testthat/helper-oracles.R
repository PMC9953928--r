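# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity.

# All-pairs double-loop RMS deviation over every signed lag up to L.
brute_rms_map <- function(z, L) {
  n <- nrow(z)
  out <- expand.grid(v = -L:L, p = -L:L)
  out$d <- NA_real_
  out$n_pairs <- NA_real_
  for (r in seq_len(nrow(out))) {
    v <- out$v[r]; p <- out$p[r]
    if (v == 0 && p == 0) next
    s <- 0; N <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      i2 <- i + p; j2 <- j + v
      if (i2 >= 1 && i2 <= n && j2 >= 1 && j2 <= n) {
        s <- s + (z[i, j] - z[i2, j2])^2
        N <- N + 1
      }
    }
    out$d[r] <- sqrt(s / N)
    out$n_pairs[r] <- N
  }
  out
}

# Dense 2D convolution with an explicit separable Gaussian kernel and
# reflect padding (edge pixel repeated), evaluated pixel by pixel.
dense_gaussian_smooth <- function(z, sigma_px) {
  w <- nanovario::gaussian_kernel(sigma_px)
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(z)
  reflect_idx <- function(i) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + w[a + r + 1] * w[b + r + 1] *
        z[reflect_idx(i + a), reflect_idx(j + b)]
    }
    out[i, j] <- acc
  }
  out
}

rel_err <- function(x, y) {
  denom <- pmax(abs(y), .Machine$double.eps)
  max(abs(x - y) / denom, na.rm = TRUE)
}

white_map <- function(n, seed, sd = 1, scan = 50) {
  set.seed(seed)
  nanovario::heightmap(matrix(stats::rnorm(n * n, sd = sd), n, n),
                       scan_size_um = scan)
}

plane_map <- function(n, slope_per_px, scan = n) {
  x0 <- matrix(rep(0:(n - 1), each = n), n, n)
  nanovario::heightmap(slope_per_px * x0, scan_size_um = scan)
}

# Manually assembled 1D variogram (for sill-estimator tests on known curves).
fake_vgram <- function(lag_um, gamma, n_pairs = rep(1000, length(lag_um)),
                       q = 0.5) {
  vg <- tibble::tibble(
    bin_lo_um = lag_um - 0.5, bin_hi_um = lag_um + 0.5,
    lag_um = lag_um, base_msd = gamma^2, gamma = gamma, n_pairs = n_pairs
  )
  class(vg) <- c("vgram_1d", class(vg))
  attr(vg, "moment_q") <- q
  vg
}
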