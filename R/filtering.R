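#' Truncated Gaussian filter specification
#'
#' Describes the separable Gaussian smoother whose residual carries the
#' sub-kernel-scale roughness that all variogram analysis consumes. The kernel
#' is truncated at a box of `6 * sigma_px + 1` pixels (nearest odd integer,
#' ties rounded up), so `sigma_px = 5` gives the canonical 31 px kernel, and
#' the cut-off wavelength is the kernel box (about 3 um at a 97.66 nm pixel).
#'
#' Exactly one of `sigma_px` or `sigma_um` must be given; `sigma_um` requires
#' `pixel_size_um` for the conversion.
#'
#' @param sigma_px standard deviation in pixels (> 0).
#' @param sigma_um standard deviation in micrometres (alternative to
#'   `sigma_px`).
#' @param boundary boundary handling: `"reflect"` (edge pixel repeated,
#'   default), `"nearest"` or `"wrap"`.
#' @param pixel_size_um pixel size used to convert between px and um.
#' @return An object of class `filter_spec` with elements `sigma_px`,
#'   `sigma_um` (NA when no pixel size is known), `kernel_size_px`, `boundary`.
#' @examples
#' filter_spec(sigma_px = 5)$kernel_size_px  # 31
#' @export
filter_spec <- function(sigma_px = NULL, sigma_um = NULL, boundary = "reflect",
                        pixel_size_um = NULL) {
  boundary <- match.arg(boundary, c("reflect", "nearest", "wrap"))
  if (is.null(sigma_px) == is.null(sigma_um)) {
    stop("give exactly one of `sigma_px` or `sigma_um`", call. = FALSE)
  }
  if (is.null(sigma_px)) {
    if (is.null(pixel_size_um)) {
      stop("`sigma_um` requires `pixel_size_um`", call. = FALSE)
    }
    sigma_px <- sigma_um / pixel_size_um
  } else if (!is.null(pixel_size_um)) {
    sigma_um <- sigma_px * pixel_size_um
  }
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px <= 0) {
    stop("`sigma_px` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      sigma_px = sigma_px,
      sigma_um = if (is.null(sigma_um)) NA_real_ else sigma_um,
      kernel_size_px = kernel_size_px(sigma_px),
      boundary = boundary
    ),
    class = "filter_spec"
  )
}

#' Kernel box size for a Gaussian standard deviation
#'
#' The odd integer nearest to `6 * sigma_px + 1` (ties rounded up).
#'
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return Odd integer kernel size in pixels.
#' @examples
#' kernel_size_px(5)    # 31
#' kernel_size_px(2.5)  # 17
#' @export
kernel_size_px <- function(sigma_px) {
  target <- 6 * sigma_px + 1
  lo <- 2 * floor((target - 1) / 2) + 1
  hi <- lo + 2
  if (target - lo < hi - target) lo else hi
}

#' Discrete truncated Gaussian kernel weights
#'
#' @param sigma_px standard deviation in pixels.
#' @return Numeric vector of length [kernel_size_px()] summing to 1.
#' @export
gaussian_kernel <- function(sigma_px) {
  r <- (kernel_size_px(sigma_px) - 1L) %/% 2L
  w <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  w / sum(w)
}

# 1D smoothing operator (n x n) for the truncated kernel with the chosen
# boundary rule; smoothing is then S %*% Z %*% t(S).
smoothing_operator <- function(n, sigma_px, boundary) {
  k <- kernel_size_px(sigma_px)
  if (k > n) {
    stop(sprintf("kernel (%d px) larger than image (%d px)", k, n),
         call. = FALSE)
  }
  r <- (k - 1L) %/% 2L
  w <- gaussian_kernel(sigma_px)
  S <- matrix(0, n, n)
  for (t in -r:r) {
    j <- seq_len(n) + t
    j <- switch(boundary,
      reflect = {
        j <- ifelse(j < 1, 1 - j, j)        # ... c b a | a b c ...
        ifelse(j > n, 2 * n + 1 - j, j)
      },
      nearest = pmin(pmax(j, 1), n),
      wrap = ((j - 1) %% n) + 1
    )
    S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + w[t + r + 1]
  }
  S
}

#' Gaussian smoothing of a height map
#'
#' Separable convolution with the truncated Gaussian kernel of
#' [filter_spec()]. Weights are normalized to sum to 1, so constant fields are
#' fixed points, and (away from the boundary) so are linear ramps.
#'
#' @param map a [heightmap()].
#' @param spec a [filter_spec()].
#' @return A [heightmap()] of the smoothed field, same metadata.
#' @export
gaussian_smooth <- function(map, spec) {
  stopifnot(inherits(map, "heightmap"), inherits(spec, "filter_spec"))
  S <- smoothing_operator(nrow(map$z), spec$sigma_px, spec$boundary)
  out <- map
  out$z <- S %*% map$z %*% t(S)
  out
}

#' Gaussian filtering residual (high-pass roughness field)
#'
#' `original - smoothed`, elementwise. The residual keeps structure at spatial
#' scales smaller than the kernel box (with some leakage), which is the field
#' the RMS-deviation variograms are computed on.
#'
#' @inheritParams gaussian_smooth
#' @return A [heightmap()] of the residual field, same metadata.
#' @examples
#' hm <- heightmap(matrix(rnorm(128^2), 128), scan_size_um = 50)
#' res <- gaussian_residual(hm, filter_spec(sigma_px = 5))
#' var(as.vector(res$z)) < var(as.vector(hm$z))
#' @export
gaussian_residual <- function(map, spec) {
  sm <- gaussian_smooth(map, spec)
  sm$z <- map$z - sm$z
  sm
}
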