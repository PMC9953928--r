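#' Height-map raster with physical metadata
#'
#' A `heightmap` wraps a square numeric matrix of z-values together with the
#' physical pixel size and channel metadata of an AFM scan. Rows are the y
#' (slow-scan) axis, columns the x (fast-scan) axis; the origin is the
#' top-left pixel and indices are 0-based when expressed as coordinates, so
#' `x_um = col0 * pixel_size_um`.
#'
#' @param values square numeric matrix of z-values (all finite). Analysis
#'   operations have their own minimum-size requirements; the container
#'   itself accepts any square matrix (the working resolutions are 128, 256
#'   and 512 px).
#' @param scan_size_um physical edge length of the scanned area in micrometres.
#' @param channel one of `"height"`, `"amplitude"`, `"phase"`.
#' @param value_units units of `values`; defaults to `"um"` for height and
#'   amplitude channels and `"deg"` for phase.
#' @param sample_id optional sample identifier (e.g. `"m1.1"`, `"nm2.4"`).
#'
#' @return An object of class `heightmap`: a list with elements `z`
#'   (the matrix), `pixel_size_um`, `scan_size_um`, `channel`, `value_units`
#'   and `sample_id`.
#' @examples
#' hm <- heightmap(matrix(rnorm(64^2), 64), scan_size_um = 50)
#' hm$pixel_size_um
#' @export
heightmap <- function(values, scan_size_um, channel = "height",
                      value_units = NULL, sample_id = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (ncol(values) != n) {
    stop(sprintf("`values` must be square, got %d x %d", n, ncol(values)),
         call. = FALSE)
  }
  if (n < 1) stop("`values` must be non-empty", call. = FALSE)
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop(sprintf("non-finite value at row %d, column %d (%d cell(s) affected)",
                 ij[1], ij[2], length(bad)), call. = FALSE)
  }
  if (!is.numeric(scan_size_um) || length(scan_size_um) != 1 || scan_size_um <= 0) {
    stop("`scan_size_um` must be a single positive number", call. = FALSE)
  }
  channel <- match.arg(channel, c("height", "amplitude", "phase"))
  if (is.null(value_units)) {
    value_units <- if (channel == "phase") "deg" else "um"
  }
  structure(
    list(
      z = unname(values),
      pixel_size_um = scan_size_um / n,
      scan_size_um = scan_size_um,
      channel = channel,
      value_units = value_units,
      sample_id = sample_id
    ),
    class = "heightmap"
  )
}

#' @export
print.heightmap <- function(x, ...) {
  n <- nrow(x$z)
  cat(sprintf(
    "<heightmap> %s channel, %d x %d px, %.4g um scan (%.4g nm/px)%s\n",
    x$channel, n, n, x$scan_size_um, 1000 * x$pixel_size_um,
    if (is.na(x$sample_id)) "" else paste0(", sample ", x$sample_id)
  ))
  cat(sprintf("  z [%s]: min %.4g, mean %.4g, max %.4g\n",
              x$value_units, min(x$z), mean(x$z), max(x$z)))
  invisible(x)
}

#' @export
dim.heightmap <- function(x) dim(x$z)

#' Convert a height map to a long tibble
#'
#' @param x a [heightmap()].
#' @param ... unused.
#' @return A tibble with columns `x_um`, `y_um`, `z` (one row per pixel).
#' @importFrom tibble as_tibble
#' @method as_tibble heightmap
#' @export
as_tibble.heightmap <- function(x, ...) {
  n <- nrow(x$z)
  coord <- (seq_len(n) - 1) * x$pixel_size_um
  tibble::tibble(
    x_um = rep(coord, each = n),
    y_um = rep(coord, times = n),
    z = as.vector(x$z)
  )
}

#' Block-mean downsampling of a height map
#'
#' Decimates an n x n map to `target_n` x `target_n` by averaging
#' non-overlapping square blocks. The physical scan size is preserved, so the
#' pixel size grows by the decimation factor. Block means average exactly to
#' the global mean, so the grid mean is preserved.
#'
#' @param map a [heightmap()].
#' @param target_n target points per axis; must divide `nrow(map$z)`.
#' @return A [heightmap()] of size `target_n`.
#' @examples
#' hm <- heightmap(matrix(rnorm(64^2), 64), scan_size_um = 50)
#' mean(downsample(hm, 32)$z) - mean(hm$z)  # 0
#' @export
downsample <- function(map, target_n) {
  stopifnot(inherits(map, "heightmap"))
  n <- nrow(map$z)
  if (!is.numeric(target_n) || length(target_n) != 1 || target_n < 1 ||
      target_n != round(target_n) || n %% target_n != 0) {
    stop(sprintf("`target_n` (%s) must be a positive integer divisor of n = %d",
                 format(target_n), n), call. = FALSE)
  }
  k <- n %/% target_n
  if (k == 1) return(map)
  blocks <- array(map$z, dim = c(k, target_n, k, target_n))
  zd <- apply(blocks, c(2, 4), mean)
  heightmap(zd, scan_size_um = map$scan_size_um, channel = map$channel,
            value_units = map$value_units, sample_id = map$sample_id)
}
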