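#' Read a raster with its metadata sidecar
#'
#' Two plain interchange backends, chosen by extension:
#'
#' * `.txt` — whitespace-delimited numeric matrix (Gwyddion-style ASCII
#'   export), exact to the written precision.
#' * `.tif` / `.tiff` — grayscale 32-bit float TIFF holding min-max
#'   normalized values; the affine scale (`z_min`, `z_max`) lives in the
#'   sidecar and is undone on read (exact to float32 precision).
#'
#' Metadata comes from a YAML sidecar `<path>.yaml` (keys `scan_size_um`,
#' `channel`, optional `value_units`, `sample_id`, `z_min`, `z_max`) or from
#' the `metadata` argument (a named list with the same keys).
#'
#' @param path raster file path.
#' @param metadata optional named list overriding the sidecar.
#' @return A [heightmap()] with `pixel_size_um = scan_size_um / n`.
#' @seealso [write_raster()]
#' @export
read_raster <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(metadata)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      stop("metadata sidecar not found: ", sidecar, call. = FALSE)
    }
    metadata <- yaml::read_yaml(sidecar)
  }
  if (is.null(metadata$scan_size_um)) {
    stop("metadata must provide `scan_size_um`", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) != 2) {
      stop("expected a single-channel grayscale TIFF", call. = FALSE)
    }
    if (is.null(metadata$z_min) || is.null(metadata$z_max)) {
      stop("TIFF sidecar must provide `z_min` and `z_max`", call. = FALSE)
    }
    vals <- img * (metadata$z_max - metadata$z_min) + metadata$z_min
  } else {
    vals <- as.matrix(utils::read.table(path, header = FALSE,
                                        colClasses = "numeric"))
    dimnames(vals) <- NULL
  }
  if (nrow(vals) != ncol(vals)) {
    stop(sprintf("non-square grid: %d x %d", nrow(vals), ncol(vals)),
         call. = FALSE)
  }
  heightmap(vals,
            scan_size_um = metadata$scan_size_um,
            channel = metadata$channel %||% "height",
            value_units = metadata$value_units,
            sample_id = metadata$sample_id %||% NA_character_)
}

#' Write a raster with its metadata sidecar
#'
#' Text rasters are written at full double precision (`%.17g`), so
#' `read_raster(write_raster(m))` reproduces the values bit-exactly. The
#' TIFF backend stores min-max normalized 32-bit floats plus the scale in
#' the sidecar, exact to float32 resolution. Both formats write a YAML
#' sidecar `<path>.yaml` carrying `n_px`, `scan_size_um`, `channel`,
#' `value_units` and `sample_id`.
#'
#' @param map a [heightmap()].
#' @param path output path ending in `.txt`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(map, path) {
  stopifnot(inherits(map, "heightmap"))
  meta <- list(
    n_px = nrow(map$z),
    scan_size_um = map$scan_size_um,
    channel = map$channel,
    value_units = map$value_units
  )
  if (!is.na(map$sample_id)) meta$sample_id <- map$sample_id
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    zmin <- min(map$z)
    zmax <- max(map$z)
    norm <- if (zmax > zmin) (map$z - zmin) / (zmax - zmin) else map$z * 0
    tiff::writeTIFF(norm, path, bits.per.sample = 32L)
    meta$z_min <- zmin
    meta$z_max <- zmax
  } else {
    lines <- apply(map$z, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = " ")
    })
    writeLines(lines, path)
  }
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Write a cohort to disk (rasters plus manifest)
#'
#' @param cohort tibble from [generate_cohort()] (columns `sample_id`,
#'   `label`, `map`).
#' @param dir output directory (created if needed).
#' @param format `"txt"` (default) or `"tif"`.
#' @return Path of the written `manifest.csv` (columns `sample_id`, `label`,
#'   `path`), invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("txt", "tif")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map2_chr(cohort$map, cohort$sample_id, function(m, id) {
    p <- file.path(dir, paste0(id, ".", format))
    write_raster(m, p)
    p
  })
  manifest <- tibble::tibble(sample_id = cohort$sample_id,
                             label = cohort$label, path = paths)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a manifest CSV with columns `sample_id`, `label`,
#'   `path` (paths relative to the manifest's directory or absolute).
#' @return A cohort tibble (`sample_id`, `label`, `map` list-column).
#' @export
read_cohort <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  base <- dirname(manifest)
  maps <- purrr::map2(man$path, man$sample_id, function(p, id) {
    if (!file.exists(p)) p <- file.path(base, p)
    m <- read_raster(p)
    m$sample_id <- id
    m
  })
  tibble::tibble(sample_id = man$sample_id, label = man$label, map = maps)
}
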