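#' Analysis configuration
#'
#' Bundles every tunable of the filtering -> variogram -> sill -> theta ->
#' baseline -> classification pipeline, with the defaults used throughout:
#' sigma 5 px (the 31 px kernel), radial bins of 1 px up to n/4, moments
#' `c(0.5, 1, 2, 3, 4, 5)`, plateau mean over the trailing 30% of lags,
#' Welch t-test. `sigma_um` (exclusive with `sigma_px`) is resolved per map
#' via its pixel size, so the same physical cut-off can be applied across
#' resolutions.
#'
#' @param sigma_px Gaussian sd in pixels (default 5).
#' @param sigma_um Gaussian sd in um (alternative to `sigma_px`).
#' @param boundary boundary rule for the smoother; default `"reflect"`.
#' @param max_lag_px maximum radial lag in px; default `NULL` = n/4.
#' @param bin_width_px radial bin width in px; default 1.
#' @param q_list variogram moments; default `c(0.5, 1, 2, 3, 4, 5)`.
#' @param plateau_fraction trailing lag fraction for the sill; default 0.3.
#' @param t_test `"welch"` or `"student"`.
#' @param bin_width_deg theta histogram bin width; default 1.
#' @param baselines compute the baseline battery too; default TRUE.
#' @return A list of class `vario_config`.
#' @export
vario_config <- function(sigma_px = 5, sigma_um = NULL, boundary = "reflect",
                         max_lag_px = NULL, bin_width_px = 1,
                         q_list = c(0.5, 1, 2, 3, 4, 5),
                         plateau_fraction = 0.3, t_test = "welch",
                         bin_width_deg = 1, baselines = TRUE) {
  if (!is.null(sigma_um)) sigma_px <- NULL
  structure(
    list(sigma_px = sigma_px, sigma_um = sigma_um, boundary = boundary,
         max_lag_px = max_lag_px, bin_width_px = bin_width_px,
         q_list = q_list, plateau_fraction = plateau_fraction,
         t_test = t_test, bin_width_deg = bin_width_deg,
         baselines = baselines),
    class = "vario_config"
  )
}

resolve_filter <- function(map, config) {
  filter_spec(sigma_px = config$sigma_px, sigma_um = config$sigma_um,
              boundary = config$boundary, pixel_size_um = map$pixel_size_um)
}

#' Per-sample sill indexes of a cohort
#'
#' For every sample: Gaussian residual, shared binned base curve, one
#' plateau sill per moment.
#'
#' @param cohort cohort tibble (`sample_id`, `label`, `map`).
#' @param config a [vario_config()].
#' @return Long tibble: `sample_id`, `label`, `moment_q`, `sill`, `rising`.
#' @export
cohort_sills <- function(cohort, config = vario_config()) {
  purrr::pmap_dfr(cohort, function(sample_id, label, map, ...) {
    res <- gaussian_residual(map, resolve_filter(map, config))
    prof <- moment_sill_profile(
      res, q_list = config$q_list, max_lag_px = config$max_lag_px,
      bin_width_px = config$bin_width_px,
      plateau_fraction = config$plateau_fraction)
    tibble::tibble(sample_id = sample_id, label = label,
                   moment_q = prof$moment_q, sill = prof$sill,
                   rising = prof$rising)
  })
}

#' Full cohort analysis
#'
#' Runs the whole pipeline on a labelled (or partially labelled) cohort:
#' residual variogram sills for every moment, theta statistics, optional
#' baseline battery, the per-moment threshold classification sweep and the
#' theta sign calls.
#'
#' @param cohort cohort tibble (`sample_id`, `label`, `map` list-column),
#'   e.g. from [generate_cohort()] or [read_cohort()].
#' @param config a [vario_config()].
#' @return A list of class `cohort_analysis`: `sills` (long per-sample
#'   tibble), `features` (one row per sample: theta markers plus baselines),
#'   `sweep` (per-moment [moment_sweep()] table), `classifier` (the
#'   [fit_threshold()] object at q = 1), `theta_calls`, `config`.
#' @examples
#' \donttest{
#' co <- generate_cohort(3, 3, surface_spec("phantom_rough", n_px = 128),
#'                       seed = 1)
#' an <- analyze_cohort(co, vario_config(baselines = FALSE))
#' glance(an$classifier)
#' }
#' @export
analyze_cohort <- function(cohort, config = vario_config()) {
  sills <- cohort_sills(cohort, config)
  theta <- purrr::pmap_dfr(cohort, function(sample_id, label, map, ...) {
    dplyr::bind_cols(tibble::tibble(sample_id = sample_id, label = label),
                     theta_summary(map))
  })
  features <- theta
  if (isTRUE(config$baselines)) {
    base <- purrr::map_dfr(cohort$map, baseline_features)
    features <- dplyr::bind_cols(theta, base)
  }
  sweep <- moment_sweep(sills, q_list = config$q_list, t_test = config$t_test)
  q_main <- if (1 %in% config$q_list) 1 else config$q_list[1]
  q1 <- dplyr::filter(sills, .data$moment_q == q_main)
  classifier <- fit_threshold(q1, q = q_main, t_test = config$t_test)
  structure(
    list(sills = sills, features = features, sweep = sweep,
         classifier = classifier, theta_calls = theta_call(features),
         config = config),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d samples, %d moments\n",
              dplyr::n_distinct(x$sills$sample_id),
              dplyr::n_distinct(x$sills$moment_q)))
  print(x$classifier)
  invisible(x)
}
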