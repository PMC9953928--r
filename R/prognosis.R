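#' Midpoint-threshold sill classifier
#'
#' Fits the two-group threshold rule on per-sample sill indexes: the group
#' mean sill is computed for each labelled class, the threshold is the median
#' of the two group means (their midpoint), and every sample — labelled or
#' unknown — is called `non_metastatic` if its sill lies above the threshold
#' and `metastatic` below it (ties are called non-metastatic, conservative
#' toward follow-up, and flagged). Group separation of the labelled sills is
#' quantified with a two-sample t-test (Welch by default).
#'
#' A valid orientation requires the non-metastatic group mean to exceed the
#' metastatic one (rougher fine texture, higher residual sill); otherwise the
#' result is flagged `inverted`.
#'
#' @param samples data frame with columns `sample_id`, `label`
#'   (`"metastatic"`, `"non_metastatic"` or `"unknown"`) and `sill`.
#' @param q moment the sills belong to (annotation only); default NA.
#' @param t_test `"welch"` (unequal variance, default) or `"student"`.
#' @return An object of class `sill_classifier`; see [tidy.sill_classifier()]
#'   and [glance.sill_classifier()].
#' @examples
#' sam <- tibble::tibble(
#'   sample_id = c("m1.1", "m1.2", "m1.3", "nm1.1", "nm1.2", "x"),
#'   label = c(rep("metastatic", 3), rep("non_metastatic", 2), "unknown"),
#'   sill = c(0.40, 0.50, 0.45, 0.70, 0.90, 0.60))
#' fit <- fit_threshold(sam)
#' fit$threshold              # 0.625
#' tidy(fit)$call             # the 0.60 sample is called metastatic
#' @export
fit_threshold <- function(samples, q = NA_real_, t_test = c("welch", "student")) {
  t_test <- match.arg(t_test)
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "label", "sill")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns sample_id, label, sill", call. = FALSE)
  }
  bad <- setdiff(unique(samples$label),
                 c("metastatic", "non_metastatic", "unknown"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  met <- samples$sill[samples$label == "metastatic"]
  nonmet <- samples$sill[samples$label == "non_metastatic"]
  if (length(met) < 2 || length(nonmet) < 2) {
    stop("need at least 2 labelled samples per class", call. = FALSE)
  }
  mean_met <- mean(met)
  mean_nonmet <- mean(nonmet)
  threshold <- stats::median(c(mean_met, mean_nonmet))  # midpoint of two means
  call <- ifelse(samples$sill >= threshold, "non_metastatic", "metastatic")
  tied <- samples$sill == threshold
  labelled <- samples$label != "unknown"
  mis <- samples$sample_id[labelled & call != samples$label]
  degenerate <- stats::var(met) == 0 && stats::var(nonmet) == 0
  tt <- if (!degenerate) {
    stats::t.test(nonmet, met, var.equal = (t_test == "student"))
  } else NULL
  pooled_sd <- sqrt(((length(met) - 1) * stats::var(met) +
                       (length(nonmet) - 1) * stats::var(nonmet)) /
                      (length(met) + length(nonmet) - 2))
  structure(
    list(
      q = q,
      group_mean_met = mean_met,
      group_mean_nonmet = mean_nonmet,
      threshold = threshold,
      inverted = mean_nonmet <= mean_met,
      calls = tibble::tibble(
        sample_id = samples$sample_id,
        label = samples$label,
        sill = samples$sill,
        call = call,
        tied = tied,
        correct = ifelse(labelled, call == samples$label, NA)
      ),
      misclassified = mis,
      n_met = length(met),
      n_nonmet = length(nonmet),
      separation = (mean_nonmet - mean_met) / mean_met,
      cohen_d = if (pooled_sd > 0) (mean_nonmet - mean_met) / pooled_sd
                else NA_real_,
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      p_degenerate = degenerate,
      t_test = t_test
    ),
    class = "sill_classifier"
  )
}

#' @export
print.sill_classifier <- function(x, ...) {
  cat(sprintf(
    "<sill_classifier> q = %s: threshold %.4g (met mean %.4g, non-met mean %.4g)%s\n",
    format(x$q), x$threshold, x$group_mean_met, x$group_mean_nonmet,
    if (x$inverted) " [INVERTED]" else ""))
  nlab <- sum(x$calls$label != "unknown")
  cat(sprintf("  %d/%d labelled samples called correctly; %s p = %.3g\n",
              nlab - length(x$misclassified), nlab, x$t_test, x$p_value))
  invisible(x)
}

#' Per-sample calls of a sill classifier
#'
#' @param x a [fit_threshold()] result.
#' @param ... unused.
#' @return Tibble with one row per sample: `sample_id`, `label`, `sill`,
#'   `call`, `tied`, `correct` (NA for unknowns).
#' @method tidy sill_classifier
#' @export
tidy.sill_classifier <- function(x, ...) x$calls

#' One-row summary of a sill classifier
#'
#' @param x a [fit_threshold()] result.
#' @param ... unused.
#' @return One-row tibble: `q`, `group_mean_met`, `group_mean_nonmet`,
#'   `threshold`, `inverted`, `n_correct`, `n_labelled`, `separation`
#'   (gap relative to the metastatic group mean), `cohen_d`, `statistic`,
#'   `p_value`.
#' @method glance sill_classifier
#' @export
glance.sill_classifier <- function(x, ...) {
  nlab <- sum(x$calls$label != "unknown")
  tibble::tibble(
    q = x$q,
    group_mean_met = x$group_mean_met,
    group_mean_nonmet = x$group_mean_nonmet,
    threshold = x$threshold,
    inverted = x$inverted,
    n_correct = nlab - length(x$misclassified),
    n_labelled = nlab,
    separation = x$separation,
    cohen_d = x$cohen_d,
    statistic = x$statistic,
    p_value = x$p_value
  )
}

#' Threshold classification across variogram moments
#'
#' One [fit_threshold()] per moment q, on a long table of per-sample sills.
#' Reports, per q, the relative group separation (gap between the group mean
#' sills divided by the metastatic group mean) so that the growth of the
#' separation with q — and threshold-side flips of borderline samples at
#' higher moments — can be checked on cohorts. Per-q p-values are not
#' corrected for multiple testing by default; `bonferroni = TRUE` multiplies
#' them by the number of moments.
#'
#' @param sills long data frame with columns `sample_id`, `label`,
#'   `moment_q`, `sill`.
#' @param q_list moments to fit; default all present in `sills`.
#' @param bonferroni apply Bonferroni correction across moments; default
#'   FALSE.
#' @inheritParams fit_threshold
#' @return A tibble with one [glance.sill_classifier()] row per q, plus a
#'   `misclassified` list-column.
#' @export
moment_sweep <- function(sills, q_list = NULL, t_test = c("welch", "student"),
                         bonferroni = FALSE) {
  t_test <- match.arg(t_test)
  sills <- tibble::as_tibble(sills)
  if (is.null(q_list)) q_list <- sort(unique(sills$moment_q))
  if (!all(q_list %in% sills$moment_q)) {
    stop("`sills` does not cover all requested moments", call. = FALSE)
  }
  out <- purrr::map_dfr(q_list, function(q) {
    sub <- dplyr::filter(sills, .data$moment_q == q)
    fit <- fit_threshold(sub, q = q, t_test = t_test)
    g <- glance(fit)
    g$misclassified <- list(fit$misclassified)
    g
  })
  if (bonferroni) {
    out$p_value <- pmin(out$p_value * length(q_list), 1)
  }
  out
}

#' Theta-skewness sign calls
#'
#' Secondary marker: positive theta-distribution skewness is called
#' metastatic-like (smoother, de-structured texture piles facet angles near
#' zero with a long right tail), non-positive skewness non-metastatic-like.
#' Reports the agreement rate with the labels where present.
#'
#' @param samples data frame with columns `sample_id`, `label`,
#'   `theta_skewness`.
#' @return A tibble with `sample_id`, `label`, `theta_skewness`, `call`;
#'   attribute `agreement` (fraction of labelled samples whose call matches).
#' @examples
#' theta_call(tibble::tibble(sample_id = c("a", "b"),
#'                           label = c("metastatic", "non_metastatic"),
#'                           theta_skewness = c(0.8, -0.3)))
#' @export
theta_call <- function(samples) {
  samples <- tibble::as_tibble(samples)
  req <- c("sample_id", "label", "theta_skewness")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns sample_id, label, theta_skewness",
         call. = FALSE)
  }
  out <- dplyr::mutate(
    dplyr::select(samples, dplyr::all_of(req)),
    call = ifelse(.data$theta_skewness > 0, "metastatic", "non_metastatic")
  )
  lab <- out$label != "unknown"
  attr(out, "agreement") <- if (any(lab)) {
    mean(out$call[lab] == out$label[lab])
  } else NA_real_
  out
}
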