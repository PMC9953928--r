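sample_table <- function(met, nonmet, unknown = numeric(0)) {
  tibble::tibble(
    sample_id = c(sprintf("m%d", seq_along(met)),
                  sprintf("nm%d", seq_along(nonmet)),
                  sprintf("u%d", seq_along(unknown))),
    label = c(rep("metastatic", length(met)),
              rep("non_metastatic", length(nonmet)),
              rep("unknown", length(unknown))),
    sill = c(met, nonmet, unknown)
  )
}

test_that("the midpoint threshold and the call rule follow the arithmetic", {
  fit <- fit_threshold(sample_table(c(0.40, 0.50, 0.45), c(0.70, 0.90),
                                    unknown = 0.60))
  expect_equal(fit$group_mean_met, 0.45)
  expect_equal(fit$group_mean_nonmet, 0.80)
  expect_equal(fit$threshold, 0.625)
  expect_false(fit$inverted)
  calls <- tidy(fit)
  expect_equal(calls$call[calls$sample_id == "u1"], "metastatic")  # 0.60 below
  expect_length(fit$misclassified, 0)
  g <- glance(fit)
  expect_equal(g$n_correct, 5)
  expect_equal(g$separation, (0.80 - 0.45) / 0.45)
})

test_that("the t statistic and p-value match the Welch closed form", {
  # groups {1..5} vs {2..6}: t = -1, df = 8, p = 2*pt(-1, 8) ~ 0.347
  fit <- fit_threshold(sample_table(met = 2:6, nonmet = 1:5))
  expect_equal(fit$statistic, -1, tolerance = 1e-12)
  expect_equal(fit$p_value, 2 * stats::pt(-1, 8), tolerance = 1e-12)
  expect_true(fit$inverted)  # non-met mean below met mean
})

test_that("calls are scale-equivariant and ties go to non-metastatic", {
  tab <- sample_table(c(0.4, 0.5), c(0.8, 0.9), unknown = c(0.3, 0.7))
  fit1 <- fit_threshold(tab)
  tab2 <- tab; tab2$sill <- tab2$sill * 3.7
  fit2 <- fit_threshold(tab2)
  expect_equal(fit2$threshold, 3.7 * fit1$threshold)
  expect_identical(tidy(fit2)$call, tidy(fit1)$call)

  tied <- fit_threshold(sample_table(c(0.4, 0.5), c(0.8, 0.9),
                                     unknown = 0.65))
  tc <- tidy(tied)
  expect_equal(tc$call[tc$sample_id == "u1"], "non_metastatic")
  expect_true(tc$tied[tc$sample_id == "u1"])
})

test_that("degenerate and malformed inputs are caught", {
  expect_error(fit_threshold(sample_table(0.4, c(0.8, 0.9))), "2 labelled")
  expect_error(fit_threshold(tibble::tibble(sample_id = "a", label = "met",
                                            sill = 1)), "label")
  degen <- fit_threshold(sample_table(c(0.4, 0.4), c(0.8, 0.8)))
  expect_true(degen$p_degenerate)
  expect_true(is.na(degen$p_value))
})

test_that("moment sweeps preserve within-group rank order and can flip calls", {
  # per-lag identity: sill(q) = sill(1)^q per sample
  base <- sample_table(c(0.5, 0.6), c(0.9, 1.3), unknown = 0.9)
  long <- purrr::map_dfr(c(0.5, 1, 3), function(q) {
    dplyr::mutate(base, moment_q = q, sill = .data$sill^q)
  })
  sw <- moment_sweep(long)
  expect_equal(sw$q, c(0.5, 1, 3))

  # rank order within each group is invariant under the monotone transform
  for (q in c(0.5, 3)) {
    sub <- dplyr::filter(long, .data$moment_q == q)
    expect_equal(order(sub$sill[sub$label == "metastatic"]),
                 order(base$sill[base$label == "metastatic"]))
  }

  # a sample at the lower edge of the non-met group flips side as q grows:
  # q = 1: 0.9 >= (0.55 + 1.1)/2 -> non-metastatic;
  # q = 3: 0.9^3 = 0.729 < (0.1705 + 1.463)/2 -> metastatic
  fit1 <- fit_threshold(dplyr::filter(long, .data$moment_q == 1), q = 1)
  fit3 <- fit_threshold(dplyr::filter(long, .data$moment_q == 3), q = 3)
  c1 <- tidy(fit1); c3 <- tidy(fit3)
  expect_equal(c1$call[c1$sample_id == "u1"], "non_metastatic")
  expect_equal(c3$call[c3$sample_id == "u1"], "metastatic")

  expect_error(moment_sweep(long, q_list = c(1, 7)), "cover")
  swb <- moment_sweep(long, bonferroni = TRUE)
  expect_true(all(swb$p_value >= sw$p_value))
})

test_that("theta sign calls count their agreement correctly", {
  tab <- tibble::tibble(
    sample_id = c("m1", "m2", "nm1", "nm2", "u1"),
    label = c("metastatic", "metastatic", "non_metastatic", "non_metastatic",
              "unknown"),
    theta_skewness = c(0.8, -0.1, -0.3, 0.2, 0.5)
  )
  tc <- theta_call(tab)
  expect_equal(tc$call,
               c("metastatic", "non_metastatic", "non_metastatic",
                 "metastatic", "metastatic"))
  # hand count over labelled: m1 correct, m2 wrong, nm1 correct, nm2 wrong
  expect_equal(attr(tc, "agreement"), 2 / 4)
})
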