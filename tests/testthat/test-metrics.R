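# Hand-built toy fit tables with known counts exercise every rate exactly.

toy_response <- function() {
  tibble::tibble(
    kind = "response",
    ec50_true = c(1, 1, 1, 1, 0.43, 0.43, 0.43, 0.43),
    noise_fraction = 0.1,
    ec50_hat = c(1, 1, 2, 1, 0.5, 0.1, 1, 0.5),
    p_value = c(0.01, 0.2, 0.01, 0.03, 0.04, 0.2, 0.01, 5e-4)
  )
}

toy_null <- function() {
  tibble::tibble(
    kind = "null",
    ec50_true = NA_real_,
    noise_fraction = rep(c(0.1, 0.5), each = 5),
    ec50_hat = c(0.1, 10, 10, 5, 3, 0.1, 0.1, 10, 2, 8),
    p_value = c(0.2, 0.3, 0.04, 0.5, 0.9, 0.6, 0.7, 0.8, 0.9, 0.02)
  )
}

test_that("model-fit sensitivity and specificity match direct counts", {
  sens <- model_fit_sensitivity(toy_response(), alpha = 0.05)
  # cells keyed by (truth, noise): 3/4 and 3/4 significant
  expect_equal(nrow(sens), 2)
  expect_equal(sens$sensitivity, c(3 / 4, 3 / 4))
  expect_equal(sens$n, c(4L, 4L))

  # Bonferroni: with n_comparisons = 50 only p < 0.001 survives, which is
  # one replicate of the truth-0.43 cell (cells are ordered by truth)
  sens_b <- model_fit_sensitivity(toy_response(), alpha = 0.05,
                                  n_comparisons = 50)
  expect_equal(sens_b$sensitivity, c(1 / 4, 0))

  spec <- model_fit_specificity(toy_null(), alpha = 0.05)
  expect_equal(spec$specificity[spec$noise_fraction == 0.1], 1 - 1 / 5)
  expect_equal(spec$specificity[spec$noise_fraction == 0.5], 1 - 1 / 5)
  all_sig <- toy_null(); all_sig$p_value <- 0.001
  expect_equal(model_fit_specificity(all_sig)$specificity, c(0, 0))
  none_sig <- toy_null(); none_sig$p_value <- 0.5
  expect_equal(model_fit_specificity(none_sig)$specificity, c(1, 1))

  expect_error(model_fit_sensitivity(toy_null()), "no response")
  expect_error(model_fit_specificity(toy_response()), "no null")
})

test_that("in-range correctness brackets off-grid truths and pins on-grid ones", {
  allowed <- c(0.1, 0.5, 1, 2, 3, 4, 5, 6.5, 8, 10)
  expect_true(ec50_in_range(0.43, 0.5, allowed))
  expect_true(ec50_in_range(0.43, 0.1, allowed))
  expect_false(ec50_in_range(0.43, 1.0, allowed))
  # on-grid truth counts only when returned exactly
  expect_true(ec50_in_range(1.0, 1.0, allowed))
  expect_false(ec50_in_range(1.0, 0.5, allowed))
  expect_false(ec50_in_range(1.0, 2.0, allowed))
  # truth between 8 and 10
  expect_equal(ec50_in_range(9.2, c(8, 10, 6.5), allowed),
               c(TRUE, TRUE, FALSE))
  # truth outside the grid range: nearest endpoint
  expect_true(ec50_in_range(0.05, 0.1, allowed))
  expect_false(ec50_in_range(0.05, 0.5, allowed))
  expect_true(ec50_in_range(12, 10, allowed))
  expect_true(is.na(ec50_in_range(NA, 1, allowed)))
})

test_that("EC50 sensitivity counts in-range fractions, NA on empty subsets", {
  allowed <- c(0.1, 0.5, 1, 2)
  es <- ec50_sensitivity(toy_response(), allowed)
  # truth 1 (on-grid): hats 1,1,2,1 -> 3/4; truth 0.43: 0.5,0.1,1,0.5 -> 3/4
  expect_equal(es$ec50_sensitivity[es$ec50_true == 1], 3 / 4)
  expect_equal(es$ec50_sensitivity[es$ec50_true == 0.43], 3 / 4)

  # significant-only: truth 1 -> hats 1,2,1 of which 2/3 in range
  es_sig <- ec50_sensitivity(toy_response(), allowed,
                             restrict_significant = TRUE)
  expect_equal(es_sig$ec50_sensitivity[es_sig$ec50_true == 1], 2 / 3)
  expect_equal(es_sig$n[es_sig$ec50_true == 1], 3L)

  # no significant replicates in a cell: rate is missing, not 0 or 1
  none <- toy_response(); none$p_value <- 0.9
  es_na <- ec50_sensitivity(none, allowed, restrict_significant = TRUE)
  expect_true(all(is.na(es_na$ec50_sensitivity)))
  expect_equal(es_na$n, c(0L, 0L))
})

test_that("EC50 specificity counts returned values among null voxels", {
  allowed <- c(0.1, 2, 10)
  # uncensored: 10 nulls; 0.1 returned 3x, 10 returned 3x, 2 returned 1x
  un <- ec50_specificity(toy_null(), allowed, censor = FALSE)
  expect_equal(un$specificity, 1 - c(3, 1, 3) / 10)
  expect_equal(un$n, rep(10L, 3))

  # censored at p < 0.05: two significant nulls returned 10 and 8
  ce <- ec50_specificity(toy_null(), allowed, censor = TRUE)
  expect_equal(ce$n, rep(2L, 3))
  expect_equal(ce$specificity[ce$ec50_value == 10], 1 - 1 / 2)
  expect_equal(ce$specificity[ce$ec50_value == 0.1], 1)

  # no null passes the threshold: vacuously 100% for every value
  quiet <- toy_null(); quiet$p_value <- 0.5
  vac <- ec50_specificity(quiet, allowed, censor = TRUE)
  expect_equal(vac$specificity, rep(1, 3))
  expect_equal(vac$n, rep(0L, 3))
})

test_that("PPV divides correct returns by total returns per output value", {
  fits <- tibble::tibble(
    kind = "response",
    ec50_true = c(0.43, 0.43, 0.43, 1, 1, 5, 5),
    ec50_hat = c(0.5, 0.5, 0.5, 0.5, 1, 1, 5),
    p_value = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01, 0.2)
  )
  allowed <- c(0.1, 0.5, 1, 5)
  ppv <- ec50_ppv(fits, allowed)
  # 0.5 returned 4x, correct for truth 0.43 (3x), wrong for truth 1 -> 0.75
  expect_equal(ppv$ppv[ppv$ec50_value == 0.5], 3 / 4)
  # 1 returned twice: truth 1 correct, truth 5 wrong -> 0.5
  expect_equal(ppv$ppv[ppv$ec50_value == 1], 1 / 2)
  expect_equal(ppv$ppv[ppv$ec50_value == 5], 1)
  # never-returned values have undefined PPV
  expect_true(is.na(ppv$ppv[ppv$ec50_value == 0.1]))

  # perfect corpus: PPV 1 everywhere it is defined
  perfect <- fits; perfect$ec50_hat <- c(0.5, 0.1, 0.5, 1, 1, 5, 5)
  expect_true(all(ec50_ppv(perfect, allowed)$ppv == 1, na.rm = TRUE))

  # restricting to significant fits drops the p >= alpha rows
  ppv_sig <- ec50_ppv(fits, allowed, restrict_significant = TRUE)
  expect_equal(ppv_sig$times_returned[ppv_sig$ec50_value == 0.5], 3L)
})

test_that("metrics_table assembles every summary for a mixed corpus", {
  fits <- dplyr::bind_rows(toy_response(), toy_null())
  m <- metrics_table(fits, allowed = c(0.1, 0.5, 1, 2), alpha = 0.05)
  expect_s3_class(m, "pd_metrics")
  expect_named(m, c("alpha", "allowed", "model_fit_sensitivity",
                    "ec50_sensitivity_all", "ec50_sensitivity_significant",
                    "ec50_ppv_all", "ec50_ppv_significant",
                    "model_fit_specificity", "ec50_specificity_censored",
                    "ec50_specificity_uncensored"))
  expect_output(print(m), "pd_metrics")
})

test_that("noise/effect ratio estimates noise SD relative to the drug peak", {
  # single-dose session: baseline 0-15 min, infusion at 15 min
  g <- time_grid(800)
  sched <- dose_schedule(15, 1)
  tm <- tissue_model(g, sched, pk_params(30, 0.43), pd_params(25, 1),
                     ref_drift())

  # noiseless curve: ratio exactly 0
  r0 <- noise_effect_ratio(tibble::tibble(time_min = g$time_min,
                                          signal = tm$signal))
  expect_equal(r0$ratio, 0)

  # known noise and peak: ratio approximates sd / peak
  set.seed(12)
  noisy <- tibble::tibble(time_min = g$time_min,
                          signal = tm$signal + rnorm(800, 0, 1.2))
  truth_peak <- max(abs(tm$signal - (1000 + 0.05 * g$time_min)))
  r <- noise_effect_ratio(noisy)
  expect_equal(r$noise_sd, 1.2, tolerance = 0.15)
  expect_equal(r$ratio, 1.2 / truth_peak, tolerance = 0.15)

  # flat baseline with pure noise and no drug effect: ratio near or above 1,
  # the uninformative regime
  flat <- tibble::tibble(time_min = g$time_min,
                         signal = 1000 + rnorm(800, 0, 1))
  expect_gt(noise_effect_ratio(flat)$ratio, 0.2)
})
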