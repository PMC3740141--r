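metric_keys <- function(fits) {
  intersect(c("ec50_true", "noise_fraction", "noise_sd"), names(fits))
}

take_kind <- function(fits, which, fn) {
  if (!"kind" %in% names(fits))
    stop_input("`fits` must have a `kind` column ('response'/'null'); see fit_corpus()")
  out <- fits[fits$kind == which, , drop = FALSE]
  if (nrow(out) == 0) stop_input("%s(): no %s voxels in `fits`", fn, which)
  out
}

#' Model-fit sensitivity
#'
#' The frequency with which the F statistic exceeds the significance
#' threshold among drug-response voxels, per (true EC50, noise level) cell.
#' With `n_comparisons > 1` the threshold is Bonferroni-corrected
#' (`alpha / n_comparisons`); 64000 reproduces a whole-brain voxel count.
#'
#' @param fits A fit table from [fit_corpus()] (needs `kind`, `p_value` and
#'   the truth columns).
#' @param alpha Significance level.
#' @param n_comparisons Bonferroni correction count.
#' @return A tibble with one row per cell: truth keys, `n`, `sensitivity`.
#' @export
model_fit_sensitivity <- function(fits, alpha = 0.05, n_comparisons = 1) {
  fits <- take_kind(fits, "response", "model_fit_sensitivity")
  thr <- alpha / n_comparisons
  fits |>
    group_by(across(dplyr::all_of(metric_keys(fits)))) |>
    summarise(n = dplyr::n(),
              sensitivity = mean(.data$p_value < thr),
              .groups = "drop")
}

#' Model-fit specificity
#'
#' One minus the false-positive frequency: the fraction of drug-free (null)
#' voxels whose F statistic does not exceed the significance threshold, per
#' noise level.
#'
#' @inheritParams model_fit_sensitivity
#' @param overall Also append a pooled row across noise levels (key columns
#'   `NA`).
#' @return A tibble with noise keys, `n`, `specificity`.
#' @export
model_fit_specificity <- function(fits, alpha = 0.05, n_comparisons = 1,
                                  overall = FALSE) {
  fits <- take_kind(fits, "null", "model_fit_specificity")
  thr <- alpha / n_comparisons
  keys <- setdiff(metric_keys(fits), "ec50_true")
  out <- fits |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(n = dplyr::n(),
              specificity = 1 - mean(.data$p_value < thr),
              .groups = "drop")
  if (overall) {
    pooled <- summarise(fits, n = dplyr::n(),
                        specificity = 1 - mean(.data$p_value < thr))
    out <- bind_rows(out, pooled)
  }
  out
}

#' Is a returned (quantized) EC50 in range of the truth?
#'
#' The estimator can only return values from its output grid, so
#' correctness is defined against that grid: a truth lying strictly between
#' two adjacent allowed values makes exactly those two values correct (e.g.,
#' truth 0.43 against the default grid makes 0.1 and 0.5 correct); a truth
#' equal to an allowed value makes only that value correct; a truth outside
#' the grid's range makes the nearest endpoint correct.
#'
#' @param true_ec50,ec50_hat True and returned EC50 (vectorized, recycled).
#' @param allowed The output grid of allowed EC50 values.
#' @return Logical vector.
#' @examples
#' ec50_in_range(0.43, c(0.1, 0.5, 1), allowed = search_grid()$ec50_values)
#' @export
ec50_in_range <- function(true_ec50, ec50_hat,
                          allowed = search_grid()$ec50_values) {
  allowed <- sort(allowed)
  n <- max(length(true_ec50), length(ec50_hat))
  true_ec50 <- rep_len(true_ec50, n)
  ec50_hat <- rep_len(ec50_hat, n)
  vapply(seq_len(n), function(i) {
    tr <- true_ec50[i]
    if (is.na(tr) || is.na(ec50_hat[i])) return(NA)
    hit <- abs(allowed - tr) < 1e-9
    correct <- if (any(hit)) {
      allowed[hit]
    } else if (tr < allowed[1]) {
      allowed[1]
    } else if (tr > allowed[length(allowed)]) {
      allowed[length(allowed)]
    } else {
      lo <- max(allowed[allowed < tr])
      hi <- min(allowed[allowed > tr])
      c(lo, hi)
    }
    any(abs(correct - ec50_hat[i]) < 1e-9)
  }, logical(1))
}

#' EC50 sensitivity
#'
#' The fraction of drug-response voxels whose returned EC50 is in range of
#' the truth (see [ec50_in_range()]), per (true EC50, noise) cell; either
#' over all voxels or restricted to voxels whose model fit is significant.
#' A cell with an empty significant subset yields `NA` (undefined, never 0
#' or 1).
#'
#' @inheritParams model_fit_sensitivity
#' @param allowed Output grid of allowed EC50 values.
#' @param restrict_significant Only count voxels with `p_value < alpha`.
#' @return A tibble with truth keys, `n` (denominator used),
#'   `ec50_sensitivity`.
#' @export
ec50_sensitivity <- function(fits, allowed = search_grid()$ec50_values,
                             restrict_significant = FALSE, alpha = 0.05) {
  fits <- take_kind(fits, "response", "ec50_sensitivity")
  fits$in_range <- ec50_in_range(fits$ec50_true, fits$ec50_hat, allowed)
  fits$counted <- if (restrict_significant) fits$p_value < alpha else TRUE
  fits |>
    group_by(across(dplyr::all_of(metric_keys(fits)))) |>
    summarise(
      n = sum(.data$counted),
      ec50_sensitivity = ifelse(sum(.data$counted) > 0,
                                mean(.data$in_range[.data$counted]), NA_real_),
      .groups = "drop")
}

#' EC50 specificity on drug-free voxels
#'
#' For each allowed output value, one minus the fraction of null voxels for
#' which the estimator returned that value. The censored variant counts only
#' null voxels whose model fit passes the F threshold; if none do, every
#' value's specificity is vacuously 1.
#'
#' @inheritParams ec50_sensitivity
#' @param censor Restrict to null voxels with `p_value < alpha`.
#' @return A tibble with one row per allowed value: `ec50_value`, `n`
#'   (null voxels considered), `times_returned`, `specificity`.
#' @export
ec50_specificity <- function(fits, allowed = search_grid()$ec50_values,
                             censor = TRUE, alpha = 0.05) {
  fits <- take_kind(fits, "null", "ec50_specificity")
  if (censor) fits <- fits[fits$p_value < alpha, , drop = FALSE]
  n_considered <- nrow(fits)
  returned <- vapply(allowed, function(v)
    if (n_considered == 0) 0L else sum(abs(fits$ec50_hat - v) < 1e-9),
    integer(1))
  tibble(ec50_value = allowed, n = n_considered, times_returned = returned,
         specificity = if (n_considered == 0) rep(1, length(allowed)) else
           1 - returned / n_considered)
}

#' Positive predictive value of the returned EC50
#'
#' For each allowed output value v: of all the times the estimator returned
#' v across the drug-response corpus, what fraction came from a truth for
#' which v is in range? Values never returned have an undefined PPV (`NA`).
#'
#' @inheritParams ec50_sensitivity
#' @return A tibble with one row per allowed value: `ec50_value`,
#'   `times_returned`, `times_correct`, `ppv`.
#' @export
ec50_ppv <- function(fits, allowed = search_grid()$ec50_values,
                     restrict_significant = FALSE, alpha = 0.05) {
  fits <- take_kind(fits, "response", "ec50_ppv")
  if (restrict_significant) fits <- fits[fits$p_value < alpha, , drop = FALSE]
  in_range <- ec50_in_range(fits$ec50_true, fits$ec50_hat, allowed)
  out <- map(allowed, function(v) {
    idx <- abs(fits$ec50_hat - v) < 1e-9
    d <- sum(idx)
    tibble(ec50_value = v, times_returned = d,
           times_correct = sum(in_range[idx]),
           ppv = if (d > 0) sum(in_range[idx]) / d else NA_real_)
  })
  bind_rows(out)
}

#' Full operating-characteristic table for a fitted corpus
#'
#' Convenience wrapper assembling the per-cell and per-output-value metrics
#' into one object.
#'
#' @inheritParams ec50_sensitivity
#' @param n_comparisons Bonferroni correction count for the F threshold.
#' @return A list of class `"pd_metrics"` with tibbles
#'   `model_fit_sensitivity`, `model_fit_specificity`, `ec50_sensitivity`
#'   (all voxels and significant-only), `ec50_specificity` (censored and
#'   uncensored, when null voxels are present) and `ec50_ppv` (all and
#'   significant-only), plus the `alpha` and `allowed` values used.
#' @export
metrics_table <- function(fits, allowed = search_grid()$ec50_values,
                          alpha = 0.05, n_comparisons = 1) {
  has_null <- "kind" %in% names(fits) && any(fits$kind == "null")
  has_resp <- "kind" %in% names(fits) && any(fits$kind == "response")
  out <- list(alpha = alpha, allowed = allowed)
  if (has_resp) {
    out$model_fit_sensitivity <- model_fit_sensitivity(fits, alpha, n_comparisons)
    out$ec50_sensitivity_all <- ec50_sensitivity(fits, allowed, FALSE, alpha)
    out$ec50_sensitivity_significant <- ec50_sensitivity(fits, allowed, TRUE, alpha)
    out$ec50_ppv_all <- ec50_ppv(fits, allowed, FALSE, alpha)
    out$ec50_ppv_significant <- ec50_ppv(fits, allowed, TRUE, alpha)
  }
  if (has_null) {
    out$model_fit_specificity <- model_fit_specificity(fits, alpha, n_comparisons)
    out$ec50_specificity_censored <- ec50_specificity(fits, allowed, TRUE, alpha)
    out$ec50_specificity_uncensored <- ec50_specificity(fits, allowed, FALSE, alpha)
  }
  structure(out, class = "pd_metrics")
}

#' @export
print.pd_metrics <- function(x, ...) {
  cat("<pd_metrics> alpha =", x$alpha, "\n")
  for (nm in setdiff(names(x), c("alpha", "allowed"))) {
    cat("\n$", nm, "\n", sep = "")
    print(x[[nm]], n = 5)
  }
  invisible(x)
}

#' Noise-to-effect ratio of a measured time-signal curve
#'
#' Estimates how large the measurement noise is relative to the drug-induced
#' signal, for comparison with the simulated noise/e_max grid: a regression
#' line is fit to the pre-drug baseline window, the standard deviation of
#' its residuals is the noise estimate, and it is divided by the maximal
#' absolute deviation of the post-drug signal from the extrapolated
#' baseline. Because the observed peak effect cannot exceed `|e_max|`, the
#' ratio is an upper bound on noise SD / `|e_max|`.
#'
#' @param data A data frame with `time_min` and `signal`.
#' @param baseline_end_min End of the drug-free baseline window (minutes
#'   from series start).
#' @param post_start_min Start of the post-drug window; defaults to
#'   `baseline_end_min`.
#' @return A one-row tibble with `noise_sd`, `peak_effect`, `ratio`.
#' @export
noise_effect_ratio <- function(data, baseline_end_min = 15,
                               post_start_min = NULL) {
  check_time_df(data, "noise_effect_ratio")
  if (!"signal" %in% names(data)) stop_input("`data` must have a `signal` column")
  if (is.null(post_start_min)) post_start_min <- baseline_end_min
  base <- data[data$time_min <= baseline_end_min, , drop = FALSE]
  post <- data[data$time_min >= post_start_min, , drop = FALSE]
  if (nrow(base) < 3) stop_input("baseline window has fewer than 3 points")
  if (nrow(post) < 1) stop_input("post-drug window is empty")
  line <- lm(signal ~ time_min, data = base)
  noise_sd <- sd(stats::residuals(line))
  pred <- predict(line, newdata = post)
  peak <- max(abs(post$signal - pred))
  tibble(noise_sd = noise_sd, peak_effect = peak,
         ratio = if (peak > 0) noise_sd / peak else ifelse(noise_sd > 0, Inf, 0))
}
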