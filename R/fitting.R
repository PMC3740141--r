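#' Temporal median filter
#'
#' Replaces each sample with the median of the samples in a window of
#' duration `window_s` centered on it; the window is truncated at the ends
#' of the series. The default 45-s window at 3-s sampling is a 15-point
#' running median, which removes isolated spikes while preserving the slow
#' drug-response waveform.
#'
#' @param x Numeric series.
#' @param window_s Window duration in seconds; must be at least `dt_s`.
#' @param dt_s Sampling interval in seconds.
#' @return Filtered series, same length as `x`.
#' @examples
#' median_filter(c(1, 1, 100, 1, 1), window_s = 9, dt_s = 3)
#' @export
median_filter <- function(x, window_s = 45, dt_s = 3) {
  check_number(window_s, "window_s", lower = 0, allow_equal_lower = FALSE)
  check_number(dt_s, "dt_s", lower = 0, allow_equal_lower = FALSE)
  if (window_s < dt_s)
    stop_input("filter window (%g s) is shorter than the sampling interval (%g s)",
               window_s, dt_s)
  k <- floor(window_s / dt_s / 2)
  n <- length(x)
  if (k == 0L || n < 2L) return(x)
  if (2 * k + 1 > n) {
    return(vapply(seq_len(n), function(i)
      median(x[max(1, i - k):min(n, i + k)]), numeric(1)))
  }
  out <- as.numeric(runmed(x, 2L * k + 1L, endrule = "keep"))
  edge <- c(seq_len(k), seq.int(n - k + 1L, n))
  out[edge] <- vapply(edge, function(i)
    median(x[max(1, i - k):min(n, i + k)]), numeric(1))
  out
}

#' Median-filter a time-signal series
#'
#' Data-frame interface to [median_filter()]; the sampling interval is taken
#' from the `time_min` column.
#'
#' @param data A data frame with `time_min` and `signal` columns.
#' @param window_s Window duration in seconds.
#' @return `data` with `signal` replaced by its filtered version and the
#'   original kept as `signal_raw`.
#' @export
median_filter_series <- function(data, window_s = 45) {
  check_time_df(data, "median_filter_series")
  if (!"signal" %in% names(data)) stop_input("`data` must have a `signal` column")
  dt_s <- series_dt_s(data$time_min)
  data <- as_tibble(data)
  data$signal_raw <- data$signal
  data$signal <- median_filter(data$signal, window_s, dt_s)
  data
}

series_dt_s <- function(time_min) {
  dt <- diff(time_min)
  if (length(dt) < 1L || any(dt <= 0) || any(abs(dt - dt[1]) > 1e-8))
    stop_input("`time_min` must be evenly sampled and increasing")
  dt[1] * 60
}

#' Search grid for the nonlinear parameters
#'
#' The quantized output ranges searched exhaustively by [fit_pkpd()]. Each
#' candidate (time shift, EC50, half-life) cell is completed by a linear
#' least-squares fit of the effect amplitude and drift coefficients, so only
#' these three parameters are gridded. The defaults are the output ranges
#' used for the simulation testing; biological multi-dose analyses use
#' `t_half_values = c(30, 5)`.
#'
#' @param t_shift_values Candidate time shifts (minutes).
#' @param ec50_values Candidate EC50 values, strictly increasing
#'   (concentration units relative to the first-dose peak).
#' @param t_half_values Candidate elimination half-lives (minutes). With more
#'   than one candidate the model spends one extra degree of freedom
#'   (`j = 4` instead of 3).
#' @param hill_n Fixed Hill coefficient.
#' @param drift_degree Fixed drift polynomial degree M.
#' @return A list of class `"search_grid"`.
#' @export
search_grid <- function(t_shift_values = seq(0, 1, by = 0.1),
                        ec50_values = c(0.1, 0.5, 1, 2, 3, 4, 5, 6.5, 8, 10),
                        t_half_values = 41,
                        hill_n = 1,
                        drift_degree = 2) {
  if (length(t_shift_values) < 1L || length(ec50_values) < 1L ||
      length(t_half_values) < 1L)
    stop_input("all grid value lists must be non-empty")
  if (is.unsorted(ec50_values, strictly = TRUE))
    stop_input("`ec50_values` must be strictly increasing")
  if (any(ec50_values <= 0) || any(t_half_values <= 0) ||
      any(t_shift_values < 0))
    stop_input("grid values out of range: ec50 > 0, t_half > 0, t_shift >= 0")
  check_number(hill_n, "hill_n", lower = 0, allow_equal_lower = FALSE)
  check_number(drift_degree, "drift_degree", lower = 0)
  structure(list(t_shift_values = sort(t_shift_values),
                 ec50_values = ec50_values,
                 t_half_values = t_half_values,
                 hill_n = hill_n,
                 drift_degree = as.integer(drift_degree)),
            class = "search_grid")
}

# Model df convention: EC50, t_shift and e_max are free (j = 3); searching
# multiple half-life candidates spends one more.
grid_j <- function(grid) 3L + as.integer(length(grid$t_half_values) > 1L)

# Precompute everything that depends only on (time grid, schedule, grid):
# per-cell thin-Q factors for SSE, per-cell QR objects for coefficients,
# and the comparison-polynomial Q. Cells are ordered by the tie-break
# priority (EC50, then t_shift, then half-life candidate order) so the
# first minimum wins ties deterministically.
build_fit_engine <- function(t, schedule, grid) {
  T_ <- length(t)
  M <- grid$drift_degree
  j <- grid_j(grid)
  N <- M + j
  if (N + 1 >= T_) stop_input("series too short for a degree-%d comparison polynomial", N)
  tmax <- max(t)
  drift_basis <- outer(t / tmax, 0:M, `^`)
  qr_drift <- qr(drift_basis)
  Qd <- qr.Q(qr_drift)

  cells <- tidyr::expand_grid(
    ec50 = grid$ec50_values,
    t_shift = grid$t_shift_values,
    th_idx = seq_along(grid$t_half_values)
  )
  cells$t_half <- grid$t_half_values[cells$th_idx]

  n_cells <- nrow(cells)
  Qs <- vector("list", n_cells)
  qrs <- vector("list", n_cells)
  degen <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    conc <- pk_concentration(t, schedule,
                             pk_params(cells$t_half[i], cells$t_shift[i]))
    ecol <- hill_effect(conc, 1, cells$ec50[i], grid$hill_n)
    e_orth <- ecol - Qd %*% crossprod(Qd, ecol)
    nrm <- sqrt(sum(ecol^2))
    degen[i] <- nrm < 1e-10 * sqrt(T_) || sqrt(sum(e_orth^2)) < 1e-7 * max(nrm, 1e-12)
    X <- cbind(ecol, drift_basis)
    qrX <- qr(X)
    qrs[[i]] <- qrX
    Qs[[i]] <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  }
  if (all(degen))
    stop_input("every grid cell is degenerate: the effect regressor is indistinguishable from drift (concentrations far below all candidate EC50s?)")

  Xp <- cbind(1, poly(t, N))
  qrp <- qr(Xp)
  list(t = t, tmax = tmax, M = M, j = j, N = N, n_points = T_,
       cells = cells, Qs = Qs, qrs = qrs, degenerate = degen,
       Qpoly = qr.Q(qrp)[, seq_len(qrp$rank), drop = FALSE],
       schedule = schedule, grid = grid)
}

# Fit every column of Y (already median-filtered) with a prebuilt engine.
# SSE uses mean-centered columns (the intercept is in both model spans) to
# avoid catastrophic cancellation against the large baseline.
batch_grid_fit <- function(Y, engine) {
  Y <- as.matrix(Y)
  V <- ncol(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- colSums(Yc^2)
  n_cells <- nrow(engine$cells)
  sse <- matrix(NA_real_, n_cells, V)
  for (i in seq_len(n_cells)) {
    qty <- crossprod(engine$Qs[[i]], Yc)
    sse[i, ] <- pmax(ss_tot - colSums(qty^2), 0)
  }
  best <- apply(sse, 2, which.min)
  sse_model <- sse[cbind(best, seq_len(V))]
  sse_poly <- pmax(ss_tot - colSums(crossprod(engine$Qpoly, Yc)^2), 0)

  e_max_hat <- numeric(V)
  drift_hat <- vector("list", V)
  degen <- logical(V)
  pw <- (engine$tmax)^(0:engine$M)
  for (v in seq_len(V)) {
    b <- qr.coef(engine$qrs[[best[v]]], Y[, v])
    degen[v] <- engine$degenerate[best[v]] || anyNA(b)
    b[is.na(b)] <- 0
    e_max_hat[v] <- unname(b[1])
    drift_hat[[v]] <- as.numeric(b[-1] / pw)
  }
  ft <- f_test(sse_poly, sse_model, engine$j, engine$n_points)
  tibble(
    ec50_hat = engine$cells$ec50[best],
    t_shift_hat = engine$cells$t_shift[best],
    t_half_hat = engine$cells$t_half[best],
    e_max_hat = e_max_hat,
    drift_hat = drift_hat,
    sse_model = sse_model,
    sse_poly = sse_poly,
    f_stat = ft$f_stat,
    df1 = ft$df1,
    df2 = ft$df2,
    p_value = ft$p_value,
    degenerate = degen,
    n_points = engine$n_points
  )
}

#' Linear least-squares subfit at fixed nonlinear parameters
#'
#' With (EC50, time shift, half-life, Hill n) held fixed, the forward model
#' is linear in the effect amplitude `e_max` and the drift coefficients, so
#' these are solved by ordinary least squares: the design matrix holds the
#' unit-amplitude effect curve and the drift monomials. This is the inner
#' solver of [fit_pkpd()]'s grid search.
#'
#' @param data A data frame with `time_min` and `signal` (already filtered if
#'   desired).
#' @param schedule A [dose_schedule()].
#' @param ec50,t_shift,t_half,hill_n Fixed nonlinear parameter values.
#' @param drift_degree Drift polynomial degree M.
#' @return A one-row tibble: `e_max_hat`, `drift_hat` (list-column,
#'   coefficients `a_0..a_M` in natural units), `sse`, `degenerate`. The fit
#'   is flagged degenerate when the effect regressor is numerically
#'   indistinguishable from drift (e.g., all concentrations far below EC50);
#'   rank-deficient fits use the minimum-norm completion (dropped
#'   coefficients set to zero).
#' @export
linear_subfit <- function(data, schedule = default_dose_schedule(),
                          ec50 = 1, t_shift = 0.43, t_half = 41, hill_n = 1,
                          drift_degree = 2) {
  check_time_df(data, "linear_subfit")
  if (!"signal" %in% names(data)) stop_input("`data` must have a `signal` column")
  g <- search_grid(t_shift_values = t_shift, ec50_values = ec50,
                   t_half_values = t_half, hill_n = hill_n,
                   drift_degree = drift_degree)
  engine <- build_fit_engine(data$time_min, schedule, g)
  y <- data$signal
  b <- qr.coef(engine$qrs[[1]], y)
  degen <- engine$degenerate[1] || anyNA(b)
  b[is.na(b)] <- 0
  r <- qr.resid(engine$qrs[[1]], y)
  tibble(e_max_hat = unname(b[1]),
         drift_hat = list(as.numeric(b[-1] / engine$tmax^(0:engine$M))),
         sse = sum(r^2),
         degenerate = degen)
}

#' Comparison polynomial fit
#'
#' Least-squares fit of a degree-`degree` polynomial in time — the null
#' model, which knows nothing about the dose timing. Its degree defaults to
#' `N = M + j` so that it spends the same number of degrees of freedom as
#' the PK-PD model.
#'
#' @param data A data frame with `time_min` and `signal`.
#' @param degree Polynomial degree N; must satisfy `degree + 1 < nrow(data)`.
#' @return A one-row tibble with `degree` and `sse_poly`.
#' @export
comparison_poly_fit <- function(data, degree = 5) {
  check_time_df(data, "comparison_poly_fit")
  if (!"signal" %in% names(data)) stop_input("`data` must have a `signal` column")
  check_number(degree, "degree", lower = 0)
  if (degree + 1 >= nrow(data))
    stop_input("degree %d polynomial needs more than %d points", degree, degree + 1)
  X <- cbind(1, poly(data$time_min, degree))
  r <- qr.resid(qr(X), data$signal)
  tibble(degree = as.integer(degree), sse_poly = sum(r^2))
}

#' F-ratio test of model fit against the comparison polynomial
#'
#' The test statistic is the ratio of the comparison polynomial's summed
#' squared error to the PK-PD model's, `F = sse_poly / sse_model`; larger
#' values mean the model (which knows the dose times) fits better than a
#' curve of equal flexibility that does not. The p-value is the upper tail
#' of the F distribution with `j` and `n_points - j - 2` degrees of freedom.
#' Conventions for degenerate inputs: both SSEs zero gives `f = 1, p = 1`;
#' a perfect model fit against a nonzero polynomial SSE gives `f = Inf,
#' p = 0`.
#'
#' @param sse_poly,sse_model Summed squared errors (vectorized).
#' @param j Number of PK-PD model parameters (default 3: EC50, time shift,
#'   e_max).
#' @param n_points Number of time points in the series; must exceed `j + 2`.
#' @return A tibble with `f_stat`, `df1`, `df2`, `p_value`.
#' @export
f_test <- function(sse_poly, sse_model, j = 3, n_points = 800) {
  if (any(sse_poly < 0) || any(sse_model < 0))
    stop_input("summed squared errors must be >= 0")
  check_number(j, "j", lower = 1)
  check_number(n_points, "n_points", lower = 0)
  if (n_points <= j + 2)
    stop_input("need more than j + 2 = %d time points, got %d", j + 2, n_points)
  df2 <- n_points - j - 2
  len <- max(length(sse_poly), length(sse_model))
  sse_poly <- rep_len(sse_poly, len)
  sse_model <- rep_len(sse_model, len)
  f <- ifelse(sse_model == 0,
              ifelse(sse_poly == 0, 1, Inf),
              sse_poly / sse_model)
  p <- pf(f, j, df2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  p[sse_model == 0 & sse_poly == 0] <- 1
  tibble(f_stat = f, df1 = as.integer(j), df2 = as.integer(df2), p_value = p)
}

#' Fit the PK-PD model to one time-signal curve
#'
#' The estimator: the series is median-filtered, then every cell of the
#' quantized (time shift x EC50 x half-life) grid is completed by the linear
#' least-squares subfit and the global minimizer of the summed squared error
#' is returned, together with the comparison-polynomial fit, the F ratio and
#' its p-value. Exact SSE ties are resolved toward smaller EC50, then
#' smaller time shift, then the earlier half-life candidate.
#'
#' @param data A data frame with `time_min` and `signal` columns.
#' @param schedule A [dose_schedule()]; must describe the doses actually
#'   given during the acquisition.
#' @param grid A [search_grid()].
#' @param window_s Median-filter window in seconds; `NULL` or `0` skips
#'   filtering (use when `data` is already filtered).
#' @param alpha Significance level used by downstream summaries (stored on
#'   the object; the p-value itself is always reported).
#' @return An object of class `"pkpd_fit"`; see [tidy.pkpd_fit()] and
#'   [glance.pkpd_fit()] for tabular views, and [autoplot.pkpd_fit()] to
#'   plot data and fitted curves.
#' @examples
#' vox <- simulate_voxel(time_grid(), pd = pd_params(10, 1), noise_sd = 0.5,
#'                       seed = 7)
#' fit <- fit_pkpd(vox)
#' glance(fit)
#' @export
fit_pkpd <- function(data, schedule = default_dose_schedule(),
                     grid = search_grid(), window_s = 45, alpha = 0.05) {
  check_time_df(data, "fit_pkpd")
  if (!"signal" %in% names(data)) stop_input("`data` must have a `signal` column")
  t <- data$time_min
  y_raw <- data$signal
  yf <- if (is.null(window_s) || window_s == 0) y_raw else
    median_filter(y_raw, window_s, series_dt_s(t))
  engine <- build_fit_engine(t, schedule, grid)
  res <- batch_grid_fit(matrix(yf, ncol = 1), engine)

  best_drift <- res$drift_hat[[1]]
  fitted_model <- hill_effect(
    pk_concentration(t, schedule, pk_params(res$t_half_hat, res$t_shift_hat)),
    res$e_max_hat, res$ec50_hat, grid$hill_n) +
    poly_eval(best_drift, t)
  Xp <- cbind(1, poly(t, engine$N))
  fitted_poly <- as.numeric(Xp %*% qr.coef(qr(Xp), yf))

  structure(list(
    estimates = res,
    j = engine$j, N = engine$N, n_points = engine$n_points,
    alpha = alpha, window_s = window_s,
    schedule = schedule, grid = grid,
    data = tibble(time_min = t, signal = y_raw, filtered = yf,
                  fitted_model = fitted_model, fitted_poly = fitted_poly)
  ), class = "pkpd_fit")
}

#' @export
print.pkpd_fit <- function(x, ...) {
  e <- x$estimates
  cat("<pkpd_fit>  grid search over",
      length(x$grid$ec50_values) * length(x$grid$t_shift_values) *
        length(x$grid$t_half_values), "cells,", x$n_points, "time points\n")
  cat(sprintf("  EC50 = %g   t_shift = %g min   t_half = %g min   e_max = %.4g\n",
              e$ec50_hat, e$t_shift_hat, e$t_half_hat, e$e_max_hat))
  cat(sprintf("  SSE(model) = %.6g   SSE(poly%d) = %.6g\n",
              e$sse_model, x$N, e$sse_poly))
  cat(sprintf("  F(%d, %d) = %.4g   p = %.4g%s\n", e$df1, e$df2, e$f_stat,
              e$p_value, if (e$degenerate) "   [degenerate effect column]" else ""))
  invisible(x)
}

#' Tidy a PK-PD fit
#'
#' @param x A `"pkpd_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`).
#' @method tidy pkpd_fit
#' @export
tidy.pkpd_fit <- function(x, ...) {
  e <- x$estimates
  drift <- e$drift_hat[[1]]
  tibble(
    term = c("ec50", "t_shift_min", "t_half_min", "e_max",
             paste0("drift_a", seq_along(drift) - 1L)),
    estimate = c(e$ec50_hat, e$t_shift_hat, e$t_half_hat, e$e_max_hat, drift)
  )
}

#' Glance at a PK-PD fit
#'
#' @param x A `"pkpd_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with fit-quality summaries: `sse_model`,
#'   `sse_poly`, `f_stat`, `df1`, `df2`, `p_value`, `n_points`,
#'   `degenerate`.
#' @method glance pkpd_fit
#' @export
glance.pkpd_fit <- function(x, ...) {
  e <- x$estimates
  tibble(sse_model = e$sse_model, sse_poly = e$sse_poly, f_stat = e$f_stat,
         df1 = e$df1, df2 = e$df2, p_value = e$p_value,
         n_points = e$n_points, degenerate = e$degenerate)
}

#' Fit with each candidate half-life and keep the better fit
#'
#' Runs the full grid fit once per elimination half-life candidate (each
#' with its own three-parameter grid) and retains the result with the larger
#' F statistic; an exact tie keeps the first-listed candidate. Used for
#' biological data where the effective half-life is uncertain (e.g.,
#' candidates of 30 and 5 minutes, in case distribution-phase kinetics
#' dominate on the session's time scale).
#'
#' @inheritParams fit_pkpd
#' @param t_half_values Candidate half-lives in minutes, in preference order.
#' @return A `"pkpd_fit"` for the retained candidate, with the candidate set
#'   recorded in `$t_half_candidates`.
#' @export
select_half_life <- function(data, schedule = default_dose_schedule(),
                             t_half_values = c(30, 5), grid = search_grid(),
                             window_s = 45, alpha = 0.05) {
  fits <- map(t_half_values, function(th) {
    g <- grid
    g$t_half_values <- th
    fit_pkpd(data, schedule, g, window_s, alpha)
  })
  fs <- map_dbl(fits, function(f) f$estimates$f_stat)
  best <- fits[[which.max(fs)]]
  best$t_half_candidates <- t_half_values
  best
}

#' Fit the PK-PD model to every voxel of a simulated corpus
#'
#' All voxels share one time grid, dose schedule and search grid, so the
#' design matrices and their factorizations are computed once and the summed
#' squared errors of all voxels evaluated in a batch; results are identical
#' to calling [fit_pkpd()] per voxel.
#'
#' @param corpus A corpus tibble from [simulate_corpus()] (or any tibble with
#'   a `series` list-column of `time_min`/`signal` tibbles).
#' @param schedule A [dose_schedule()]; defaults to the schedule of the
#'   corpus design when present.
#' @param grid A [search_grid()].
#' @param window_s Median-filter window in seconds (`NULL`/`0` to skip).
#' @param alpha Significance level for the `significant` column.
#' @return The corpus manifest (without the series) with fit columns added:
#'   `ec50_hat`, `t_shift_hat`, `t_half_hat`, `e_max_hat`, `sse_model`,
#'   `sse_poly`, `f_stat`, `df1`, `df2`, `p_value`, `significant`,
#'   `degenerate`, `n_points`.
#' @export
fit_corpus <- function(corpus, schedule = NULL, grid = search_grid(),
                       window_s = 45, alpha = 0.05) {
  if (!is.data.frame(corpus) || !"series" %in% names(corpus) ||
      nrow(corpus) == 0)
    stop_input("`corpus` must be a non-empty tibble with a `series` list-column")
  if (is.null(schedule)) {
    design <- attr(corpus, "design")
    schedule <- if (!is.null(design)) design$schedule else default_dose_schedule()
  }
  t <- corpus$series[[1]]$time_min
  same <- map_lgl(corpus$series, function(s)
    length(s$time_min) == length(t) && all(abs(s$time_min - t) < 1e-9))
  if (!all(same)) stop_input("all corpus series must share one time grid")

  Y <- series_matrix(corpus)
  if (!is.null(window_s) && window_s > 0) {
    dt_s <- series_dt_s(t)
    Y <- apply(Y, 2, median_filter, window_s = window_s, dt_s = dt_s)
  }
  engine <- build_fit_engine(t, schedule, grid)
  res <- batch_grid_fit(Y, engine)
  res$significant <- res$p_value < alpha
  manifest <- as_tibble(corpus[setdiff(names(corpus), "series")])
  bind_cols(manifest, res)
}
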