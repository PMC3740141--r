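test_that("median filter matches a direct truncated-window median oracle", {
  # constant series unchanged; one-sample window is the identity
  expect_identical(median_filter(rep(3, 20)), rep(3, 20))
  x <- rnorm(30)
  expect_identical(median_filter(x, window_s = 3, dt_s = 3), x)

  # an isolated spike in a linear series is removed: the output at the
  # spike equals the median of its 15-sample window
  tt <- seq_len(100)
  y <- 0.2 * tt
  y[50] <- y[50] + 100
  f <- median_filter(y, 45, 3)
  win <- 0.2 * (43:57); win[8] <- win[8] + 100
  expect_equal(f[50], median(win))
  expect_lt(abs(f[50] - 0.2 * 50), 0.5)

  # full-series oracle, including the truncated ends
  set.seed(42)
  z <- rnorm(40)
  k <- 3  # 21 s window at 3 s
  oracle <- vapply(seq_along(z), function(i)
    median(z[max(1, i - k):min(40, i + k)]), numeric(1))
  expect_equal(median_filter(z, 21, 3), oracle)

  expect_error(median_filter(z, 1, 3), "shorter than the sampling")

  df <- median_filter_series(tibble::tibble(time_min = tt / 20, signal = y))
  expect_equal(df$signal, f)
  expect_equal(df$signal_raw, y)
})

test_that("linear subfit solves the normal equations at fixed nonlinear parameters", {
  g <- time_grid(800)
  tm <- tissue_model(g, ref_schedule(), ref_pk(0.4), pd_params(10, 1),
                     ref_drift())
  dat <- tibble::tibble(time_min = g$time_min, signal = tm$signal)

  # exact interpolation of a noise-free model
  ex <- linear_subfit(dat, ref_schedule(), ec50 = 1, t_shift = 0.4,
                      t_half = 41, drift_degree = 2)
  expect_equal(ex$e_max_hat, 10, tolerance = 1e-8)
  expect_lt(ex$sse, 1e-10)
  expect_equal(ex$drift_hat[[1]], c(1000, 0.05, 0), tolerance = 1e-6)

  # a pure polynomial yields a null effect amplitude
  dat0 <- tibble::tibble(time_min = g$time_min,
                         signal = 1000 + 0.05 * g$time_min)
  ex0 <- linear_subfit(dat0, ref_schedule(), ec50 = 1, t_shift = 0.4)
  expect_equal(ex0$e_max_hat, 0, tolerance = 1e-8)
  expect_lt(ex0$sse, 1e-10)

  # noisy data: SSE and coefficients match brute-force normal equations
  set.seed(8)
  datn <- tibble::tibble(time_min = g$time_min,
                         signal = tm$signal + rnorm(800, 0, 2))
  fit <- linear_subfit(datn, ref_schedule(), ec50 = 1, t_shift = 0.4)
  conc <- plasma_concentration(g, ref_schedule(), pk_params(41, 0.4))$conc
  X <- cbind(hill_effect(conc, 1, 1, 1), 1, g$time_min, g$time_min^2)
  beta <- solve(crossprod(X), crossprod(X, datn$signal))
  expect_equal(fit$e_max_hat, beta[1], tolerance = 1e-7)
  expect_equal(fit$drift_hat[[1]], beta[-1], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(fit$sse, sum((datn$signal - X %*% beta)^2), tolerance = 1e-9)
})

test_that("comparison polynomial fit is a nested least-squares fit", {
  g <- time_grid(200)
  # an exact degree-N polynomial leaves no residual
  y <- 3 + 0.4 * g$time_min - 0.02 * g$time_min^3
  dat <- tibble::tibble(time_min = g$time_min, signal = y)
  expect_lt(comparison_poly_fit(dat, 3)$sse_poly, 1e-14)

  set.seed(2)
  dat$signal <- y + rnorm(200)
  # SSE non-increasing in degree (nested models)
  sses <- vapply(1:7, function(N) comparison_poly_fit(dat, N)$sse_poly,
                 numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
  # matches an independent lm() oracle
  lm5 <- lm(signal ~ poly(time_min, 5), data = dat)
  expect_equal(comparison_poly_fit(dat, 5)$sse_poly,
               sum(residuals(lm5)^2), tolerance = 1e-10)
  expect_error(comparison_poly_fit(dat[1:4, ], 5), "points")
})

test_that("F ratio and p-value follow the stated conventions", {
  expect_equal(f_test(10, 10, 3, 800)$f_stat, 1)
  ft0 <- f_test(0, 0, 3, 800)
  expect_equal(ft0$f_stat, 1)
  expect_equal(ft0$p_value, 1)
  fti <- f_test(5, 0, 3, 800)
  expect_identical(fti$f_stat, Inf)
  expect_identical(fti$p_value, 0)
  expect_equal(f_test(10, 10, 3, 800)$df2, 795L)
  expect_error(f_test(1, 1, 3, 5), "time points")

  # p = 0.05 exactly at the F(j, T - j - 2) critical point
  fcrit <- qf(0.95, 3, 795)
  expect_equal(f_test(fcrit, 1, 3, 800)$p_value, 0.05, tolerance = 1e-12)

  # agrees with numerical integration of the F density
  p_quad <- integrate(function(x) df(x, 3, 795), lower = 2.5,
                      upper = Inf)$value
  expect_equal(f_test(2.5, 1, 3, 800)$p_value, p_quad, tolerance = 1e-6)
})

test_that("grid fit recovers every on-grid truth exactly from noiseless data", {
  d <- simulation_design(ec50_inputs = search_grid()$ec50_values,
                         noise_fractions = 0, replicates = 1,
                         pk = pk_params(41, 0.4), include_nulls = FALSE,
                         master_seed = 1)
  fits <- fit_corpus(simulate_corpus(d))
  expect_equal(fits$ec50_hat, fits$ec50_true)
  expect_equal(fits$t_shift_hat, rep(0.4, 10))
  expect_equal(fits$t_half_hat, rep(41, 10))
  expect_equal(fits$e_max_hat, rep(10, 10), tolerance = 1e-3)

  # without filtering, the SSE at the truth is numerically zero
  v <- simulate_voxel(time_grid(), pk = pk_params(41, 0.4),
                      pd = pd_params(10, 1), noise_sd = 0)
  f0 <- fit_pkpd(v, window_s = 0)
  expect_lt(f0$estimates$sse_model, 1e-6)
  expect_equal(f0$estimates$ec50_hat, 1)
  expect_gt(f0$estimates$f_stat, 1e3)
})

test_that("off-grid truths resolve to a bracketing output value", {
  # truth 0.43 lies between the allowed outputs 0.1 and 0.5
  v <- simulate_voxel(time_grid(), pd = pd_params(10, 0.43), noise_sd = 0)
  f <- fit_pkpd(v)
  expect_true(f$estimates$ec50_hat %in% c(0.1, 0.5))
  # true t_s = 0.43 resolves to a neighboring grid value
  expect_true(f$estimates$t_shift_hat %in% c(0.4, 0.5))
})

test_that("grid fit equals brute-force enumeration with independent OLS", {
  g <- time_grid(50, dt_s = 60)  # 1-min sampling so all four doses fall inside
  set.seed(31)
  tm <- tissue_model(g, ref_schedule(), ref_pk(0.2), pd_params(8, 2),
                     ref_drift())
  dat <- tibble::tibble(time_min = g$time_min,
                        signal = tm$signal + rnorm(50, 0, 1))
  sg <- search_grid(t_shift_values = c(0, 0.2, 0.4),
                    ec50_values = c(0.5, 2, 5), t_half_values = 41,
                    drift_degree = 2)
  fit <- fit_pkpd(dat, ref_schedule(), sg, window_s = 0)

  cells <- expand.grid(ec50 = sg$ec50_values, t_shift = sg$t_shift_values)
  brute <- apply(cells, 1, function(cell) {
    conc <- plasma_concentration(g, ref_schedule(),
                                 pk_params(41, cell["t_shift"]))$conc
    e1 <- hill_effect(conc, 1, cell["ec50"], 1)
    sum(residuals(lm(dat$signal ~ e1 + g$time_min + I(g$time_min^2)))^2)
  })
  expect_equal(fit$estimates$sse_model, min(brute), tolerance = 1e-9)
  best <- cells[which.min(brute), ]
  expect_equal(fit$estimates$ec50_hat, best$ec50)
  expect_equal(fit$estimates$t_shift_hat, best$t_shift)
})

test_that("the drug regressor never increases the SSE over drift alone", {
  g <- time_grid(300)
  set.seed(77)
  for (i in 1:5) {
    y <- 1000 + 0.05 * g$time_min + rnorm(300, 0, 3)
    dat <- tibble::tibble(time_min = g$time_min, signal = y)
    fit <- fit_pkpd(dat, window_s = 0)
    drift_only <- sum(residuals(lm(y ~ poly(g$time_min, 2)))^2)
    expect_lte(fit$estimates$sse_model, drift_only + 1e-8)
  }
})

test_that("fit results expose tidy() and glance() views", {
  v <- simulate_voxel(time_grid(), pd = pd_params(10, 1), noise_sd = 0.5,
                      seed = 3)
  f <- fit_pkpd(v)
  td <- tidy(f)
  expect_setequal(td$term, c("ec50", "t_shift_min", "t_half_min", "e_max",
                             "drift_a0", "drift_a1", "drift_a2"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$f_stat, gl$sse_poly / gl$sse_model)
  expect_equal(gl$df2, 800L - 3L - 2L)
  expect_s3_class(autoplot(f), "ggplot")
})

test_that("half-life selection retains the candidate with the larger F", {
  # a single candidate is identical to the plain grid fit
  v <- simulate_voxel(time_grid(), pd = pd_params(10, 1), noise_sd = 0.5,
                      seed = 11)
  s1 <- select_half_life(v, t_half_values = 41)
  f1 <- fit_pkpd(v)
  expect_identical(glance(s1), glance(f1))

  # data generated with a 5-min half-life picks 5 over 30 in most replicates
  wins <- vapply(1:9, function(i) {
    vi <- simulate_voxel(time_grid(), ref_schedule(), pk_params(5, 0.43),
                         pd_params(10, 1), ref_drift(), noise_sd = 1,
                         seed = 500 + i)
    select_half_life(vi, t_half_values = c(30, 5))$estimates$t_half_hat
  }, numeric(1))
  expect_gt(mean(wins == 5), 0.5)

  # an exact F tie keeps the first-listed candidate
  tie <- select_half_life(v, t_half_values = c(41, 41))
  expect_equal(tie$estimates$t_half_hat, 41)
  expect_equal(tie$t_half_candidates, c(41, 41))
})

test_that("searching several half-lives spends an extra degree of freedom", {
  v <- simulate_voxel(time_grid(200), pd = pd_params(10, 1), noise_sd = 0.5,
                      seed = 4)
  f <- fit_pkpd(v, grid = search_grid(t_half_values = c(41, 5)))
  expect_equal(f$j, 4L)
  expect_equal(f$N, 6L)
  expect_equal(glance(f)$df1, 4L)
})

test_that("a fully degenerate grid is rejected with a clear error", {
  g <- time_grid(100)
  dat <- tibble::tibble(time_min = g$time_min, signal = rnorm(100))
  # every candidate EC50 astronomically above any achieved concentration:
  # the effect column is then proportional to C(t) for all cells, which is
  # still informative, so degeneracy needs a schedule with no doses inside
  # the acquisition window
  late <- dose_schedule(1000, 1)
  expect_error(fit_pkpd(dat, late, window_s = 0), "degenerate")
})
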