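#' Dosing schedule
#'
#' Describes the K bolus doses of the challenge drug: amounts and
#' administration times. Doses are treated as instantaneous boluses; a slow
#' infusion is represented as a bolus at infusion start (the plasma model has
#' no absorption phase).
#'
#' @param times_min Dose times in minutes, strictly increasing, on the same
#'   clock as the imaging time grid (time 0 = first frame).
#' @param amounts Dose amounts in arbitrary units (e.g., ng); recycled to the
#'   length of `times_min`. All must be positive.
#' @return A tibble with columns `time_min` and `dose` and class
#'   `"dose_schedule"`.
#' @examples
#' dose_schedule(c(8, 16, 24, 32))
#' @export
dose_schedule <- function(times_min, amounts = 1) {
  if (length(times_min) < 1L) stop_input("a dose schedule needs at least one dose")
  if (!is.numeric(times_min) || anyNA(times_min))
    stop_input("`times_min` must be numeric with no missing values")
  if (is.unsorted(times_min, strictly = TRUE))
    stop_input("dose times must be strictly increasing")
  amounts <- rep_len(amounts, length(times_min))
  if (!is.numeric(amounts) || any(!is.finite(amounts)) || any(amounts <= 0))
    stop_input("dose amounts must all be positive and finite")
  out <- tibble(time_min = as.numeric(times_min), dose = as.numeric(amounts))
  class(out) <- c("dose_schedule", class(out))
  out
}

#' Default four-dose schedule
#'
#' Four equal unit doses at 8, 16, 24 and 32 minutes into a 40-minute
#' session — the dosing timeline used throughout the simulation studies.
#' @return A [dose_schedule()].
#' @export
default_dose_schedule <- function() dose_schedule(c(8, 16, 24, 32), 1)

#' Pharmacokinetic parameters
#'
#' One-compartment elimination kinetics: a fixed delay `t_shift_min` between
#' administration and appearance in plasma, and an elimination half-life
#' `t_half_min`.
#'
#' @param t_half_min Elimination half-life in minutes (> 0). Default 41.
#' @param t_shift_min Fixed time delay (shift) in minutes (>= 0). Default 0.43.
#' @return A list of class `"pk_params"`.
#' @export
pk_params <- function(t_half_min = 41, t_shift_min = 0.43) {
  check_number(t_half_min, "t_half_min", lower = 0, allow_equal_lower = FALSE)
  check_number(t_shift_min, "t_shift_min", lower = 0)
  structure(list(t_half_min = t_half_min, t_shift_min = t_shift_min),
            class = "pk_params")
}

#' Pharmacodynamic parameters of the sigmoid Emax model
#'
#' @param e_max Maximal (asymptotic) effect in imaging units. May be negative:
#'   a drug can decrease the measured signal.
#' @param ec50 Plasma concentration producing half of `e_max` (> 0), in the
#'   same units as the concentration curve.
#' @param hill_n Hill coefficient (> 0); steepness of the sigmoid. Default 1.
#' @return A list of class `"pd_params"`.
#' @export
pd_params <- function(e_max = 10, ec50 = 1, hill_n = 1) {
  check_number(e_max, "e_max")
  check_number(ec50, "ec50", lower = 0, allow_equal_lower = FALSE)
  check_number(hill_n, "hill_n", lower = 0, allow_equal_lower = FALSE)
  structure(list(e_max = e_max, ec50 = ec50, hill_n = hill_n),
            class = "pd_params")
}

#' Polynomial baseline drift
#'
#' Slow artifactual signal drift modeled as a polynomial in time,
#' `a_0 + a_1 t + ... + a_M t^M`, with `a_k` in imaging-units * min^-k.
#'
#' @param coefficients Numeric vector `c(a_0, ..., a_M)`; the degree M is
#'   `length(coefficients) - 1`. Default is the linear drift `1000 + 0.05 t`
#'   used to generate the simulated data.
#' @return A list of class `"drift_spec"` with elements `coefficients` and
#'   `degree`.
#' @export
drift_spec <- function(coefficients = c(1000, 0.05)) {
  if (!is.numeric(coefficients) || length(coefficients) < 1L ||
      any(!is.finite(coefficients)))
    stop_input("drift `coefficients` must be a non-empty finite numeric vector")
  structure(list(coefficients = as.numeric(coefficients),
                 degree = length(coefficients) - 1L),
            class = "drift_spec")
}

#' Imaging time grid
#'
#' Evenly sampled acquisition times. The default mirrors a 40-minute session
#' of 800 whole-brain frames, one every 3 seconds.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt_s Frame interval in seconds (> 0).
#' @param start_min Time of the first frame in minutes.
#' @return A tibble with columns `frame` (0-based) and `time_min`.
#' @examples
#' head(time_grid())
#' @export
time_grid <- function(n_frames = 800, dt_s = 3, start_min = 0) {
  check_number(n_frames, "n_frames", lower = 2)
  check_number(dt_s, "dt_s", lower = 0, allow_equal_lower = FALSE)
  frame <- seq_len(n_frames) - 1L
  tibble(frame = frame, time_min = start_min + frame * dt_s / 60)
}

# vectorized plasma concentration at times t (minutes)
pk_concentration <- function(t, schedule, pk) {
  conc <- numeric(length(t))
  for (k in seq_len(nrow(schedule))) {
    dt <- t - pk$t_shift_min - schedule$time_min[k]
    on <- dt >= 0
    conc[on] <- conc[on] + schedule$dose[k] * 2^(-dt[on] / pk$t_half_min)
  }
  conc
}

#' Plasma concentration over time
#'
#' One-compartment superposition model: each bolus `D_k` given at `t_k`
#' contributes `D_k * 0.5^((t - t_s - t_k)/t_half)` for `t >= t_s + t_k` and
#' nothing before (unit step onset; the full amount appears exactly at
#' `t = t_s + t_k`).
#'
#' @param data A data frame with a `time_min` column (e.g., [time_grid()]).
#' @param schedule A [dose_schedule()].
#' @param pk [pk_params()].
#' @return `data` as a tibble with an added `conc` column (concentration
#'   units).
#' @examples
#' plasma_concentration(time_grid(), default_dose_schedule(), pk_params())
#' @export
plasma_concentration <- function(data, schedule = default_dose_schedule(),
                                 pk = pk_params()) {
  check_time_df(data, "plasma_concentration")
  mutate(as_tibble(data), conc = pk_concentration(.data$time_min, schedule, pk))
}

#' Concentration scale relative to the first-dose peak
#'
#' EC50 is expressed relative to the peak plasma concentration after the
#' first bolus, which is taken as 1 unit. For instantaneous-bolus kinetics
#' that peak equals `D_1` (attained at `t_1 + t_s`), so the scale factor is
#' `1 / D_1`: multiplying the concentration curve by it makes the first-dose
#' peak exactly 1. Relative EC50 estimates can be converted to absolute
#' concentrations by multiplying by a measured first-peak plasma level.
#'
#' @param schedule A [dose_schedule()].
#' @return A single number, `1 / D_1` (units 1/concentration).
#' @export
first_peak_scale <- function(schedule) {
  d1 <- schedule$dose[1]
  if (!is.finite(d1) || d1 == 0) stop_input("first dose amount must be nonzero")
  1 / d1
}

#' Sigmoid concentration-effect (Hill) curve, numeric form
#'
#' `E(C) = e_max * C^n / (ec50^n + C^n)`. At `C = ec50` the effect is exactly
#' `e_max / 2` for every Hill coefficient.
#'
#' @param conc Non-negative concentrations (vectorized).
#' @param e_max,ec50,hill_n See [pd_params()].
#' @return Effect in imaging units, same length as `conc`.
#' @examples
#' hill_effect(c(0, 1, 3), e_max = 10, ec50 = 1)
#' @export
hill_effect <- function(conc, e_max = 10, ec50 = 1, hill_n = 1) {
  if (any(conc < 0, na.rm = TRUE)) stop_input("concentrations must be >= 0")
  cn <- conc^hill_n
  e_max * cn / (ec50^hill_n + cn)
}

#' Sigmoid concentration-effect transform of a concentration series
#'
#' @param data A data frame with a `conc` column (e.g., the output of
#'   [plasma_concentration()]).
#' @param pd [pd_params()].
#' @return `data` with an added `effect` column (imaging units).
#' @export
sigmoid_effect <- function(data, pd = pd_params()) {
  if (!is.data.frame(data) || !"conc" %in% names(data))
    stop_input("`data` must contain a `conc` column; see plasma_concentration()")
  mutate(as_tibble(data),
         effect = hill_effect(.data$conc, pd$e_max, pd$ec50, pd$hill_n))
}

poly_eval <- function(coefficients, t) {
  out <- numeric(length(t))
  for (k in rev(seq_along(coefficients))) out <- out * t + coefficients[k]
  out
}

#' Polynomial drift series
#'
#' @param data A data frame with a `time_min` column.
#' @param drift A [drift_spec()].
#' @return `data` with an added `drift` column.
#' @export
drift_signal <- function(data, drift = drift_spec()) {
  check_time_df(data, "drift_signal")
  mutate(as_tibble(data), drift = poly_eval(drift$coefficients, .data$time_min))
}

#' Predicted noise-free imaging signal
#'
#' The forward model of the imaging time-signal curve: the drug effect
#' `E(C(t))` plus polynomial baseline drift. This is the curve that, with
#' Gaussian noise added, constitutes a simulated voxel.
#'
#' @inheritParams plasma_concentration
#' @param pd [pd_params()].
#' @param drift [drift_spec()].
#' @return A tibble with columns `time_min`, `conc`, `effect`, `drift` and
#'   `signal` (= effect + drift).
#' @examples
#' tissue_model(time_grid(), default_dose_schedule(), pk_params(),
#'              pd_params(e_max = 10, ec50 = 1), drift_spec())
#' @export
tissue_model <- function(data, schedule = default_dose_schedule(),
                         pk = pk_params(), pd = pd_params(),
                         drift = drift_spec()) {
  data |>
    plasma_concentration(schedule, pk) |>
    sigmoid_effect(pd) |>
    drift_signal(drift) |>
    mutate(signal = .data$effect + .data$drift)
}
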