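#' Write a model parameter configuration
#'
#' Serializes a complete forward-model parameter set to a single JSON or YAML
#' file (chosen by extension). Keys: `doses`, `dose_times_min`, `t_half_min`,
#' `t_shift_min`, `e_max`, `ec50`, `hill_n`, `drift_coeffs`, `dt_s`,
#' `n_frames`.
#'
#' @param schedule A [dose_schedule()].
#' @param pk,pd,drift Parameter objects; see [pk_params()], [pd_params()],
#'   [drift_spec()].
#' @param grid A [time_grid()] tibble (must be evenly sampled from 0).
#' @param path Output file path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(schedule, pk, pd, drift, grid, path) {
  dt_min <- diff(grid$time_min)
  if (length(dt_min) < 1L || any(abs(dt_min - dt_min[1]) > 1e-9))
    stop_input("`grid` must be evenly sampled")
  cfg <- list(
    doses = schedule$dose,
    dose_times_min = schedule$time_min,
    t_half_min = pk$t_half_min,
    t_shift_min = pk$t_shift_min,
    e_max = pd$e_max,
    ec50 = pd$ec50,
    hill_n = pd$hill_n,
    drift_coeffs = drift$coefficients,
    dt_s = dt_min[1] * 60,
    n_frames = nrow(grid)
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, digits = NA, auto_unbox = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else {
    stop_input("config path must end in .json, .yaml or .yml, got '%s'", ext)
  }
  invisible(path)
}

#' Read a model parameter configuration
#'
#' Inverse of [write_model_config()].
#'
#' @param path A `.json`, `.yaml` or `.yml` file written by
#'   [write_model_config()] (or hand-authored with the same keys).
#' @return A list with elements `schedule`, `pk`, `pd`, `drift` and `grid`.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_input("config path must end in .json, .yaml or .yml, got '%s'", ext)
  }
  needed <- c("doses", "dose_times_min", "t_half_min", "t_shift_min", "e_max",
              "ec50", "hill_n", "drift_coeffs", "dt_s", "n_frames")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0)
    stop_input("config is missing key(s): %s", paste(missing, collapse = ", "))
  list(
    schedule = dose_schedule(unlist(cfg$dose_times_min), unlist(cfg$doses)),
    pk = pk_params(cfg$t_half_min, cfg$t_shift_min),
    pd = pd_params(cfg$e_max, cfg$ec50, cfg$hill_n),
    drift = drift_spec(unlist(cfg$drift_coeffs)),
    grid = time_grid(cfg$n_frames, cfg$dt_s)
  )
}
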