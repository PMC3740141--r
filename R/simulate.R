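# Deterministic per-voxel seed: iterated mix over integer keys, kept below
# 2^31 so set.seed() receives a valid integer. Exact in double precision
# (69069 * (2^31 - 1) < 2^53).
voxel_seed <- function(master_seed, keys) {
  m <- 2147483647
  s <- as.numeric(master_seed) %% m
  for (k in keys) s <- (69069 * s + as.numeric(k) + 1) %% m
  as.integer(s)
}

#' Simulate one drug-response voxel
#'
#' A simulated voxel is the noise-free forward model [tissue_model()] plus
#' independent Gaussian noise at each time point.
#'
#' @param data A data frame with a `time_min` column ([time_grid()]).
#' @param schedule,pk,pd,drift Forward-model parameters.
#' @param noise_sd Noise standard deviation in imaging units (>= 0). Noise
#'   levels are conventionally reported as a fraction of `|e_max|`; pass
#'   `sd_fraction * abs(pd$e_max)` for that convention.
#' @param seed Optional integer seed making the voxel reproducible.
#' @return A tibble with columns `time_min`, `model` (noise-free signal) and
#'   `signal` (model + noise).
#' @examples
#' simulate_voxel(time_grid(), noise_sd = 1, seed = 1)
#' @export
simulate_voxel <- function(data, schedule = default_dose_schedule(),
                           pk = pk_params(), pd = pd_params(),
                           drift = drift_spec(), noise_sd = 0, seed = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  tm <- tissue_model(data, schedule, pk, pd, drift)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(nrow(tm), 0, noise_sd) else numeric(nrow(tm))
  tibble(time_min = tm$time_min, model = tm$signal, signal = tm$signal + noise)
}

#' Simulate one drug-free (null) voxel
#'
#' Polynomial drift plus Gaussian noise, with no drug response (`e_max = 0`).
#' Used to measure the false-positive behavior of the fitter.
#'
#' @inheritParams simulate_voxel
#' @return A tibble with columns `time_min`, `model` and `signal`.
#' @export
simulate_null_voxel <- function(data, drift = drift_spec(), noise_sd = 0,
                                seed = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  dm <- drift_signal(data, drift)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) rnorm(nrow(dm), 0, noise_sd) else numeric(nrow(dm))
  tibble(time_min = dm$time_min, model = dm$drift, signal = dm$drift + noise)
}

#' Simulation design
#'
#' The full factorial design of a simulated test corpus: true EC50 values x
#' noise levels x replicates, plus matched drug-free null voxels at each
#' noise level. Defaults are the conditions of the published simulation
#' study: ten EC50 values (half of them off the fitter's output grid), noise
#' SD from 0.01 to 2 times `e_max`, 1000 replicates per cell, four unit doses
#' over 40 minutes, `e_max` 10 over a linear drift 1000 + 0.05 t.
#'
#' @param ec50_inputs True EC50 values; may be `numeric(0)` for a null-only
#'   corpus.
#' @param noise_fractions Noise SD as a fraction of `abs(e_max)`.
#' @param replicates Voxels per (EC50, noise) cell (>= 1).
#' @param e_max,hill_n True pharmacodynamic parameters of response voxels.
#' @param schedule,pk,drift,grid Shared forward-model ingredients.
#' @param include_nulls Generate `replicates` matched null voxels per noise
#'   level. Null-voxel noise SD is resolved against the design's `e_max` so
#'   null and response cells are comparable.
#' @param master_seed Integer master seed; every voxel's seed is derived from
#'   it deterministically, so any voxel can be regenerated in isolation.
#' @param max_voxels Refuse designs whose corpus exceeds this size.
#' @return A list of class `"simulation_design"`.
#' @export
simulation_design <- function(ec50_inputs = c(0.1, 0.43, 1.0, 1.7, 3.0, 3.8,
                                              5.0, 6.1, 8.0, 9.2),
                              noise_fractions = c(0.01, 0.05, 0.1, 0.2, 0.5,
                                                  1, 2),
                              replicates = 1000,
                              e_max = 10, hill_n = 1,
                              schedule = default_dose_schedule(),
                              pk = pk_params(),
                              drift = drift_spec(),
                              grid = time_grid(),
                              include_nulls = TRUE,
                              master_seed = 1L,
                              max_voxels = 2e5) {
  check_number(replicates, "replicates", lower = 1)
  if (length(noise_fractions) < 1L || any(noise_fractions < 0))
    stop_input("`noise_fractions` must be non-negative and non-empty")
  if (length(ec50_inputs) > 0 && any(ec50_inputs <= 0))
    stop_input("`ec50_inputs` must be positive")
  n_response <- length(ec50_inputs) * length(noise_fractions) * replicates
  n_null <- if (include_nulls) length(noise_fractions) * replicates else 0
  if (n_response + n_null > max_voxels)
    stop_input("design would generate %d voxels, above the cap of %g; raise `max_voxels` deliberately if intended",
               n_response + n_null, max_voxels)
  structure(list(ec50_inputs = ec50_inputs, noise_fractions = noise_fractions,
                 replicates = as.integer(replicates), e_max = e_max,
                 hill_n = hill_n, schedule = schedule, pk = pk, drift = drift,
                 grid = grid, include_nulls = include_nulls,
                 master_seed = as.integer(master_seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("<simulation_design>\n")
  cat("  EC50 inputs:    ", paste(x$ec50_inputs, collapse = ", "), "\n")
  cat("  noise fractions:", paste(x$noise_fractions, collapse = ", "),
      "(x |e_max| =", x$e_max, ")\n")
  cat("  replicates/cell:", x$replicates,
      if (x$include_nulls) " (+ matched nulls)" else "", "\n", sep = "")
  cat("  frames:", nrow(x$grid), " master seed:", x$master_seed, "\n")
  invisible(x)
}

#' Generate a simulated voxel corpus
#'
#' Generates every voxel of a [simulation_design()]: one series per
#' (EC50, noise, replicate) cell plus, if requested, matched drug-free null
#' voxels per (noise, replicate). The corpus is bit-reproducible from the
#' design's master seed.
#'
#' @param design A [simulation_design()].
#' @return A tibble (manifest) with one row per voxel: `voxel_id`, `kind`
#'   (`"response"`/`"null"`), `ec50_true` (`NA` for nulls), `e_max_true`,
#'   `noise_fraction`, `noise_sd` (imaging units), `replicate`, `seed`, and a
#'   `series` list-column of per-voxel tibbles (`time_min`, `model`,
#'   `signal`). The design is attached as attribute `"design"`.
#' @examples
#' corpus <- simulate_corpus(simulation_design(
#'   ec50_inputs = c(1, 5), noise_fractions = 0.1, replicates = 2,
#'   grid = time_grid(100)))
#' corpus
#' @export
simulate_corpus <- function(design) {
  if (!inherits(design, "simulation_design"))
    stop_input("`design` must come from simulation_design()")
  rows <- list()
  for (w in seq_along(design$noise_fractions)) {
    sd_abs <- design$noise_fractions[w] * abs(design$e_max)
    for (e in seq_along(design$ec50_inputs)) {
      rows[[length(rows) + 1L]] <- tibble(
        kind = "response",
        ec50_true = design$ec50_inputs[e],
        noise_fraction = design$noise_fractions[w],
        noise_sd = sd_abs,
        replicate = seq_len(design$replicates),
        seed = vapply(seq_len(design$replicates), function(r)
          voxel_seed(design$master_seed, c(1L, e, w, r)), integer(1))
      )
    }
    if (design$include_nulls) {
      rows[[length(rows) + 1L]] <- tibble(
        kind = "null",
        ec50_true = NA_real_,
        noise_fraction = design$noise_fractions[w],
        noise_sd = sd_abs,
        replicate = seq_len(design$replicates),
        seed = vapply(seq_len(design$replicates), function(r)
          voxel_seed(design$master_seed, c(2L, 0L, w, r)), integer(1))
      )
    }
  }
  manifest <- bind_rows(rows)
  manifest$voxel_id <- seq_len(nrow(manifest))
  manifest$e_max_true <- ifelse(manifest$kind == "null", 0, design$e_max)

  manifest$series <- pmap(
    list(manifest$kind, manifest$ec50_true, manifest$noise_sd, manifest$seed),
    function(kind, ec50, sd_abs, seed) {
      if (kind == "null") {
        simulate_null_voxel(design$grid, design$drift, sd_abs, seed)
      } else {
        simulate_voxel(design$grid, design$schedule, design$pk,
                       pd_params(design$e_max, ec50, design$hill_n),
                       design$drift, sd_abs, seed)
      }
    })
  out <- manifest[, c("voxel_id", "kind", "ec50_true", "e_max_true",
                      "noise_fraction", "noise_sd", "replicate", "seed",
                      "series")]
  attr(out, "design") <- design
  out
}

# T x V matrix of signals from a corpus series list-column
series_matrix <- function(corpus) {
  vapply(corpus$series, function(s) s$signal, numeric(nrow(corpus$series[[1]])))
}
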