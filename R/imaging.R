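as_volume_array <- function(volume, ndim, what) {
  a <- if (inherits(volume, "niftiImage")) as.array(volume) else volume
  if (!is.array(a) || length(dim(a)) != ndim)
    stop_input("`%s` must be a %dD array or NIfTI image", what, ndim)
  a
}

#' Lay a simulated corpus out as a 4D imaging phantom
#'
#' Places each voxel's series on a 3D lattice so the whole corpus can be
#' analyzed through the voxelwise imaging pathway. Voxels fill the lattice
#' in column-major order; unused lattice positions are masked out and hold
#' zeros.
#'
#' @param corpus A corpus from [simulate_corpus()].
#' @param dim3 Length-3 lattice dimensions; defaults to a near-square single
#'   slice large enough for the corpus.
#' @return A list of class `"pd_phantom"`: `volume` (X x Y x Z x T array),
#'   `mask` (3D logical), `manifest` (corpus manifest with lattice indices
#'   `i`, `j`, `k`), `dt_s`.
#' @export
corpus_to_phantom <- function(corpus, dim3 = NULL) {
  if (!is.data.frame(corpus) || !"series" %in% names(corpus))
    stop_input("`corpus` must come from simulate_corpus()")
  V <- nrow(corpus)
  if (is.null(dim3)) {
    nx <- ceiling(sqrt(V))
    dim3 <- c(nx, ceiling(V / nx), 1)
  }
  if (length(dim3) != 3 || prod(dim3) < V)
    stop_input("`dim3` must hold all %d voxels", V)
  t <- corpus$series[[1]]$time_min
  T_ <- length(t)
  vol <- array(0, c(dim3, T_))
  mask <- array(FALSE, dim3)
  ijk <- arrayInd(seq_len(V), dim3)
  Y <- series_matrix(corpus)
  flat <- matrix(vol, prod(dim3), T_)
  flat[seq_len(V), ] <- t(Y)
  vol <- array(flat, c(dim3, T_))
  mask[ijk] <- TRUE
  manifest <- as_tibble(corpus[setdiff(names(corpus), "series")])
  manifest$i <- ijk[, 1]; manifest$j <- ijk[, 2]; manifest$k <- ijk[, 3]
  structure(list(volume = vol, mask = mask, manifest = manifest,
                 dt_s = series_dt_s(t)),
            class = "pd_phantom")
}

#' Write a phantom to NIfTI
#'
#' Writes the 4D volume (double precision, so series round-trip bit-exactly)
#' and optionally the mask and a JSON manifest.
#'
#' @param phantom A [corpus_to_phantom()] result.
#' @param path Output path for the 4D volume (`.nii` or `.nii.gz`).
#' @param mask_path,manifest_path Optional outputs for the mask volume and
#'   the JSON manifest.
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, path, mask_path = NULL,
                                manifest_path = NULL) {
  if (!inherits(phantom, "pd_phantom"))
    stop_input("`phantom` must come from corpus_to_phantom()")
  img <- RNifti::asNifti(phantom$volume)
  RNifti::pixdim(img) <- c(1, 1, 1, phantom$dt_s)
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(mask_path))
    RNifti::writeNifti(RNifti::asNifti(phantom$mask * 1L), mask_path,
                       datatype = "int16")
  if (!is.null(manifest_path))
    jsonlite::write_json(list(schema_version = 1L,
                              manifest = phantom$manifest),
                         manifest_path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Mean time-signal curve over a volume of interest
#'
#' Averages the 4D volume over the in-mask voxels at each frame, with
#' optional temporal median filtering of the resulting curve.
#'
#' @param volume A 4D array or NIfTI image (X x Y x Z x T).
#' @param mask A 3D array (logical or 0/1) with the same spatial dimensions;
#'   must select at least one voxel.
#' @param dt_s Frame interval in seconds.
#' @param start_min Acquisition time of the first frame.
#' @param window_s Optional median-filter window in seconds (`NULL` = no
#'   filtering).
#' @return A tibble with `time_min` and `signal`.
#' @export
extract_voi_curve <- function(volume, mask, dt_s = 3, start_min = 0,
                              window_s = NULL) {
  vol <- as_volume_array(volume, 4L, "volume")
  msk <- as_volume_array(mask, 3L, "mask")
  if (!all(dim(msk) == dim(vol)[1:3]))
    stop_input("mask dimensions %s do not match volume %s",
               paste(dim(msk), collapse = "x"),
               paste(dim(vol)[1:3], collapse = "x"))
  sel <- which(msk > 0)
  if (length(sel) == 0) stop_input("the mask selects no voxels")
  T_ <- dim(vol)[4]
  flat <- matrix(vol, prod(dim(vol)[1:3]), T_)
  signal <- colMeans(flat[sel, , drop = FALSE])
  if (!is.null(window_s)) signal <- median_filter(signal, window_s, dt_s)
  tibble(time_min = start_min + (seq_len(T_) - 1) * dt_s / 60, signal = signal)
}

#' Voxelwise PK-PD fitting of a 4D volume
#'
#' Fits every in-mask voxel's time-signal curve with [fit_pkpd()]'s grid
#' search (batched: the design matrices are shared across voxels) and
#' assembles 3D parameter maps. Alongside the uncorrected p-value map, a
#' binary significance map thresholded at the Bonferroni-corrected level
#' for the number of in-mask voxels is produced.
#'
#' @inheritParams extract_voi_curve
#' @param schedule A [dose_schedule()] on the acquisition clock.
#' @param grid A [search_grid()].
#' @param window_s Median-filter window in seconds.
#' @param alpha Uncorrected significance level.
#' @param n_comparisons Comparison count for the Bonferroni map; defaults to
#'   the number of in-mask voxels.
#' @param mask `NULL` fits every voxel.
#' @return An object of class `"parameter_maps"`: a named list `maps` of 3D
#'   arrays (`ec50`, `e_max`, `t_shift`, `t_half`, `f_stat`, `p_value`,
#'   `degenerate`, `significant_bonferroni`; masked-out voxels are `NA`), a
#'   per-voxel `results` tibble, and the settings used. See
#'   [tidy.parameter_maps()].
#' @export
voxelwise_fit <- function(volume, mask = NULL,
                          schedule = default_dose_schedule(),
                          grid = search_grid(), window_s = 45, alpha = 0.05,
                          n_comparisons = NULL, dt_s = 3, start_min = 0) {
  vol <- as_volume_array(volume, 4L, "volume")
  d3 <- dim(vol)[1:3]
  T_ <- dim(vol)[4]
  msk <- if (is.null(mask)) array(TRUE, d3) else as_volume_array(mask, 3L, "mask")
  if (!all(dim(msk) == d3)) stop_input("mask dimensions do not match volume")
  sel <- which(msk > 0)
  if (length(sel) == 0) stop_input("the mask selects no voxels")
  if (is.null(n_comparisons)) n_comparisons <- length(sel)

  t <- start_min + (seq_len(T_) - 1) * dt_s / 60
  flat <- matrix(vol, prod(d3), T_)
  Y <- t(flat[sel, , drop = FALSE])
  Y <- apply(Y, 2, median_filter, window_s = window_s, dt_s = dt_s)
  engine <- build_fit_engine(t, schedule, grid)
  res <- batch_grid_fit(Y, engine)

  ijk <- arrayInd(sel, d3)
  results <- bind_cols(tibble(voxel = sel, i = ijk[, 1], j = ijk[, 2],
                              k = ijk[, 3]), res)
  results$significant <- results$p_value < alpha
  results$significant_bonferroni <- results$p_value < alpha / n_comparisons

  blank <- array(NA_real_, d3)
  fill <- function(vals) { m <- blank; m[sel] <- vals; m }
  maps <- list(ec50 = fill(res$ec50_hat), e_max = fill(res$e_max_hat),
               t_shift = fill(res$t_shift_hat), t_half = fill(res$t_half_hat),
               f_stat = fill(res$f_stat), p_value = fill(res$p_value),
               degenerate = fill(as.numeric(res$degenerate)),
               significant_bonferroni = fill(as.numeric(results$significant_bonferroni)))
  structure(list(maps = maps, results = results, dim = d3, alpha = alpha,
                 n_comparisons = n_comparisons),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat("<parameter_maps>", paste(x$dim, collapse = " x "), "volume,",
      nrow(x$results), "voxels fit\n")
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  cat("  significant (p <", x$alpha, "uncorrected):",
      sum(x$results$significant), "voxels;",
      "Bonferroni n =", x$n_comparisons, ":",
      sum(x$results$significant_bonferroni), "voxels\n")
  invisible(x)
}

#' Tidy voxelwise parameter maps
#'
#' @param x A `"parameter_maps"` object.
#' @param ... Unused.
#' @return The per-voxel results tibble (lattice indices plus every fit
#'   column).
#' @method tidy parameter_maps
#' @export
tidy.parameter_maps <- function(x, ...) x$results

#' Write parameter maps to NIfTI files
#'
#' @param x A `"parameter_maps"` object.
#' @param dir Output directory (created if needed).
#' @return Tibble of map names and file paths, invisibly.
#' @export
write_parameter_maps <- function(x, dir) {
  if (!inherits(x, "parameter_maps")) stop_input("`x` must be parameter_maps")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- imap(x$maps, function(m, nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(m), p, datatype = "double")
    p
  })
  invisible(tibble(map = names(paths), path = unlist(paths)))
}
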