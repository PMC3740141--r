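# rapidpd

Rapid quantitative pharmacodynamic imaging: estimate a tissue's sensitivity
to a drug — principally **EC50**, the plasma concentration producing half the
maximal effect — from a *single* pharmacological-challenge imaging session,
even with a nonquantitative modality such as BOLD fMRI.

## The idea

Give K small boluses of the challenge drug during one short acquisition
(e.g., four doses at 8, 16, 24 and 32 min of a 40-min scan). A
one-compartment model predicts the plasma concentration

```
C(t) = Σ_k D_k · 0.5^((t − t_s − t_k)/t½) · u(t − t_s − t_k)
```

(dose amounts D_k at times t_k, fixed delay t_s, elimination half-life t½,
unit step u). The imaging signal follows a sigmoid Emax (Hill)
concentration–effect curve on top of slow polynomial baseline drift:

```
E(C)            = Emax · C^n / (EC50^n + C^n)
tissue_model(t) = E(C(t)) + a₀ + a₁t + … + a_M t^M
```

Because a sensitive region (low EC50) saturates after the first dose while
an insensitive one responds mainly to the later doses, the *shape* of the
time–signal curve encodes EC50. The fitter median-filters the series (45-s
window), searches a quantized grid over (time shift × EC50 × half-life) —
each cell completed by an exact linear least-squares fit of Emax and the
drift coefficients — and keeps the summed-squared-error minimizer. Goodness
of fit is tested against a polynomial with the same number of degrees of
freedom (degree N = M + j, which knows nothing about the dose times) via
the ratio `F = SSE_poly / SSE_model`, referred to an F(j, T − j − 2)
distribution.

The package also ships the full simulation framework used to characterize
the estimator — reproducible synthetic voxels (model + Gaussian noise, and
drug-free drift + noise nulls), operating-characteristic metrics
(sensitivity, specificity, per-output-value EC50 specificity and positive
predictive value), VOI curve extraction and voxelwise fitting of 4D NIfTI
volumes into parameter maps.

## Worked example

Simulate one voxel under the reference conditions (four unit doses,
t_s = 0.43 min, t½ = 41 min, Emax = 10 over drift 1000 + 0.05 t, noise
SD = 0.05·Emax) with a true EC50 of 1.7 — deliberately *between* the
fitter's allowed outputs 1 and 2 — and fit it:

```r
library(rapidpd)

vox <- simulate_voxel(time_grid(), schedule = default_dose_schedule(),
                      pk = pk_params(), pd = pd_params(e_max = 10, ec50 = 1.7),
                      drift = drift_spec(), noise_sd = 0.5, seed = 42)
fit <- fit_pkpd(vox)
fit
#> <pkpd_fit>  grid search over 110 cells, 800 time points
#>   EC50 = 2   t_shift = 0.5 min   t_half = 41 min   e_max = 10.59
#>   SSE(model) = 31.8184   SSE(poly5) = 281.016
#>   F(3, 795) = 8.832   p = 9.177e-06
```

The model fits far better than the dose-blind comparison polynomial
(F ≈ 8.8, p ≈ 9×10⁻⁶), and the returned EC50 = 2 is one of the two values
bracketing the true 1.7 — "in range", the estimator's definition of a
correct answer on its quantized output grid. `glance(fit)` returns the
one-row fit summary, `tidy(fit)` the parameter estimates
(EC50 = 2, t_shift = 0.5 min, Emax ≈ 10.6, drift ≈ 1000 + 0.068t − 0.0005t²),
and `autoplot(fit)` plots data, filtered series and both fitted curves.

Corpus-level evaluation chains the same pieces:

```r
design <- simulation_design(replicates = 100, master_seed = 1)  # Table-style grid
fits   <- simulate_corpus(design) |> fit_corpus()
metrics_table(fits)          # sensitivity / specificity / PPV tables
```

For imaging data: `extract_voi_curve(volume, mask)` then `fit_pkpd()`, or
`voxelwise_fit(volume, mask, ...)` for whole-volume parameter maps
(`write_parameter_maps()` writes NIfTI). `run_pipeline(config, out_dir)`
orchestrates simulate → fit → evaluate from a JSON/YAML config, and
`inst/scripts/rapidpd.R` exposes `simulate` / `fit` / `evaluate` /
`voxelwise` / `voi` verbs for shell use.

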