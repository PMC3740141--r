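---
title: "Quantitative pharmacodynamic imaging: model, estimator and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative pharmacodynamic imaging: model, estimator and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidpd)
```

## The forward model and its assumptions

The package estimates within-subject pharmacodynamic parameters from one
imaging session in which several small boluses of a challenge drug are
given while the signal is sampled densely in time. Three components are
composed:

1. **Pharmacokinetics.** A one-compartment model with first-order
   elimination. Each dose $D_k$ given at $t_k$ contributes
   $D_k \, 0.5^{(t - t_s - t_k)/t_{1/2}}$ from its arrival time
   $t_s + t_k$ onward and nothing before. Absorption is instantaneous:
   a slow infusion is represented as a bolus at infusion start plus the
   shift $t_s$. This is deliberate — the concentration equation has no
   absorption phase, and on the session's time scale a 30-s infusion is
   indistinguishable from a bolus at our sampling density. Drugs with a
   prominent distribution phase violate the single-exponential assumption;
   the half-life-selection analysis (below) is the pragmatic mitigation.
2. **Pharmacodynamics.** The sigmoid Emax (Hill) curve
   $E(C) = E_{\max} C^n / (EC_{50}^n + C^n)$. $E_{\max}$ may be negative
   (drugs that decrease the measured signal). At $C = EC_{50}$ the effect
   is exactly $E_{\max}/2$ for every Hill coefficient — the defining
   property, and the package's first sanity check. Hysteresis
   (effect-compartment) models are out of scope.
3. **Drift.** Nonquantitative modalities drift slowly; a polynomial
   $a_0 + a_1 t + \dots + a_M t^M$ absorbs it.

The predicted signal is `tissue_model(t) = E(C(t)) + poly_M(t)`. Crucially
it is *linear* in $(E_{\max}, a_0, \dots, a_M)$ once
$(EC_{50}, t_s, t_{1/2}, n)$ are fixed — the basis of the estimator.

Concentration units are arbitrary: EC50 is expressed relative to the peak
plasma concentration after the first dose (`first_peak_scale()`), and can
be converted to absolute units by one measured blood level.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| dose times | 8, 16, 24, 32 | min | four equal doses across a 40-min session |
| $t_s$ | 0.43 | min | circulation delay from injection to plasma peak |
| $t_{1/2}$ | 41 | min | reference elimination half-life; fixed during fitting |
| $E_{\max}$ | 10 | imaging units | ~1% of a baseline of 1000, a realistic evoked amplitude |
| $n$ | 1 | — | fixed during fitting; the cost surface in $n$ is too flat to estimate from imaging, and in-vitro estimates exist |
| drift | $1000 + 0.05t$ | imaging units | slow linear drift on a large baseline (generation); fitted drift is quadratic |
| time grid | 800 frames, 3 s | — | dense sampling; time is the best-measured variable in imaging |

The generation drift is linear while the *fitted* drift degree is $M = 2$:
the estimator should not be handed the true drift family, and quadratic
drift is the operational choice for real BOLD data.

## The estimator

`fit_pkpd()` proceeds in three steps.

**Median filter.** The series is smoothed with a 45-s running median
(15 samples at 3-s sampling), truncated symmetrically at the series ends
(the interior uses `stats::runmed`; the ends are computed explicitly as
medians over the available window, and the series length is preserved — T
in the degrees of freedom below is unchanged).

**Grid search with a linear subfit.** Only $(t_s, EC_{50}, t_{1/2})$ are
nonlinear; they are searched exhaustively over quantized output ranges
(defaults: $t_s \in \{0, 0.1, \dots, 1.0\}$ min,
$EC_{50} \in \{0.1, 0.5, 1, 2, 3, 4, 5, 6.5, 8, 10\}$,
$t_{1/2} \in \{41\}$). In each cell the unit-amplitude effect curve and the
drift monomials form a design matrix and $(\hat E_{\max}, \hat a_k)$ come
from ordinary least squares; the cell cost is the residual sum of squares.
Quantized output is adequate in practice because a useful EC50 only needs
to approximate the achieved blood concentration. Numerical conventions:

- Time is rescaled to $[0, 1]$ inside the drift basis (coefficients are
  reported back in natural units) and the comparison polynomial uses
  orthogonal polynomials, for conditioning.
- SSE is computed on mean-centered data (the intercept lies in every model
  span) so that residual sums of squares near zero are not destroyed by
  cancellation against the $\sim 10^3$ baseline.
- Exact SSE ties break toward smaller EC50, then smaller $t_s$, then the
  earlier half-life candidate: the search enumerates cells in that
  priority order and keeps the first minimum.
- A cell whose effect regressor is numerically indistinguishable from the
  drift span (all concentrations far below the candidate EC50, or no dose
  inside the acquisition window) is flagged *degenerate*; a rank-deficient
  solve falls back to the minimum-norm completion and flags the fit rather
  than reporting an absurd $\hat E_{\max}$ silently. A grid whose every
  cell is degenerate is an error.
- No iterative refinement beyond the grid is performed; the grid *is* the
  estimator's output resolution.

Because the design matrices depend only on the time grid, schedule and
search grid — never on the data — their QR factors are computed once and
reused, so `fit_corpus()` and `voxelwise_fit()` evaluate thousands of
voxels by matrix products, with results identical to per-voxel calls.

**Model comparison.** The null model is a polynomial of degree
$N = M + j$, with $j$ the number of free PK-PD parameters ($j = 3$:
EC50, $t_s$, $E_{\max}$; one more if several half-life candidates are
searched). It has the same degrees of freedom as the PK-PD model but knows
nothing about the dose times. The statistic is
$F = \mathrm{SSE}_{\mathrm{poly}} / \mathrm{SSE}_{\mathrm{model}}$ with
$p$ from the upper tail of $F(j,\, T - j - 2)$. Degenerate conventions:
both SSEs zero gives $F = 1, p = 1$; a perfect model fit against a nonzero
polynomial SSE gives $F = \infty, p = 0$. A historical analysis used the
fixed cutoff $F > 1.218$ for $p = 0.05$; that value is inconsistent with
the $F(3, 795)$ critical point ($\approx 2.61$) and the convention that
produced it cannot be reconstructed, so this package always computes the
threshold from the F distribution at run time and exports
`legacy_f_threshold` purely for comparison with historical output. Model
significance here is therefore *more conservative* than in that analysis.

**Half-life selection.** For biological data where the effective
half-life is uncertain (distribution-phase kinetics), `select_half_life()`
fits once per candidate (e.g., 30 and 5 min) and retains the larger F.
Since the comparison polynomial's SSE does not depend on the candidate,
this is equivalent to retaining the smaller model SSE; an exact tie keeps
the first-listed candidate.

## The synthetic-data generator

`simulate_corpus()` realizes a factorial design: true EC50 values
$\{0.1, 0.43, 1.0, 1.7, 3.0, 3.8, 5.0, 6.1, 8.0, 9.2\}$ (half deliberately
off the output grid, so the fitter is never handed an exactly attainable
answer; the generator's $t_s = 0.43$ is likewise off the $t_s$ grid) ×
noise SD $\{0.01, 0.05, 0.1, 0.2, 0.5, 1, 2\} \times |E_{\max}|$ × 1000
replicates per cell, plus matched drug-free nulls (drift + noise,
$E_{\max} = 0$) per noise level. Null-voxel noise is resolved against the
design's $E_{\max}$ so null and response cells are comparable. Noise is
added to the *unfiltered* model curve; filtering is the estimator's job.

Reproducibility: every voxel's seed derives from the master seed by the
integer mix $s \leftarrow (69069\,s + \mathrm{key} + 1) \bmod (2^{31}-1)$
over the keys (kind, EC50 index, noise index, replicate), so any voxel can
be regenerated in isolation from its manifest row and the whole corpus is
bit-reproducible.

What the generator emulates: additive i.i.d. Gaussian measurement noise on
a smoothly drifting baseline. What it does **not** emulate: temporally
correlated physiological noise, motion and spin-history artifacts,
spatially correlated noise, hysteresis, or multi-compartment kinetics.
Passing simulation tests therefore demonstrate the estimator's behavior
under its own assumptions — not robustness to structured real-world
artifacts, which is exactly the caveat that applies to any model-based
phMRI analysis.

## Operating-characteristic metrics

All metrics consume a table of fit records plus manifest truth — no
refitting. *Model-fit sensitivity* is the fraction of response voxels with
$p < \alpha$ per (EC50, noise) cell (`n_comparisons = 64000` reproduces a
whole-brain Bonferroni variant); *model-fit specificity* is one minus the
null false-positive fraction. *EC50 correctness* on a quantized output
grid: an off-grid truth makes exactly its two bracketing outputs correct;
an on-grid truth only itself; a truth outside the grid range its nearest
endpoint. *EC50 sensitivity* is the in-range fraction per cell (optionally
among significant fits only); *EC50 specificity* is, per output value, one
minus the fraction of nulls returning it, optionally censored to
significant nulls (vacuously 1 when none passes); *PPV* is, per output
value, the fraction of its returns that were in range for their truth.
Undefined rates (zero denominators) are reported as missing — never 0 or
1. `noise_effect_ratio()` reproduces the baseline-regression noise/effect
estimate used to place measured curves on the simulated noise axis; it is
an upper bound on SD$/E_{\max}$ because the observed peak cannot exceed
the maximal effect.

## Problem sizes

The test suite and acceptance script scale the factorial design down to
keep runs quick while leaving every rate estimable: 600 drug-free voxels
(100 per noise level) for the specificity checks, 100 replicates per EC50
at noise 0.05 and 0.08 × $E_{\max}$ for the PPV analysis, 20–40
replicates per cell for ordering properties. These are the package's
standing sizes; the full 1000-replicate design is one
`simulation_design(replicates = 1000)` away.

## Known limitations

- **High-EC50 identifiability.** When $EC_{50}$ far exceeds every achieved
  concentration, $E(C) \approx (E_{\max}/EC_{50})\,C$: amplitude and EC50
  trade off along a ridge and adjacent high grid values differ only
  through mild curvature. At noise levels around 0.05–0.08 × $E_{\max}$
  even an ideal observer confuses neighboring high-EC50 cells at an
  appreciable rate, so per-output-value PPV at the top of the grid is
  intrinsically limited under a uniform prior over inputs — the acceptance
  script computes and reports the achieved minimum rather than asserting
  an aspirational one. Estimates that claim *low* EC50, or any estimate at
  low noise, are far more trustworthy; censoring by the F threshold
  improves accuracy where it bites.
- The F reference distribution treats the filtered samples as independent;
  the 45-s median filter correlates neighboring samples, so the stated
  degrees of freedom are generous. The conservative runtime threshold (vs.
  the legacy cutoff) works in the safe direction, as the null-corpus
  specificity checks confirm.
- Fixed $n$ and externally supplied $t_{1/2}$ are assumptions, not
  estimates; both are carried as explicit fields and grids so sensitivity
  analyses are one argument away.
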