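# mrpleio

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
the full pleiotropy-appraisal battery used in modern epidemiological
practice: inverse-variance-weighted (IVW) estimation, MR-Egger with SIMEX
regression-dilution correction, weighted median and weighted mode
estimators, multivariable MR for confounder adjustment, bidirectional
appraisal, and Benjamini–Hochberg FDR reporting — plus a seeded synthetic
summary-statistics generator with known ground truth, so every stage of the
pipeline is testable against construction.

## Who this is for

Genetic epidemiologists who have per-SNP association estimates
(`beta_zx ± se_zx`) for an exposure from one GWA study and estimates for an
outcome (`beta_zy ± se_zy`) from a second, non-overlapping study, and who
want causal-effect estimates that are honest about horizontal and
confounding pleiotropy. It is also for methodologists who want a
self-contained simulator of the three pleiotropy structures — vertical,
horizontal, confounding — to study estimator calibration.

## The model

Each instrument SNP *j* yields a Wald ratio
`beta_j = beta_zy_j / beta_zx_j`. The IVW estimate meta-analyzes the ratios
with first-order weights `w_j = beta_zx_j² / se_zy_j²`:

```
beta_IVW = Σ w_j beta_j / Σ w_j
```

equivalent to a zero-intercept weighted regression of outcome betas on
exposure betas. The sensitivity battery relaxes the exclusion-restriction
assumption in different ways:

* **MR-Egger** frees the intercept; the intercept estimates average
  directional pleiotropy and its test is the directional-pleiotropy test.
  The slope remains consistent under the InSIDE assumption.
* **SIMEX** counters regression dilution of the Egger slope when the
  no-measurement-error assumption fails (low `I²_GX`): noise of variance
  `λ·se_zx²` is added over a grid of λ, the mean estimate is modelled as a
  quadratic in λ, and the fit is extrapolated to λ = −1.
* **Weighted median** is consistent when ≥ 50% of the weight comes from
  valid SNPs; **weighted mode** when the largest cluster of ratios does.
* **Multivariable IVW** regresses outcome betas jointly on several
  exposures' betas, giving each exposure's *direct* effect holding the
  others constant — the instrument for separating a trait's effect from a
  correlated confounder trait's.

Instrument hygiene before estimation: p < 5e-8 selection with greedy LD
pruning (r² < 0.01), allele harmonization with strand-flip resolution and
frequency-based orientation of palindromic SNPs, radial-regression outlier
removal, Cochran's Q heterogeneity diagnostics, and F-statistic /
R² instrument-strength reporting (F < 10 flagged as weak). Bidirectional
analyses exclude SNPs shared between, or in LD across, the two instruments.

## Worked example

```r
library(mrpleio)

# simulate a two-sample design with a true effect of 0.3 (SD per SD)
sim <- simulate_pair(scenario_config("V", theta = 0.3, seed = 11))
report <- run_univariable(sim$exposure, sim$outcome,
                          options = list(seed = 11, n_boot = 300,
                                         simex_reps = 100))
print(report)
```

```
MR test 'exposure_on_outcome' (univariable): exposure -> outcome
ivw: beta = 0.2936 (95% CI 0.2654, 0.3218), se = 0.01439, p = 1.56e-92, k = 31
egger: beta = 0.2655 (95% CI 0.1871, 0.344), se = 0.04003, p = 2.85e-07, k = 31
  intercept = 0.002698 (se 0.003589, p = 0.458)
egger_simex: beta = 0.2735 (95% CI 0.1881, 0.359), se = 0.0436, p = 7.55e-07, k = 31
  intercept = 0.002081 (se 0.003903, p = 0.598)
weighted_median: beta = 0.3103 (95% CI 0.2667, 0.354), se = 0.02225, p = 3.32e-44, k = 31
weighted_mode: beta = 0.3189 (95% CI 0.2594, 0.3784), se = 0.03036, p = 8.2e-26, k = 31
  raw p = 1.56e-92, FDR p = NA, concordant directions: TRUE
```

Reading it: 31 of the 50 simulated SNPs pass genome-wide significance and
form the instrument; the IVW estimate 0.294 (truth 0.3) is the main result;
all sensitivity estimators agree in direction and magnitude
(`concordant directions: TRUE`) and the Egger intercept is compatible with
zero (p = 0.46), so there is no evidence that directional pleiotropy biases
the IVW estimate. The FDR column is filled when tests run as a battery. For
binary outcomes the same report adds odds ratios (`exp(beta)`).

Batch analyses mirror a published multi-test design: register summary
tables by trait id, list univariable / multivariable / bidirectional tests
in a plan (R list or YAML via `read_plan()`), and `run_plan()` executes
them all, applies BH-FDR across the battery's IVW p-values, and writes the
estimate table, the total-versus-direct comparison table, and a run log.

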