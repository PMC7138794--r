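---
title: "Methods: two-sample MR estimation, pleiotropy appraisal, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation, pleiotropy appraisal, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

Two-sample Mendelian randomization treats genetic variants as instruments:
per-SNP effects on an exposure (`beta_zx ± se_zx`) come from one GWA study,
effects on an outcome (`beta_zy ± se_zy`) from a second study with no
shared participants. Under the instrumental-variable assumptions — the SNPs
are robustly associated with the exposure, independent of confounders, and
affect the outcome only through the exposure — every Wald ratio
`beta_zy/beta_zx` estimates the same causal effect, and the IVW estimate is
their inverse-variance-weighted mean with first-order weights
`w_j = beta_zx_j²/se_zy_j²`.

The battery exists because the third assumption fails in three
recognizable ways. Under *vertical* pleiotropy a variant's outcome effect
is fully mediated by the exposure and IVW is consistent. Under *horizontal*
pleiotropy variants have direct outcome effects `alpha_j`; if these are
directional, IVW is biased and the MR-Egger intercept estimates their
average. Under *confounding* pleiotropy a third trait drives both exposure
and outcome; no univariable estimator can fix this, but multivariable MR —
joint weighted regression on both traits' SNP effects — recovers each
trait's direct effect.

## Estimators and numerical choices

**IVW.** Computed as the analytic weighted mean of ratios (identical to
zero-intercept weighted least squares). Default inference is
*multiplicative random effects*: the fixed-effect SE is scaled by
`sqrt(max(1, Q/(k−1)))`, so between-SNP heterogeneity can widen but never
narrow the interval. A fixed-effect model is available. A single-SNP set
degenerates to the Wald ratio with delta-method SE `se_zy/|beta_zx|`.

**MR-Egger.** Rows are first oriented so every exposure beta is
nonnegative (both betas negated together); the weighted regression with a
free intercept is then solved in closed form from the normal equations.
Residual scaling is multiplicative and floored at 1; inference uses a t
distribution with `k − 2` degrees of freedom — the conservative choice for
the small instruments where Egger is most fragile. The `I²_GX` statistic
(weighted, computed from the exposure betas and their SEs) is reported as
the regression-dilution diagnostic.

**SIMEX.** For each λ in `{0, 0.5, 1, 1.5, 2}` and each of `b_reps`
replicates, noise with variance `λ·se_zx²` is added to the exposure betas
and the *full* Egger estimator — orientation included — is refit; the
replicate means are extrapolated with a quadratic in λ to λ = −1.
Re-applying the complete estimator matters: fixing the orientation and
perturbing afterwards treats the added noise differently from the intrinsic
error (which the orientation step "folds" at small betas) and produces
systematic overcorrection. Variances follow the simulation–extrapolation
difference method (mean model-based variance minus between-replicate
variance, extrapolated to λ = −1, falling back to the λ = 0 model variance
if non-positive). With `se_zx ≡ 0` the corrected estimate equals plain
Egger exactly. A seed is mandatory; results are bit-reproducible.

**Weighted median.** The weighted median of the ratios under normalized
IVW weights, interpolating the cumulative-weight function
`s_j = cumsum(w')_j − w'_j/2` at 1/2. **Weighted mode.** The argmax of a
weighted normal-kernel density over the ratios with bandwidth
`phi · 0.9 · min(sd, IQR/1.349) · k^(−1/5)` (φ = 1 by default, exposed as
a tuning knob) on a 2048-point grid spanning the ratios ± 3 bandwidths.
Both report SEs from a parametric bootstrap (default 1000 replicates) that
resamples the summary estimates from `Normal(beta, se)` — the only
bootstrap available in a summary-data design.

**Multivariable IVW.** Weighted normal equations without intercept across
the K exposure-beta columns; rank is checked first and collinear exposures
are reported by name. Residual scaling is multiplicative, floored at 1, on
`k − K` degrees of freedom.

All intervals are 95% with the normal quantile 1.959964 (t for Egger).
Two-sided p-values are clamped to `(0, 1]` to avoid tail underflow.

## Instrument construction and harmonization

Selection keeps SNPs below the genome-wide threshold 5e-8 and greedily
prunes for independence (accept in ascending p-value order, ties broken by
rsid for reproducibility, reject any candidate with LD r² ≥ 0.01 against an
accepted SNP). LD is supplied as a matrix; without one, SNPs are treated as
independent.

Harmonization aligns outcome rows to the exposure's effect allele:
matching alleles pass through, swapped alleles flip the outcome beta's
sign, and strand-complement pairs are resolved before a SNP is declared
incompatible (summary files differ in strand conventions). Palindromic
(A/T, C/G) SNPs cannot be resolved from labels; the default policy orients
them by comparing effect-allele frequency to 0.5 in both studies, dropping
any SNP whose frequency falls inside the ambiguity band (0.42, 0.58) —
standard two-sample MR practice that keeps SNPs when frequency is
informative. A strict `drop` policy is available; the choice is
configuration because conventions differ across toolchains. Every SNP's
fate is recorded in an audit log (`rsid`, `action`, `reason`).

Radial outlier detection refits the IVW estimate in radial form and flags
SNPs whose per-SNP contribution `Q_j = w_j(ratio_j − beta_radial)²` exceeds
the upper chi-square(1) tail at α = 0.05, Bonferroni-divided by k by
default (the conservative published convention; no threshold is canonical).
The per-SNP contributions sum exactly to the radial Q.

Instrument strength reports `R² = Σ 2·eaf·(1−eaf)·beta²` when frequencies
are available, else the summary-data approximation
`beta²/(beta² + n·se²)`, and `F = R²(n−1−k)/((1−R²)k)`, flagging F < 10 as
conventionally weak. Published F statistics are often not reproducible from
published R², n, and k because the computation is rarely stated; this
package documents its formula rather than matching any particular report.

## Pipeline conventions

The stage order is select → harmonize → outlier-remove → estimate, with
heterogeneity diagnostics recomputed after outlier removal. All estimators
consume identical rows — no estimator-specific re-filtering — so
sensitivity comparisons are interpretable. Bidirectional analyses exclude
SNPs shared between the two instruments or in LD across them, from both
sides. In a battery, each test's raw p is its IVW p (for multivariable
tests, the first exposure is the exposure of interest and contributes its
mv-IVW p); Benjamini–Hochberg adjustment is applied across the battery and
both raw and adjusted columns are always reported. Failed tests are
captured as failed reports and never abort a batch. Odds ratios are
reported only for binary outcomes, as `exp(beta)`.

## The synthetic benchmark

The generator simulates at the summary level — no individual genotypes —
because that is all a two-sample design consumes. True SNP-exposure
effects are drawn `gamma_j = |Normal(0, gamma_sd²)|`: real instruments are
reported on the exposure-increasing allele after harmonization, and a
sign-symmetric gamma would make directional pleiotropy undetectable by
construction (the oriented Egger regression would see sign-balanced direct
effects, and the IVW bias `Σγ_jα_j/Σγ_j²` would have expectation zero).
Standard errors take the exact summary-statistic form
`se = 1/sqrt(2·eaf(1−eaf)·n)` with `eaf ~ Uniform(0.05, 0.5)`; observed
betas are drawn around their truths independently in the two samples.
Binary outcomes use the same normal model on the log-odds scale — an
explicit approximation that matches how case-control outcomes enter
summary-data MR.

Defaults: `k = 50` SNPs (between small and large real instruments),
`n = 50,000` per sample, `gamma_sd = 0.08` — sized so typical SNPs clear
genome-wide significance at that sample size (significance needs
`|gamma| ≳ 5.45·se_zx ≈ 0.034`), i.e. the instrument behaves like a set of
genuinely genome-wide-significant loci.

Scenario parameters: vertical (V) sets `alpha ≡ 0`; directional horizontal
(H-directional) gives a fraction of SNPs direct effects
`Normal(0.05, 0.01²)`; balanced horizontal zeroes the mean; the InSIDE
violation draws `alpha` correlated with `gamma` (ρ = 0.5 default). The
confounding triangle gives a confounder trait its own k SNPs influencing
both the focal exposure (δ₁ = 0.4) and the outcome (δ₂ = 0.5) with a null
direct exposure effect, so an instrument selected from the exposure alone
inherits confounder SNPs and produces an artefactual univariable estimate
that multivariable adjustment removes. The bidirectional generator uses the
reduced form of the simultaneous equations (core effects scaled by
`1/(1 − θ_ab·θ_ba)`), so each direction's Wald ratios equal the structural
effect exactly; defaults `θ_ab = 0.4, θ_ba = 0.095` keep the two arrows in
roughly the 4:1 proportion seen in real education–intelligence appraisals
while leaving cross-significant SNPs rare enough that overlap exclusion
does not empty the instrument.

## Benchmark fixtures and what they show

The calibration studies run by the test suite and `scripts/acceptance.R`
use these problem sizes, chosen at design time:

* **Recovery (V):** θ = 0.3, k = 50, n = 50,000, 500 replicates — mean IVW
  estimate, 95% CI coverage, Egger-intercept type-I rate.
* **Robustness (H-directional, 40% invalid):** k = 100, n = 500,000, 500
  replicates for the IVW-versus-weighted-median contrast. The consortium
  scale is deliberate: the median's guarantee assumes the valid majority
  holds over half the *weight*; with k = 50 the invalid 40% of SNPs carries
  more than half the (heavy-tailed, γ²-proportional) weight in roughly one
  draw in six, and with n = 50,000 the ratio noise `se_zy/γ` (~0.17)
  dominates what the study is meant to measure. Egger-intercept power is
  reported at the default k = 50, n = 50,000 scale.
* **Confounding reversal (TRIANGLE):** θ₁ = 0, δ₁ = 0.4, δ₂ = 0.5, 500
  replicates — univariable artefact versus multivariable direct effect.
* **SIMEX:** k = 100 SNPs measured in an exposure sample of n = 1,000
  (I²_GX well below 1 — a large instrument from a small GWAS is the regime
  where regression dilution bites), 200 replicates, 100 SIMEX replicates
  per λ.
* **Bidirectional:** 300 replicates, overlap exclusion applied. The forward
  arrow is recovered with a visible shortfall (~0.36 versus 0.4): exclusion
  removes exactly the strongest shared SNPs, and the surviving instrument
  is selected on noisy exposure betas near the significance threshold, a
  winner's-curse attenuation that real bidirectional analyses share.

What passing these studies does *not* show: the generator has no LD
structure, no sample overlap between the two studies, no selection or
collider effects, and binary traits are normal on the log-odds scale —
so calibration here demonstrates correctness of the estimators under the
stated models, not robustness to every failure mode of real GWAS data.

## Known limitations

* LD pruning requires a supplied LD matrix; there is no reference-panel
  clumping, proxy lookup, or distance windowing.
* Palindromic-SNP policy for any given published analysis is rarely
  stated; replication of published numbers can hinge on matching it.
* The SIMEX quadratic extrapolant is the convention but is not exact for
  the true attenuation curve; under extreme dilution it can over- or
  under-correct, which is why the corrected and uncorrected estimates are
  both reported.
* No MR-PRESSO, contamination-mixture, MR-RAPS, Steiger filtering, or
  correlated-SNP generalized IVW.
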