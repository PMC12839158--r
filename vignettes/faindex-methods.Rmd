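---
title: "faindex: methods, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{faindex: methods, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faindex)
```

This vignette documents the statistical model behind `faindex`, the
assumptions baked into its defaults, the numerical choices that matter, and
what a green test suite does and does not establish. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. From concentrations to composition

The pipeline starts at per-analyte plasma concentrations (ng/mL) over a
24-analyte fatty-acid panel (8 saturated, 4 cis-monounsaturated, 3 trans,
6 omega-6, 3 omega-3 species). Each concentration is divided by the
analyte's molecular weight, and each quantified analyte is expressed as its
molar amount over the per-sample total of quantified analytes, times 100.
Two conventions are fixed here:

* **Below-LOQ values are excluded, not zeroed.** A measurement below the
  lower limit of quantification is excluded from the molar total and
  reported as `NA`. Treating it as zero would bias every ratio whose
  denominator set includes the analyte. Downstream index functions raise an
  error on `NA` inputs rather than imputing; silent imputation hides data
  problems. (A half-LOQ imputation, sometimes used in the field, can be
  applied by the caller before conversion if desired.)
* **Molecular weights are average masses of the free acids**, shipped in
  `default_panel()` and overridable through a panel file. The source study
  does not publish its MW table; because every index is a within-sample
  ratio of molar percentages, a consistent change of MW convention (e.g.
  methyl esters) shifts all molar amounts in the same direction and moves
  the indices only marginally. Making the table explicit keeps the
  conversion auditable.
* **The denominator set is the 24-analyte panel.** Whether the emulated
  study normalized over exactly these 24 analytes or a larger in-house
  panel is not stated; the 24-analyte set is fixed as the default
  denominator, and a custom panel file changes it.

Molar-percent profiles are compositions: they sum to 100 and are invariant
to uniform scaling of the underlying concentrations. The test suite asserts
both properties on random profiles.

## 2. The indices

Ten per-sample quantities are computed from the composition: the Omega-3
Status (EPA + DHA, mol%), the omega-6/omega-3 ratio (six n-6 species over
the three n-3 species), six pairwise pathway ratios (AA/EPA,
C18:0/C18:1n-9, AA/AdA, DGLA/AA, EPA/DPA, EPA/DHA, DPA/DHA), and the
composite Omega-6/3 Balance Index

$$\mathrm{O6/3\text{-}BI} \;=\; \frac{AA \cdot \sqrt{EPA \cdot DPA}}{AdA \cdot DHA}.$$

The printed formula in the source material is typographically garbled; the
implementation follows the unambiguous prose definition (the geometric mean
of EPA and DPA over DHA, multiplied by the elongation ratio AA/AdA). The
algebraic identity `o63bi = aa_ada * sqrt(epa_dha * dpa_dha)` is asserted
to 1e-12 on random profiles, which pins the formula independently of the
typography.

**Per-sample, then aggregate.** All indices are computed per sample and
averaged afterwards. A mean of per-sample ratios is not the ratio of group
means; published group values are per-sample averages, so the
index-of-group-means appears only in documentation examples.

**Zero denominators are hard errors** naming the offending analyte. The
index functions also refuse below-LOQ inputs (see above).

## 3. ROC machinery

* **AUC** is the empirical Mann–Whitney concordance probability (ties count
  1/2), computed by midranks in O(n log n). The **DeLong
  structural-components estimator** supplies the standard error; the 95% CI
  is the plain Wald interval `auc ± 1.96·se` clipped to [0, 1] — symmetric
  around the AUC, with no logit transform, matching how the emulated study
  reports its intervals. The p-value is the two-sided Wald test of
  AUC = 0.5. Complete separation collapses the DeLong variance to zero; the
  result is then flagged `degenerate` and the p-value reported at its
  limiting value 0.
* **Youden cut-offs.** J = Se + Sp − 1 is piecewise constant in the
  threshold; the implementation scans the continuum between adjacent
  distinct pooled values and, when a contiguous interval attains the
  maximum, returns its **mid-point** — a reproducible rule robust to small
  numeric noise. If several disjoint plateaus tie exactly, the lowest is
  taken (deterministic tie-break); if the maximizing interval is unbounded,
  a finite representative inside it is returned. Sensitivity/specificity
  CIs use the **Wilson score interval**.
* **Orientation registry.** The group structure fixes each marker's disease
  direction: `c18_ratio`, `aa_ada`, `o63bi` and `omega3_status` are lower
  in disease (cut-off rule "≤ is disease"), `aa_epa` and `omega6_3` higher.
  The logit score runs the other way: its slopes are negative in both
  markers, so *high* scores mark disease, and the classification rule is
  `logit_score ≥ cutoff`. This is stated prominently because the "≤"
  wording of the single-index cut-off tables does not carry over to the
  logit scale.
* **Cliff's delta** is computed from the same placement statistics
  (`delta = 2·AUC − 1` holds exactly, including under ties with the 1/2
  convention). The CI is a normal approximation with the consistent
  variance estimator built from row/column dominance means, clipped to
  [−1, 1]; the emulated study does not name its CI method, so the standard
  consistent estimator was chosen.

## 4. Group-comparison decision tree

Routing is a pure function of per-group Shapiro–Wilk outcomes (α = 0.05,
per group — the study states the gate but not its level or granularity) and
a median-centred Levene (Brown–Forsythe) homogeneity test, again at 0.05,
chosen because "unequal variances" is stated without naming a test: all
groups normal → ANOVA or Welch ANOVA by the Levene gate; any group
non-normal → Kruskal–Wallis; two-group inputs route to Welch t /
Mann–Whitney under the same gate. Groups with fewer than three observations
cannot be normality-tested and route to the nonparametric branch with a
warning flag. A significant omnibus test triggers the matching post hoc
family with Holm adjustment: Tukey HSD after plain ANOVA, Dunn's rank test
after Kruskal–Wallis, and — a case the source leaves open — pairwise Welch
t-tests with Holm after Welch ANOVA, since Tukey's equal-variance
assumption is exactly what that branch rejected. Holm and Benjamini–
Hochberg adjustments are implemented directly (step-down/step-up with
monotonicity enforcement) and verified against `p.adjust` and an
exhaustive-k oracle. BH families are caller-defined, defaulting to one
family per marker across group pairs.

The power helper uses d = 2f and the two-sample normal-approximation
formula `n = 2(z_{1−α/2} + z_{power})²/d²` per group (33 at d = 0.8,
α = 0.05, power = 0.90); `correction = "t"` iterates with t quantiles and
yields 34. The normal approximation is the default because it is the
closed form the assumption d ≈ 0.8 was paired with.

## 5. Model development and validation

The development procedure is **LASSO screening followed by unpenalized
refit**: predictors are centred/scaled, a LASSO-penalized logistic
regression is fit over glmnet's log-spaced path with the penalty chosen by
stratified 10-fold cross-validation minimizing binomial deviance (1-SE rule
available by option), exact-zero coefficients are reported as excluded, and
the surviving predictors are refit by maximum likelihood. The refit step
mirrors the described two-stage practice (penalized pre-screening, then a
multivariable logit) and makes the reported original-scale coefficients the
MLE of the selected model; the penalized standardized path is kept
alongside. At λ = 0 the procedure reduces to plain logistic regression and
is tested against a hand-rolled Newton–Raphson oracle; at λ → ∞ it
collapses to the prevalence intercept. Complete separation in the refit is
flagged, not hidden.

`evaluate_model` computes the DeLong AUC of the logit score, the Brier
score, Cox–Snell and Nagelkerke pseudo-R², the calibration slope (an
unpenalized logistic refit of the outcome on the linear predictor; 1 means
no over/under-fitting), and cut-off-level classification metrics: confusion
counts, accuracy, sensitivity, specificity, MCC, Cohen's κ, an
**exact-binomial McNemar test** on the discordant cells (the variant that
reproduces the study's printed p = 0.383 from FP = 13 vs FN = 8), and a
one-sided exact binomial test of accuracy against the no-information rate.
Known discrepancy, surfaced rather than tuned away: the printed confusion
matrix (TN 35, FP 13, FN 8, TP 42) yields MCC = 0.573 and κ = 0.570,
whereas the source text prints MCC = 0.62 next to κ = 0.57; the matrix also
totals 98 while the cohort is 102. The standard formulas are implemented
and the matrix-consistent values are treated as canonical.

`riley_feasibility` implements the shrinkage-based minimum-sample-size
criterion `n ≥ p / ((S−1)·ln(1 − R²_CS/S))` with target shrinkage S = 0.9,
plus events-per-parameter, and flags feasibility at the study's n.

**Internal validation** reports two procedures separately, because how the
emulated study combined them is ambiguous: (a) stratified k-fold CV with
metrics computed once on the pooled out-of-fold predictions, and (b) the
optimism bootstrap — B class-stratified resamples, the *entire* development
procedure (including the LASSO screen) refit in each, optimism = bootstrap
performance minus performance of the same fit on the original data,
corrected = apparent − mean optimism. B = 0 returns apparent metrics
unchanged. On permuted labels the corrected AUC is unbiased around 0.5 but
a single realization at n = 200 carries roughly ±0.06 of Monte-Carlo noise,
so the null-experiment test averages over five permutations.

## 6. The synthetic world

No clinical data ships with the package ("data can be provided at official
request" is the source's availability statement), so a generator calibrated
to the published group summaries stands in. Its defaults *are* the stated
world: four groups (Control n = 50, atorvastatin n = 19, rosuvastatin
n = 21, no statin n = 12), the published mean ± SD for eight analytes
(mol%) and six indices per group, and pooled-atherosclerosis membership
drawn with probabilities 19/21/12 over 52.

Two simulation scales are deliberately kept separate and are not forced to
agree, because the published index rows are per-sample means whose joint
distribution with the analyte rows is unknown:

* **Analyte scale**: marginals are moment-matched per analyte — lognormal
  by default (`μ_log`, `σ_log` solved in closed form from the moment
  equations; percentages are positive and right-skewed, and the closed form
  makes the match exact, which the tests verify analytically, not only by
  sampling) — coupled through a Gaussian copula. Correlations are published
  nowhere; the default is a documented assumption of 0.3 within pathway
  blocks (C18:0+C18:1n-9; the omega-6 trio; the omega-3 trio) and 0 across,
  overridable per group. A synthetic `other` analyte absorbs
  `100 − Σ(drawn analytes)` so each profile is a valid composition. The
  alternative `truncated_normal` family resamples negative draws; that
  truncation raises the mean by exactly `s·φ(m/s)/Φ(m/s)` (up to ~4% for
  EPA, whose mean/SD ratio is lowest) — the tests check against this closed
  form rather than pretending the bias away.
* **Index scale**: index values drawn directly from the published index
  moments, Gaussian by default. Single-marker analyses depend only on
  marginals, so this mode needs no correlation assumption; it is the mode
  used by the acceptance simulations. For the logit-function targets the
  two predictors are drawn as *independent* normals per group — their true
  correlation is unknown; independence is the assumption stated in the
  acceptance setup.

The back-conversion `to_concentrations` draws a per-sample total molar pool
(default 11,000 ± 2,200 nmol/mL, roughly 3 mg/mL of total plasma fatty
acids, a typical fasting magnitude) and inverts the molar-percent map
exactly, which the round-trip tests verify to 1e-9.

**What a green suite establishes — and what it does not.** The generator
reproduces the published group *marginals* and therefore the single-marker
discrimination pattern (the acceptance AUCs land within ±0.03 of the
published values). It does not model diet, time on statin, covariates,
analyte–index joint structure, or real between-analyte correlation beyond
the block default; passing tests say the *methods* are correct and the
*summaries* are matched, not that the synthetic cohort is exchangeable with
the clinical one. Real-cohort p-values, the printed Cliff's deltas that
conflict with the 2·AUC−1 identity, and Brier/calibration/pseudo-R² point
values depend on unpublished joint distributions and are excluded from
acceptance on purpose.

## 7. Numerical and engineering notes

* Rank computations use midranks throughout; AUC, DeLong components and
  Cliff's delta share one placement routine, so the 2·AUC−1 identity is
  structural, not approximate. Tie pairs for the delta variance are counted
  per distinct value, keeping everything O(n log n) and comfortable at
  10⁵ scores per arm.
* Youden plateau detection compares J values within 1e-12; candidate
  thresholds are interval representatives, so adding a constant to all
  scores shifts the cut-off by exactly that constant.
* `fit_lasso_logistic` pads a single-predictor design with an all-zero
  dummy column (glmnet requires two columns) and drops it from every
  output; constant features are removed with a warning before scaling.
* Every stochastic entry point takes an explicit seed (`generate_cohort`
  and friends refuse to run without one); the pipeline's manifest records
  the seed, the selected λ and a config hash, and identical seeds produce
  byte-identical report tables (asserted in the tests).
* Infrastructure choices: `glmnet` backs the penalized path, base `stats`
  supplies the classical tests (Shapiro–Wilk, ANOVA/Welch, Kruskal–Wallis,
  Tukey HSD, exact binomial); Holm, BH, Wilson, Dunn, DeLong and Cliff's
  delta are implemented in-package because their exact conventions are part
  of the contract being tested, and each is verified against an independent
  oracle (`p.adjust`, closed forms, brute-force enumeration).

## 8. Known limitations

* The orientation registry covers the six markers analysed in the emulated
  study; other pathway ratios (`dgla_aa`, `epa_dpa`, `epa_dha`, `dpa_dha`)
  have no registered disease direction and must be oriented by the caller.
* Subgroup-specific multivariable models are out of scope (the subgroups
  are too small to support them); ridge/elastic-net penalties are not
  implemented beyond the LASSO default.
* The CV and bootstrap validators assume the model-development function is
  self-contained; resampling-based uncertainty for the Youden cut-off
  itself is reported only through the pipeline's validation block, not as a
  per-cut-off CI.
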