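# faindex

Plasma fatty-acid indices and diagnostic modelling for atherosclerosis.

## The problem

Atherosclerosis perturbs fatty-acid metabolism: plasma from affected
patients shows lower stearic acid (C18:0), higher oleic acid (C18:1n-9) and
an impaired flux through the long-chain polyunsaturated fatty-acid (PUFA)
elongation/desaturation pathways. Conventional plasma indices — the Omega-3
Status (EPA + DHA, mol%), the AA/EPA ratio and the omega-6/omega-3 ratio —
discriminate patients from healthy controls only weakly, and largely lose
their signal under statin therapy. `faindex` implements, as a tested and
fully reproducible pipeline, the analysis workflow around two
better-performing markers and their combination:

* the **stearic/oleic ratio** `C18:0/C18:1n-9` (an inverse index of
  stearoyl-CoA desaturase-1 activity),
* the **Omega-6/3 Balance Index**

  ```
  O6/3-BI = AA * sqrt(EPA * DPA) / (AdA * DHA)
  ```

  with AA = C20:4n-6, AdA = C22:4n-6 (all molar percent), which combines the
  omega-6 elongation ratio AA/AdA with omega-3 progression towards DHA,
  using the geometric mean of EPA and DPA to damp plasma EPA's short-term
  variability, and
* the **two-predictor diagnostic logit function**

  ```
  logit p = 5.254 - 0.145 * O6/3-BI - 11.544 * (C18:0/C18:1n-9)
  p = 1 / (1 + exp(-logit p))
  ```

  where both slopes are negative, so *high* logit scores mark disease.

The package is aimed at lipidomics and cardiovascular-biomarker researchers
who want to apply these indices to their own wide-format concentration
tables, or to study the statistical machinery (ROC with DeLong variance,
Youden mid-plateau cut-offs, Cliff's delta, LASSO-screened logistic
modelling with optimism-corrected internal validation) on calibrated
synthetic cohorts. The clinical study the defaults emulate is not publicly
available; a moment-calibrated generator stands in for it, so every stage of
the pipeline runs with no external data.

## What is in the box

| Module | Functions |
|---|---|
| Panel & molar percent | `default_panel()`, `read_cohort()`, `to_molar_percent()` |
| Indices | `omega3_status()`, `omega6_3_ratio()`, `pairwise_ratio()`, `o63_balance_index()`, `compute_index_set()` |
| ROC / effect sizes | `auc_delong()`, `youden_cutoff()`, `wilson_interval()`, `cliffs_delta()` |
| Group statistics | `compare_groups()`, `holm_adjust()`, `bh_fdr()`, `power_two_group()` |
| Modelling | `published_model()`, `predict()`, `fit_lasso_logistic()`, `evaluate_model()`, `riley_feasibility()`, `validate_model()` |
| Synthetic cohorts | `default_specs()`, `generate_cohort()`, `generate_index_cohort()`, `to_concentrations()` |
| Orchestration | `fa_pipeline_config()`, `run_pipeline()` |

## Worked example

Read the bundled synthetic cohort (per-analyte concentrations in ng/mL),
convert to molar percent, compute indices, and score with the published
diagnostic function:

```r
library(faindex)

path  <- system.file("extdata", "synthetic_cohort.csv", package = "faindex")
panel <- panel_with_other()          # 24-analyte panel + remainder column
conc  <- read_cohort(path, panel)    # below-LOQ cells parse to NA
mol   <- to_molar_percent(conc, panel)
idx   <- compute_index_set(mol, c("omega3_status", "c18_ratio", "o63bi"))
head(idx, 4)
#>     sample_id   group omega3_status c18_ratio o63bi
#> 1 Control_001 Control          2.06     0.432 24.72
#> 2 Control_002 Control          4.00     0.420  9.54
#> 3 Control_003 Control          3.70     0.454  3.98
#> 4 Control_004 Control          2.37     0.397  7.30

pred <- predict(published_model(),
                data.frame(o63bi = idx$o63bi, c18_ratio = idx$c18_ratio))
cbind(idx["group"], round(pred, 3))[c(1, 2, 5, 9), ]
#>          group logit_score probability
#> 1      Control      -3.313       0.035
#> 2      Control      -0.980       0.273
#> 5 Atorvastatin       0.360       0.589
#> 9     NoStatin       0.864       0.703
```

`probability` is the predicted probability of atherosclerosis: the two
control samples score low (0.03, 0.27), the two patient samples high (0.59,
0.70).

The full pipeline on a simulated study-sized cohort (n = 102 split
50/19/21/12 over the four groups, seeded and fully deterministic):

```r
cfg    <- fa_pipeline_config(seed = 1, validation_B = 50)
bundle <- run_pipeline(cfg, mode = "simulate")
subset(bundle$table2, marker %in% c("c18_ratio", "o63bi"))
#>              comparison    marker   auc     se ci_lo ci_hi  p_value
#> 5  Control-Atorvastatin c18_ratio 0.921 0.0313 0.860 0.982 2.70e-41
#> 6  Control-Atorvastatin     o63bi 0.762 0.0624 0.640 0.884 2.66e-05
#> 11 Control-Rosuvastatin c18_ratio 0.832 0.0612 0.712 0.952 5.51e-08
#> 12 Control-Rosuvastatin     o63bi 0.810 0.0510 0.711 0.910 1.11e-09
#> 17     Control-NoStatin c18_ratio 0.793 0.0711 0.654 0.933 3.73e-05
#> 18     Control-NoStatin     o63bi 0.767 0.0847 0.601 0.933 1.64e-03
```

Each row is one marker's ability to separate one patient subgroup from
controls on this particular simulated draw: the empirical AUC with its
DeLong standard error, Wald 95% CI, and the p-value of the test against
AUC = 0.5. The stearic/oleic ratio and the balance index discriminate well
in every subgroup, as in the cohort the generator is calibrated to (where
they reached 0.831–0.858 and 0.734–0.780 respectively).

## Repository layout

`R/` implementation · `tests/testthat/` unit, property and acceptance
suites · `scripts/acceptance.R` acceptance report ·
`vignettes/faindex-methods.Rmd` methods notes · `inst/extdata/` small
synthetic fixtures (labelled synthetic; no clinical data is included) ·
`inst/cli/faindex-pipeline.R` command-line entry point.
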