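# symptraj

Latent-class trajectories of depressive symptoms and their immunometabolic
correlates.

`symptraj` models developmental trajectories of repeated depressive-symptom
scores — the 13-item Short Mood and Feelings Questionnaire (SMFQ), measured
from late childhood to early adulthood — and relates the resulting trajectory
classes to clinical outcomes and high-dimensional blood-biomarker panels.
It implements:

- **SMFQ scoring** with the standard median-imputation rule for up to two
  missing items and a minimum-measurements eligibility filter
  (`score_smfq()`, `filter_eligible()`);
- **latent-class trajectory models** — group-based trajectory models (GBTM)
  and growth mixture models with common or class-proportional
  random-intercept variance — over fractional-polynomial age bases, fitted by
  multistart maximum likelihood (`fit_trajectory()`, `trajectory_spec()`,
  `fp_basis()`);
- **model selection** by BIC, integrated completed likelihood and relative
  entropy with class-share, average-posterior-probability and
  odds-of-correct-classification adequacy gates, producing an auditable
  decision trail (`select_model()`, `fit_indices()`);
- **outcome association** by modified Poisson regression (log-link Poisson
  GLM with robust sandwich standard errors, yielding adjusted risk ratios),
  OLS for continuous outcomes, classification-uncertainty sensitivity modes,
  and Benjamini–Hochberg FDR control (`fit_binary_outcome()`,
  `associate_outcomes()`);
- **biomarker screening** with per-analyte linear models and empirical-Bayes
  moderated t-statistics, including the protein limit-of-detection filter and
  the metabolomic feature-redundancy filter (`analyze_biomarkers()`,
  `ebayes_moderate()`, `lod_filter()`);
- **derived clinical indices** — HOMA-IR, AST/ALT ratio and the harmonised
  metabolic-syndrome classification with decision-invariant missing-data
  logic (`homa_ir()`, `metabolic_syndrome()`);
- a **synthetic-cohort generator** that plants known classes, risk ratios and
  analyte shifts (`generate_cohort()`, `generate_outcomes()`,
  `generate_biomarker_panel()`), so every estimator is validated by parameter
  recovery — the motivating class of cohort studies uses managed-access data
  that cannot be redistributed;
- an **end-to-end pipeline** with per-stage artifacts and provenance
  (`run_pipeline()`).

See `vignettes/symptraj-methods.Rmd` for the statistical background and the
rationale behind the numerical choices.

## Worked example

Simulate a cohort with four planted trajectory classes, score it, fit a
class-number sweep, select the model and estimate adjusted risk ratios for a
planted binary outcome:

```r
library(symptraj)

cfg <- cohort_config(n_subjects = 2000, seed = 2)
cohort <- generate_cohort(cfg)
scores <- score_smfq(cohort$occasions)
fl <- filter_eligible(scores)           # >= 3 measurements to enter the fit

fits <- lapply(1:5, function(G)
  fit_trajectory(trajectory_spec(G), fl$fitting, seed = 100 + G))
report <- select_model(fits, fl$fitting)
report$chosen_fit
#> Fitted 4-class GBTM | loglik -32752.896 | 1998 subjects | converged: TRUE
#> mixing proportions: 0.695 0.124 0.104 0.077

round(subset(report$candidates,
             select = c(G, BIC, ICL, relative_entropy,
                        smallest_class_share)), 3)
#>   G      BIC      ICL relative_entropy smallest_class_share
#> 1 1 73461.44 73461.44            1.000                1.000
#> 2 2 67575.68 67626.34            0.982                0.198
#> 3 3 66007.71 66093.82            0.980                0.078
#> 4 4 65627.39 66277.78            0.883                0.077
#> 5 5 65657.91 68212.62            0.603                0.077
```

The planted mixing proportions were 69.7/13.3/10.0/7.0 percent; the selected
4-class fit recovers 69.5/12.4/10.4/7.7 (classes are reported in descending
order of mixing proportion, so fitted labels need not match the generator's
ordering). Assign everyone (including subjects with fewer than three
measurements) and estimate adjusted risk ratios for a planted outcome
(true RRs 3.65, 13.11 and 6.25 versus the low-stable class):

```r
post <- predict_class(report$chosen_fit, scores,
                      subject_ids = cohort$subjects$subject_id)
outcomes <- generate_outcomes(cohort, default_outcome_configs(4), seed = 902)

d <- merge(cohort$subjects, outcomes, by = "subject_id")
d$traj_class <- post$modal_class[match(d$subject_id, post$subject_id)]
rr <- fit_binary_outcome(d, "depressive_episode", model = "adjusted")
print(rr, row.names = FALSE)
#>             outcome contrast_class   effect        se   ci_low   ci_high
#>  depressive_episode              2 2.686723 0.2361908 1.691115  4.268473
#>  depressive_episode              3 3.044834 0.2739479 1.779814  5.208981
#>  depressive_episode              4 8.661592 0.1832761 6.047696 12.405251
#>       p_value
#>  2.858910e-05
#>  4.814660e-05
#>  4.979661e-32
```

In this cohort the fitted label 4 corresponds to the planted persistent
class: its adjusted RR of 8.66 versus the planted 13.11 illustrates the
attenuation that modal-class misclassification induces — the acceptance
recovery targets therefore evaluate the estimator on known classes, and
`fit_binary_outcome()` offers posterior-based sensitivity modes for assigned
classes.

Screen a planted protein panel with moderated t-statistics (the shift was
planted on the persistent class, fitted label 4 here):

```r
panel <- generate_biomarker_panel(
  cohort, protein_catalogue(),
  class_shifts = data.frame(analyte = "IL6", class = 3, shift = 1),
  seed = 3)
design <- cohort$subjects
design$traj_class <- d$traj_class[match(design$subject_id, d$subject_id)]
res <- analyze_biomarkers(panel, design, family = "protein")
res
#> Moderated contrasts: 201 rows | d0 = 25605, s0^2 = 0.9244 | 2 FDR hits at q = 0.1
subset(res$table, fdr_significant)
#>     analyte contrast   estimate         se         t            p neg_log10_p
#> 135     IL6        4  1.1117096 0.08189156 13.575387 7.639217e-42    41.11695
#> 180  IL10RB        4 -0.2522835 0.08190260 -3.080287 2.070045e-03     2.68402
```

The one pipeline call `run_pipeline(pipeline_config(...), out_dir)` chains
all stages and writes CSV/JSON artifacts with provenance.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "symptraj", load_package = "installed")'
```

The suite contains per-module unit and property tests (closed-form oracles,
EM monotonicity, boundary grids, `limma` cross-checks) plus an acceptance
file (`tests/testthat/test-acceptance.R`) exercising the headline
parameter-recovery behaviours end to end. The full run takes on the order of
ten minutes on one CPU; the acceptance file dominates.

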