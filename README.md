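# irrs — immune cell-pair risk scores for survival prognosis

Bulk tumor transcriptomes carry a readout of the tumor immune
microenvironment, but absolute immune-cell abundance estimates are fragile:
they shift with sequencing platform, annotation version and deconvolution
method. `irrs` implements a prognostic model that sidesteps absolute scales
entirely by working with **within-sample orderings of immune cell types**.
It was designed around cutaneous melanoma cohorts (where tumor-infiltrating
immune cells are strongly prognostic) but applies to any right-censored
cohort with a bulk expression matrix and a collection of cell-type signature
gene sets.

The package is aimed at computational biologists building or validating
transcriptomic risk scores: it provides the full training cascade, a scorer
for external cohorts, a prognostic evaluation battery, and a synthetic
cohort generator with planted ground truth so every stage can be tested
without any data download.

## The model

1. **Abundance surrogate.** For each sample *j* and cell-type signature *G*,
   a single-sample enrichment score ES(*G*, *j*) is computed from the
   within-sample gene ranking (integrated weighted running sum, weight
   exponent α = 0.25). Scores are invariant to any strictly increasing
   transform of a sample's expression values.
2. **Cell pairs.** Cell types prognostic in univariate Cox regression
   (Wald *P* < 0.05) are paired with every cell type in the vocabulary.
   Each ordered pair (A, B) becomes a binary feature per sample:

   `Score_A|B(j) = 1 if ES(A, j) > ES(B, j), else 0`

   Pairs that are 0 or 1 in more than 80% of samples are removed (they
   encode systematic abundance differences between cell populations, not
   between-patient information).
3. **Selection cascade.** Surviving pairs are screened by univariate Cox
   (*P* < 0.05), reduced by cross-validated LASSO Cox, and fit jointly by
   multivariate Cox (Efron ties; optional backward elimination by AIC).
4. **Risk score.** The immune-related risk score is the exact linear form

   `IRRS(j) = Σ_pairs Score_A|B(j) × Coef_A|B`

   with no intercept and no standardization. Cohorts are stratified at the
   median IRRS (samples exactly at the median go to the low-risk group).

The evaluation battery covers Kaplan–Meier curves and the log-rank test,
Harrell's C-index, time-dependent cumulative/dynamic ROC AUC with
inverse-probability-of-censoring weights, integrated discrimination
improvement (IDI), decision-curve net benefit, calibration curves, and a
nomogram-style combined clinical Cox model with 0–100 points scaling and
closed-form survival prediction `S(t|x) = S0(t)^exp(lp)`.

A published six-pair melanoma model (with its multivariate Cox
coefficients) ships with the package: `irrs_published_model()`.

## Worked example

Simulate a cohort with two planted prognostic cell pairs, fit the full
cascade, and evaluate the score:

```r
library(irrs)

cohort <- simulate_cohort(n_samples = 250, n_cell_types = 10,
                          n_true_pairs = 2, true_coef = 1.0,
                          genes_per_signature = 8,
                          n_background_genes = 200, seed = 42)
fit <- irrs_fit(cohort$expression, cohort$gene_sets, cohort$survival,
                seed = 42)
fit$stage_report
#> # A tibble: 7 × 2
#>   stage                         count
#>   <chr>                         <int>
#> 1 cell_types_scored                10
#> 2 prognostic_cells                  4
#> 3 pairs_enumerated                 40
#> 4 pairs_after_prevalence_filter    36
#> 5 pairs_after_cox_screen           17
#> 6 pairs_after_lasso                12
#> 7 pairs_in_final_model              5

tidy(fit$model)
#> # A tibble: 5 × 7
#>   pair                      a_cell       b_cell         coef std_error  p_value hazard_ratio
#> 1 Cell type 01|Cell type 06 Cell type 01 Cell type 06 -0.708     0.206 0.000595        0.493
#> 2 Cell type 01|Cell type 08 Cell type 01 Cell type 08 -0.538     0.203 0.00796         0.584
#> 3 Cell type 05|Cell type 07 Cell type 05 Cell type 07 -0.394     0.213 0.0636          0.674
#> 4 Cell type 05|Cell type 09 Cell type 05 Cell type 09 -0.305     0.196 0.120           0.737
#> 5 Cell type 07|Cell type 10 Cell type 07 Cell type 10  0.419     0.199 0.0348          1.52

ev <- irrs_evaluate(fit$scores, cohort$survival, horizons_years = c(1, 3, 5))
ev$c_index
#> [1] 0.674
ev$auc
#> # A tibble: 3 × 2
#>   horizon_years   auc
#> 1             1 0.654
#> 2             3 0.727
#> 3             5 0.730
ev$logrank
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#> 1      43.2     1 5.06e-11
```

The planted truth in this cohort was the pair `Cell type 08|Cell type 01`
with coefficient +1 and `Cell type 05|Cell type 07` with −1; the fitted
model contains the first as its reciprocal (`Cell type 01|Cell type 08`,
negative coefficient — statistically equivalent since
`Score_B|A = 1 − Score_A|B`) and the second directly, plus a few correlated
companions. The stage counts show the cascade narrowing 40 enumerated pairs
to a 5-pair model; the median split separates survival decisively
(log-rank *P* ≈ 5×10⁻¹¹).

Scoring an external cohort only needs the model document, the new
expression matrix and the signature GMT:

```r
scores <- irrs_score(fit$model, new_expression, gene_sets,
                     median_policy = "cohort")
```

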