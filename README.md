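# smokesurg

Smoking is one of the few modifiable risk factors a patient brings to the
operating table, but in most hospital systems smoking status lives only in
free-text clinical notes. `smokesurg` implements, as a tested and reusable R
pipeline, the full computational chain of a registry study of smoking and
90-day postoperative complications:

1. **Sentence classification with abstention.** Finnish-style EHR sentences
   containing the word stems `tupak*` (tobacco/smoking), `aski*` (pack) or
   `smok*` are normalized and classified into *current smoker*, *ex-smoker*,
   *never-smoker* or *unknown* by a hashed bag-of-n-grams linear softmax
   classifier. Per-class probability thresholds, tuned on a validation split
   so that each known class reaches a required precision (default 0.95),
   reroute uncertain predictions to *unknown* — trading recall for the
   precision a risk-factor analysis needs.
2. **Surgery-level status assignment.** Timestamped classified sentences are
   collapsed to one preoperative status per surgery: the most recent
   preoperative status wins, *unless* it is never-smoker while an earlier
   note documents smoking, in which case the patient is an ex-smoker.
3. **Covariates and outcomes.** The Charlson comorbidity index is computed
   from ICD-10 codes (Quan coding, shipped as an editable CSV, with the
   supersession hierarchy), and 90-day overall and critical
   (Clavien–Dindo IV–V style) complication composites are flagged from
   diagnosis and care events in the inclusive `[0, 90]`-day window.
4. **Risk modelling.** Binary logistic regression gives unadjusted and
   adjusted odds ratios (adjustment: age, sex, ASA class, CCI band) with
   Wald 95% intervals,

   `OR = (a/b)/(c/d)`, `CI = exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`,

   plus relative variable importance by partial Wald chi-squared
   `X = bᵀV_b⁻¹b` per coefficient block and by mean |Shapley value| of each
   variable on the log-odds scale (closed form for the additive linear
   predictor, with a Monte-Carlo permutation sampler as cross-check), and
   McFadden/Nagelkerke pseudo-R².
5. **Synthetic registry.** Because no public surgical registry of this shape
   exists, a first-class generator produces labelled smoking sentences and a
   confounded cohort — ex-smokers oldest and sickest — whose conditional
   (adjusted) odds ratios are configured directly, so parameter recovery and
   the unadjusted-vs-adjusted confounding gap are testable end to end.

The package is aimed at clinical epidemiologists and research engineers who
want to reproduce, stress-test or adapt this kind of EHR-based risk-factor
pipeline without access to the original hospital data.

## Worked example

```r
library(smokesurg)

## published-table arithmetic: ex-smoker vs never-smoker, any complication
odds_ratio_2x2(10401, 12700, 27994, 62214)
#> OR 1.82 (95% CI 1.77 to 1.87)

## end-to-end study on a synthetic registry
cohort <- generate_cohort(cohort_config(n_patients = 20000, seed = 1))
corpus <- generate_corpus(corpus_config(n_sentences = 10000, seed = 1))
report <- run_study(cohort, corpus = corpus)
print(report)
#> Study report: 20000 surgeries in analysis set
#> ...
#> Smoking-status odds ratios:
#>      model adjustment   group    or ci_low ci_high
#> 1  overall unadjusted current 1.409  1.318    1.51
#> 2  overall unadjusted      ex 1.842  1.697    2.00
#> 3  overall   adjusted current 1.255  1.169    1.35
#> 4  overall   adjusted      ex 1.121  1.024    1.23
#> ...
```

The unadjusted ex-smoker odds ratio (1.84 here) is far above the adjusted
one (1.12) although the generator's true conditional effect is 1.09: the
confounding built into the cohort (ex-smokers are older, carry higher ASA
classes and more comorbidity) inflates the crude association, exactly the
pattern the adjustment is there to remove. The report also contains the
exclusion-flow table, a baseline table, yearly smoking ratios, the
variable-importance decomposition

```r
report$importance[report$importance$model == "overall", -1]
#>        variable  chisq df share_pct mean_abs_shapley
#>  age_at_surgery 363.33  1    25.093           0.2478
#>          status  39.49  2     2.727           0.0922
#>             sex   2.87  1     0.198           0.0265
#>       asa_class 887.52  4    61.296           0.3953
#>        cci_band 154.72  5    10.686           0.1291
```

(ASA class dominates, smoking status and age are of the same order — the
qualitative ranking reported for the real registry), and the evaluation of
the tuned abstaining classifier on its held-out split
(`report$nlp_evaluation`).

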