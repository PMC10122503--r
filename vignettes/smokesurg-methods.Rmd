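---
title: "Methods: smoking-status extraction and complication risk modelling"
author: "smokesurg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoking-status extraction and complication risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations of `smokesurg`. The package implements a
complete registry-study pipeline: free-text smoking-status classification
with abstention, surgery-level status assignment, comorbidity and outcome
construction, and logistic-regression risk modelling with
variable-importance decompositions — together with a synthetic-data module
that stands in for the hospital registry such studies run on.

## 1. The sentence classifier

### Model

Sentences are normalized (lower case; everything except letters —
including å/ä/ö — digits and spaces removed; whitespace collapsed) and
filtered to those containing a token starting with `tupak`, `aski` or
`smok`. Each retained sentence is represented by its unigrams and bigrams,
hashed (32-bit FNV-1a) into a fixed table of buckets. The model averages
the bucket embeddings and applies a linear layer with a softmax over the
four classes `current`, `ex`, `never`, `unknown`; both layers are trained
jointly by plain SGD on the cross-entropy, single-threaded, with a
linearly decaying learning rate. This is the classical
averaged-embedding linear text classifier: fast, deterministic, and strong
on short formulaic clinical sentences.

### Hyperparameters

The defaults are pinned in `nlp_config()` for reproducibility:
2^18 hash buckets, embedding dimension 32, n-gram order 2, 10 epochs,
initial learning rate 0.1, one seed controlling initialization, shuffling
and splits. None of these is critical on template-generated corpora; the
bucket count is generous to keep hash collisions rare, and bigrams are what
separate "lopettanut tupakoinnin 3/20" (quit with a date → ex-smoker) from
"lopettanut tupakoinnin hiljattain" (quit "recently" → unknown).

### Abstention

`apply_threshold_policy()` returns the argmax label only if the argmax is
a known class *and* its probability reaches that class's threshold;
otherwise the sentence is `unknown` (an argmax of `unknown` is always
returned as such). `tune_thresholds()` chooses the per-class thresholds on
a validation set by grid search (step 0.05 over [0, 1]³), maximizing the
total number of correctly retained known-class sentences subject to each
known class's precision being at least `min_precision_known`
(default 0.95). The published account of this tuning step says only that
thresholds were "tuned in favour of specificity"; the constrained
recall-maximization above is this package's formalization of that
objective. Because a sentence's assignment to class *c* depends only on
θ\_c, the three-dimensional grid decomposes exactly into three per-class
scans, which is how it is computed; a test verifies the decomposition
against brute-force enumeration of the full grid. Ties break toward lower
thresholds; an infeasible class gets threshold 1 (all-abstain) with a
warning.

### Evaluation conventions

Precision and recall are per class with normal-approximation 95% intervals
(p ± 1.96·√(p(1−p)/n), n the metric's denominator); a zero-denominator
metric is reported as `NA`, never as 0. Macro averages are unweighted means
over the three known classes, excluding `unknown`. The weighting behind a
published "average recall" of this kind of classifier is ambiguous (an
unweighted mean of per-class recalls and a support-weighted mean can
differ a lot when abstention hits classes unevenly), so `evaluate()`
reports both and asserts neither. Argmax ties resolve to the earlier class
in the fixed order current < ex < never < unknown.

## 2. Surgery-level status assignment

Among observations dated on or before the surgery (same-day notes count as
preoperative — admission notes are typically written on the day), the most
recent status is assigned, unless that status is `never` while *any*
earlier preoperative observation is `current` or `ex`: then the patient is
an `ex`-smoker. The override is status-level, not pairwise — one documented
smoking episode anywhere in the history suffices — and it can only produce
`ex`, never `current`. Same-day conflicts resolve by the precedence
current > ex > never, conservative toward detecting smoking exposure; the
source material is silent on this tie. A surgery with no preoperative
observation is `unknown` and is excluded by `build_analysis_set()`, which
also drops ages below 16 and missing ASA class and emits a flow table that
reconciles exactly at every step.

## 3. Comorbidity and outcomes

The Charlson comorbidity index uses the Quan ICD-10 coding with the
original Charlson weights, shipped as an editable CSV
(`inst/extdata/charlson_icd10_quan.csv`). Matching is prefix-based on the
dot-free upper-case code, overlaps resolved by longest prefix; the
hierarchy (metastatic tumour ⊃ localized cancer, moderate/severe ⊃ mild
liver disease, complicated ⊃ uncomplicated diabetes) removes both flag and
weight of the superseded category. The regression covariate is the *count*
of comorbid categories, banded 0/1/2/3/4/≥5 — the emulated study's
baseline table footnotes the count, not the weighted score — but the
weighted score is computed alongside for users who prefer score bands. The
lookback window for comorbidity codes is all recorded history by default
(the original study does not state one); a per-patient cutoff at the
(first) surgery date is always applied.

The outcome composites are prefix/event lists in an inclusive
`[surgery, surgery + 90]`-day window; day 0 counts as perioperative and
day 90 is in ("within 90 days" read as days 0–90; the boundary convention
is this package's and is declared, since the source is silent). The exact
ICD-10 composite behind the published study lives in supplementary
material that is not reproduced here; the shipped default list is
representative (wound, cardiovascular, neurological, respiratory,
thromboembolic, gastroenterological, urinary, orthopaedic, unspecified
bacterial infection codes plus death, reoperation, readmission,
ICU/ventilation) and fully overridable via CSV. The critical composite —
acute coronary syndrome, shock, cerebral infarction, pulmonary embolism,
peritonitis, plus ICU/ventilation and death only — is a strict subset of
the overall one by construction, so `critical ⇒ overall` holds on every
surgery; re-intervention (grade III) paths are deliberately excluded.

## 4. The risk models

Logistic models are fitted by IRLS (`stats::glm`) with a tightened
convergence tolerance (1e-14) so that on data collapsed from a 2×2 table
the Wald interval of the fitted coefficient reproduces the closed-form
`odds_ratio_2x2()` interval to ~1e-10. Treatment coding with declared
references: never-smoker, female, ASA 1, CCI band 0; age enters in years,
uncentered. ASA is modelled as five distinct levels. Rows with missing
covariates are dropped and counted. Complete separation (residual deviance
~ 0) and quasi-separation (a diverging coefficient) are reported as errors
naming the covariate; no continuity correction or penalization is applied,
matching the plain-ML analysis being reproduced.

Variable importance is reported two ways. The partial Wald chi-squared of
each variable's coefficient block b with covariance block V is bᵀV⁻¹b
(singular blocks fall back to a pseudo-inverse with a warning), normalized
to percentage shares. Shapley values are computed on the linear-predictor
(log-odds) scale with the in-sample covariate means as baseline; for an
additive predictor the Shapley value has the closed form
φ\_j(i) = Σ\_{k∈j} β\_k (x\_ik − x̄\_k) with dummy columns grouped per
variable, which the default `exact_linear` mode uses (efficiency
Σ\_j φ\_j(i) = η(i) − mean η holds to 1e-9 on every row). The `montecarlo`
mode estimates the same quantity by sampling permutations of the variables
with absent variables held at their means; for this value function every
marginal contribution is the group's own additive term, so the sampler
agrees with the closed form up to floating-point error — it exists as a
structural cross-check and a template for non-additive extensions.
Pseudo-R²: McFadden 1 − ℓ/ℓ₀, Cox–Snell, and Nagelkerke (Cox–Snell over
its maximum).

No multiple-testing adjustment is applied anywhere, matching the analysis
being reproduced.

## 5. The synthetic registry

`generate_cohort()` draws, per patient: smoking status (defaults at the
emulated registry's mix, 56.9% never / 14.6% ex / 28.6% current); sex and
ASA class from per-status tables; age from a per-status truncated normal
on [16, 100] years (never 56±18, ex 64±14, current 53±16 — ex-smokers are
the oldest, as in the registry's baseline table); and the 17 Charlson
categories as Bernoulli draws whose log-odds share a per-patient N(0, 1.4)
frailty. The frailty makes comorbidities cluster within patients, which is
what populates the ≥4-comorbidity bands registry data show; per-category
intercepts are recalibrated by root-finding so the marginal prevalences
still match the configured per-status values (the smoking-related
categories follow the baseline table; the rest are plausible defaults —
matching every baseline cell exactly is a non-goal).

Complications are drawn from a logistic model on status, age, sex, ASA and
CCI band. The status effects are the configured *conditional* odds ratios
(defaults: ex 1.09, current 1.17 overall; ex 1.09, current 1.21 critical —
the adjusted estimates of the emulated study); the non-smoking effects are
fixed plausible values (per-year OR 1.02, male 1.1, ASA 1/1.8/3/5/8,
CCI band 1/1.2/1.45/1.7/2/2.4) chosen so that ASA dominates the importance
decomposition as it does in practice. The intercept is calibrated by
root-finding so the never-smoker marginal risk equals the configured
baseline (31.0% overall, 3.3% critical). Overall and critical indicators
use their *own* logistic models coupled through one shared uniform per
surgery (comonotone coupling): each marginal model is exact and
critical ⊆ overall by construction. Confounding is therefore structural:
the unadjusted ex-smoker OR comes out around 1.8 against a configured
conditional 1.09, purely because ex-smokers are generated older and
sicker.

Events are then materialized: comorbidity codes 30–1825 days before the
first surgery; complication ICD codes uniformly on post-surgery days 1–90
(care events on days 0–90; keeping coded complications off day 0 prevents
a same-day complication code from leaking into the ≤-surgery-date
comorbidity lookback); complication-list codes *outside* the window
(days 91–240) and unrelated codes *inside* it as noise that the
window/prefix filters must reject; at most one death per patient and no
events after death. Status notes get rendered Finnish-style sentence text
from the same template families as the corpus generator. A configurable
fraction (default 10%) of ex-/current-smoker patients carries conflicting
timestamped notes in patterns the assignment rule resolves back to the
true status (an ex-smoker whose latest note reads "never" after an earlier
"current" exercises the never→ex override); never-smokers cannot carry a
class-conflicting note without the rule changing their status, so
conflicts are confined to ever-smokers by design.

What the generator does **not** emulate: real Finnish grammar and
vocabulary breadth (template families with slot fillers and character
noise only), pack-year dose information, repeated-measures correlation
when a patient has several surgeries (the default is one surgery per
patient; the emulated analysis also ignored clustering), per-specialty
differences in status-conditional risk (specialty is a label with a
configurable mix), and annotator disagreement. Passing tests on this
registry therefore demonstrate that the *pipeline machinery* is correct
and recovers known truth under realistic confounding — not that the
classifier would reach the same precision on real clinical Finnish, nor
that real adjusted odds ratios are unbiased for unmeasured confounding.

## 6. Problem sizes and numerical conventions

The test suite and the acceptance script use: corpora of 10 000 sentences
(noise 0.05) with an 80/10/10 train/tune/evaluate split over five seeds;
cohorts of 20 000 surgeries over 100 seeds for parameter recovery (the
adjusted 95% intervals are checked to cover the configured truth in at
least 90 of 100, the nominal-coverage expectation with Monte-Carlo slack);
and 100 000-row draws for law-of-large-numbers checks at 1% tolerance.
These sizes were chosen so each check is statistically meaningful at
desk-scale compute.

Conventions worth knowing when extending the package: all generator and
training randomness flows from explicit integer seeds through one RNG
stream (`with_seed()` restores the caller's RNG state); probability
vectors must sum to 1 within 1e-9; ICD-10 codes are validated as
letter + two digits and invalid codes are skipped with a warning; report
tables round ORs to 2 decimals and shares to 1; report files are written
atomically (temp file + rename). Degenerate inputs have defined behavior:
an empty sentence predicts the uniform distribution and is flagged; an
empty code set gives CCI 0; a 2×2 table with a zero cell is an error (no
silent continuity correction); a class absent from training data is an
error; cohorts under 100 patients warn about unstable marginals.

## 7. Limitations

The published sentence-level precision/recall of the original classifier
were measured on a private annotated corpus and cannot be reproduced here;
the synthetic corpus is deliberately learnable, so the classifier's
near-perfect synthetic performance is an upper bound, not a forecast. The
shipped outcome code list is representative, not the study's exact
supplementary list. The critical-outcome severity coupling makes the
critical model's status effects exact marginally but, because critical is
forced inside overall, joint properties beyond the two marginals are not
controlled. CCI is computed once per patient at the first analysis surgery
rather than per surgery in multi-surgery mode.
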