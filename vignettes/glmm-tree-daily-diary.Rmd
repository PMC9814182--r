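---
title: "Predicting next-day risk from daily diaries with GLMM trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting next-day risk from daily diaries with GLMM trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adolescents discharged from psychiatric inpatient care are at sharply
elevated short-term risk of suicidal ideation. Intensive longitudinal
designs — here, a brief survey texted every evening for four weeks —
make it possible to ask a clinically actionable question: *given what an
adolescent reported today, how likely are they to experience suicidal
ideation tomorrow?* `dailycart` implements the full analysis pipeline
for that question: person-specific feature construction from the daily
items, a mixed-effects model-based classification tree (GLMM tree),
participant-blocked stratified repeated cross-validation, ROC-based
cutoff selection, and extraction of the fitted tree as an explicit,
auditable decision rule. A calibrated synthetic generator stands in for
the original (non-deposited) patient data, so every stage is testable.

```{r, message = FALSE}
library(dailycart)
```

## The daily instrument and its features

Ten bounded items are collected daily (hopelessness, connectedness to
friends and to family, burdensomeness, agitation, worry, rumination,
self-efficacy to refrain from suicidal action, psychological pain, and
ideation duration) alongside an ideation-frequency item from which the
binary outcome is derived (`0` stays 0; any frequency 1–4 becomes 1).
`item_schema()` records the ranges; values outside them are rejected at
read time.

For each item and participant, day-`t` information is summarised three
ways:

* **previous-day score** — the raw day-`t` response;
* **cumulative person-specific mean (CM)** — the mean of the
  participant's *own* responses over completed surveys on days `1..t`,
  inclusive of day `t`. The inclusive convention implies the deviation
  is identically zero on a participant's first observed day;
* **deviation / change score (CS)** — the day-`t` response minus the
  CM, an acute departure from the person's running baseline.

The *simple* models use the 10 previous-day scores; the *complex*
models use the 10 CMs plus the 10 CSs. Every variant adds three context
indicators: study week (1–4, computed from the outcome day), day of
week (Mon–Sun; we also index the day-of-week from the outcome day —
the convention is arbitrary because calendar alignment is unknowable
for simulated data, and it keeps both context variables on the same
clock), and whether the previous-day survey was missed. Duration-free
variants drop all ideation-duration predictors, giving predictor
counts 13/23/12/21.

Missing data are handled asymmetrically, and deliberately so. A missed
*predictor* day keeps its row: the missingness indicator is set, the CM
is carried forward (it is a running mean over completed days), and the
raw score/deviation are absent — the tree learner routes missing values
along the majority branch recorded at fit time. A missed *outcome* day
excludes the row, because the outcome cannot be scored and we refuse to
impute it. Participants without at least two consecutive completed
surveys contribute no usable lagged pair and are excluded.

Because all engineered features are within-person functions of days
`1..t` only, computing them once on the full table before
cross-validation cannot leak information across participants or from
the future; the test suite audits this by truncating the data at day
`t` and checking that surviving rows are bit-identical.

## The GLMM tree

The learner alternates two steps until the mixed-model log-likelihood
changes by less than `1e-4` (at most 100 rounds):

1. **Tree growth with offsets.** With each observation's current random
   intercept held fixed as an offset, a classification tree is grown on
   the log-odds scale. At each node an intercept-only logistic model is
   fitted and, for every candidate predictor, a score-based parameter
   instability test is computed: ordering the score residuals by an
   ordered candidate and taking the supremum of the squared
   standardised cumulative-sum bridge over the trimmed range (a
   supLM-type statistic; default trim 0.1), with the tail probability
   from the Miller–Siegmund approximation for maximally selected
   statistics — the node model's score is one-dimensional, so the
   scalar form applies. Categorical candidates use a chi-square on
   per-level residual sums. P-values are Bonferroni-multiplied by the
   number of candidates tested at the node, and the node splits on the
   smallest adjusted p-value only if it is below `alpha` (default
   0.05); ties go to the earliest predictor in declared order. This
   "test first, then split" design is what makes selection unbiased:
   variables with many split points get no advantage.
2. **Random-intercept refit.** With leaf membership as a fixed-effect
   factor, a random-intercept logistic model is estimated by Laplace
   approximation (`lme4::glmer`), updating the per-participant
   intercepts and their standard deviation `sigma_b`.

The split *point* for the selected variable maximises the two
children's binomial log-likelihoods under the current offsets, over
midpoints of adjacent distinct values, subject to `min_node_size`
(default 50, roughly 3% of a full study's rows). For continuous
variables with more than 100 distinct values the candidate midpoints
are thinned to a quantile-spaced grid of 100 — a resolution far finer
than any threshold difference of scientific interest. Categorical
splits order levels by mean score residual and scan contiguous
prefixes, the classical shortcut that is exact for binary outcomes.
Leaf probabilities are smoothed empirical rates `(events + 0.5)/(n + 1)`
so that no leaf is ever exactly 0 or 1.

Two numerical points deserve note. First, the alternation's
log-likelihood trace is *not* guaranteed monotone: when the updated
intercepts absorb variation that the first tree had captured with extra
splits, the next tree is simpler and its integrated likelihood can be
lower despite being the better model. The trace must (and does)
stabilise; the tests assert convergence rather than monotonicity.
Second, the Miller–Siegmund tail curve is non-monotone below its peak,
where the true tail probability is essentially 1; statistics below the
peak are evaluated at the peak, keeping the reported p-value monotone
in the statistic. Neither point affects decisions at `alpha = 0.05`.

Prediction routes a row to its leaf, with missing values following the
recorded majority branches. Cross-validated predictions never use
random effects: test-fold participants are unseen by construction, so
they receive the population-level leaf probability (`b = 0`).

## Cross-validation and metrics

Folds block on participants — every row of a participant shares a fold
— because rows within a person are strongly dependent and splitting
them across train and test would flatter the model. Folds are also
stratified: participants are labelled high or low risk by a median
split of their observed proportion of ideation-endorsed days (ties at
the median go low, so the median participant is never "high"), shuffled
within stratum with a seeded RNG, and dealt round-robin, which bounds
the per-fold stratum imbalance by one. The default protocol is 5 folds
repeated 10 times.

Out-of-fold predictions are pooled *within* each repetition, and one
ROC is computed per repetition; the reported mean and standard error
(`sd/sqrt(R)`) are taken across repetitions. Pooling per repetition
(rather than averaging per-fold estimates) matches reporting a single
cross-validated value per round with a small across-round dispersion.
The operating cutoff is chosen by the closest-top-left criterion —
minimise `(1 - sensitivity)^2 + (1 - specificity)^2` — with ties broken
toward the lower, more sensitive cutoff, a deliberate choice for a
screening context where missing an event costs more than a false
alarm. Classification uses `score >= cutoff` (inclusive). AUC is
computed in Mann–Whitney form, which equals the trapezoidal ROC
integral exactly, ties counted as half.

## The synthetic generator

The generator reproduces the statistical structure the analysis
assumes, under the motivating study's design conditions: 78
participants, 28 days, 26% of surveys missing completely at random, and
39% of completed days with any ideation. Each participant receives a
random intercept (`sd` 1 by default) and, per item, a latent AR(1)
process (autocorrelation 0.5, stationary SD 1) around a person-specific
mean (between-person SD 1), observed rounded and clipped to the item's
range. Next-day ideation is Bernoulli with log-odds equal to a
ground-truth *tree* evaluated on the running features, plus the
intercept, plus a calibration constant solved by bisection on a pilot
draw of at least 50,000 person-days so the realised prevalence hits the
target. Ideation frequency is 0 on ideation-free days and truncated
geometric on 1–4 otherwise; duration is 0 exactly when frequency is 0.
The AR(1)-around-a-person-mean design is not incidental: the analysis
decomposes items into cumulative means and deviations, and the
generator must give both components signal to carry.

The default ground-truth rule splits on the cumulative burdensomeness
mean (threshold 4) and then the cumulative hopelessness mean
(threshold 2.5), with leaf offsets −0.9/0.2/1.4 — a large but plausible
subgroup contrast that places the recoverable signal in the cumulative
means. An optional mode makes missingness depend on previous-day
ideation, for stress-testing the missingness indicator; it is off by
default because the motivating design gives no basis for choosing its
strength.

What the generator does *not* emulate: the real items' correlation
matrix, participant-level zero-inflation of ideation (synthetic studies
show more participants with at least one ideation day than the real
one), demographic structure, or within-day response timing. Passing
tests therefore demonstrate that the pipeline recovers the structures
it assumes, not that the published performance numbers transfer — the
original raw data are not deposited, so the published cross-validated
metrics are not reproducible and are treated only as report-shape
templates.

## Worked example

A small end-to-end run (sizes reduced to keep the vignette light):

```{r, eval = FALSE}
cfg <- sim_config(n_participants = 60, rng_seed = 7)
sim <- simulate_study(cfg)

feats <- build_features(sim$records, "complex_with_duration")
fit <- glmm_tree(feats, config = study_config())
fit
tidy(fit)       # one row per leaf: rule, n, events, probability
glance(fit)     # sigma_b, leaf count, convergence

res <- run_cv(feats, config = study_config(n_repetitions = 2))
res$summary
autoplot(res)

rules <- tree_to_rules(fit)
write_ruleset_json(rules, "model.json")
apply_rules(rules, feats[1:5, ])
```

The shipped fixtures `load_tree_fixture("fig1")` and
`load_tree_fixture("fig2")` are synthetic reconstructions of the two
published decision trees: the risk pathway stated in the source
report's running text (ideation-duration CM ≤ 0.95, hopelessness CM ≤
2.19, burdensomeness CM > 1.95, self-efficacy CS ≤ −1.59 → ideation)
and each tree's variable vocabulary are faithful; the remaining
branches are plausible completions and carry class labels only.

## Validation strategy and problem sizes

The test suite checks every layer against an independent oracle:
feature arithmetic against brute-force sums over 10,000 random series
with missingness; AUC against the all-pairs count; cutoff selection
against exhaustive search; the rule engine against tree traversal; and
the learner against the generator itself — type-I control on 200 null
studies (100 × 28, 23 candidate predictors; the root must split in at
most 10%), and parameter recovery on 25 seeded studies of 200 × 28 days
from the two-split truth with `sigma_b = 1` (split variables,
thresholds within ±0.3, and `sigma_b` within ±0.3 must be recovered in
at least 80%). A final ordering property re-runs cross-validation on
ten seeded 120-participant studies and requires the complex variant to
out-discriminate the simple one in at least eight. These problem sizes
are the package's chosen compromise between Monte-Carlo resolution and
a test suite that runs in minutes on one core.

## Known limitations

* Random slopes, multi-class outcomes and tree ensembles are out of
  scope by design: the point of a single tree is an interpretable
  decision tool.
* The supLM approximation is asymptotic; at very small node sizes the
  test is conservative, which costs power but never inflates the
  family-wise split rate.
* The published trees cannot be fully reproduced from the available
  text; the fixtures are labelled synthetic and should not be used
  clinically.
* No hyperparameter tuning is performed (nothing was tuned in the
  motivating analysis); `alpha`, `min_node_size` and `trim` are
  config-exposed with the defaults above.
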