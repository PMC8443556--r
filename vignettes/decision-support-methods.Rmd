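---
title: "Methods: two-track decision support for vestibular schwannoma management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-track decision support for vestibular schwannoma management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdss)
```

## The clinical problem

Vestibular schwannoma (VS) is a benign, slowly growing tumor of the
vestibular nerve. Management is a choice between *wait-and-scan* (WaS) —
periodic checkups with audiometry and MRI — and *active treatment*
(surgery or radiotherapy). `vsdss` implements a decision-support
analysis of longitudinal checkup records along two complementary
tracks:

* **Static track (case-based reasoning, CBR).** Every checkup is an
  independent, anonymized sample: can a single examination predict the
  need for active treatment?
* **Dynamic track (personalized dynamic analysis, PDA).** Each
  patient's whole checkup history is summarized by temporal metrics:
  which *changes* drive the decision?

Both tracks share the same downstream machinery: ensemble-consensus
feature selection, decision trees with explicit missing-value routing,
and confusion-matrix/ROC evaluation on balanced
train/validation/test partitions.

## Data model

A cohort is a flat table with one row per checkup (`as_cohort()`,
`read_cohort()`): pure-tone thresholds for the diseased (`PTA_VS_*`)
and healthy (`PTA_H_*`) ears at 0.25--8 kHz, speech audiometry (SRT,
SDS, MDL, MDR), tumor size (mm), Koos grade (1--4), and the decision
label of that checkup (`WaS`/`Active`). Invariants are enforced on
construction: value ranges, unique (patient, time) pairs, and at most
one `Active` decision per patient, which must be the last checkup.

Three deliberate modeling choices:

* **Time is stored in days** since the patient's first checkup.
  The dynamic decision threshold on tumor growth, 0.0064 mm/day
  (≈ 2.3 mm/year), is only dimensionally sensible on a per-day scale;
  `days_to_months()`/`months_to_days()` convert for reporting.
* **Measurements are tri-state**: present, missing (`NA`), or *at the
  audiometer ceiling*. A threshold recorded at the instrument limit
  (default 110 dB, configurable — instruments differ and the exact
  limit per variable is not standardized) is a real observation that
  must not be discarded by complete-record cleaning; it is kept at the
  ceiling value and flagged (`ceiling_flags()`).
* **No imputation, ever.** `clean_complete()` only drops records and
  reports counts; the analysis philosophy is strictly non-parametric
  and assumption-free, so missingness is handled by removal (cleaning)
  or by explicit routing (trees), never by filling in values.

## Derived features

**Static (per checkup).** Each ear's audiogram is reduced over a
frequency range — *basic* (0.25--4 kHz inclusive) or *full* (0.25--8
kHz) — to its arithmetic mean (`PTA_X_ARn`), fitted slope
(`PTA_X_SRn`) and intercept (`PTA_X_IRn`), with `X ∈ {VS, H}` and
`n ∈ {4, 8}`; `PTA_D_ARn` is the inter-ear difference of averages. The
slope/intercept fit is ordinary least squares of threshold (dB) against
frequency. The abscissa is **frequency in kHz on a linear scale** by
default: it is the simplest reading of a "linear fit of pure-tone
thresholds", and the reference static tree's slope thresholds (2.3,
6.7, 7.1 dB/kHz) are consistent with that scale. Because the choice
changes slope units, `pta_linfit()` also accepts `log2khz` (octaves)
and `index` abscissas. Any missing in-range threshold makes the whole
metric missing — no partial averaging, consistent with the no-imputation
rule.

**Dynamic (per patient).** A base variable observed over the checkups
is summarized by `column_summary()` into five metrics: time average
(`_AC`), least-squares slope versus time in units/day (`_SC`),
intercept at the first checkup's time origin (`_IC`), *last difference*
(`_LD`, last minus second-to-last checkup) and *total difference*
(`_TD`, last minus first). `Koos_LD` therefore reads "did the Koos
grade change since the previous checkup", which is exactly the quantity
the dynamic reference tree tests. A single-checkup history leaves `_SC`
and `_LD` undefined (missing), with `AC = IC` and `TD = 0`.

All checkups of a record enter the dynamic summaries, including the
final one at which the decision is made: every recorded checkup belongs
to the wait-and-scan phase (active treatment happens after it), and
excluding the decision checkup would erase the very last-difference
signal the dynamic tree keys on.

The default dynamic base set is `Koos`, `Size`, `SRT`, `PTA_VS_AR4`,
`PTA_VS_AR8`, `PTA_D_AR4`, `PTA_D_AR8`; both feature vectors are
config-driven (`build_cbr_dataset()`, `build_pda_dataset()`).

## Consensus feature selection

Five supervised rankers — a classification tree, random forest,
gradient boosting, logistic regression and the lasso, each delegated to
the established implementation (`rpart`, `randomForest`, `xgboost`,
`glm`, `glmnet`) — each nominate their top-10 variables
(`rank_features()`). Within a method, ties (including variables the
learner never touches, which score zero) break by dataset column
order, making the ranking deterministic for a fixed seed. The logistic
ranker scores per-variable deviance reduction of univariate fits, which
is robust to the quasi-separation that destabilizes joint z-statistics
on small samples; the lasso ranker orders variables by entry along the
regularization path.

`consensus_table()` aggregates the lists: for each variable, `num` (in
how many lists it occurs) and `avg` (mean rank over those lists). The
candidate rule is `num >= 3` **or** `avg <= 5`. Averages are displayed
at one decimal with half-up rounding (3.25 → 3.3); the exact rational
value and the integer rank sum are kept alongside, and
`avg * num = rank_sum` is asserted in the tests. The final *minimal*
variable set is an expert decision that no rule reproduces, so it is
modeled as explicit configuration: `select_candidates()` takes an
override, and the shipped expert sets are `cbr_expert_final()` (Koos,
SRT, `PTA_VS_SR8`, `PTA_H_SR8`, `PTA_D_AR4`) and `pda_expert_final()`
(`Koos_LD`, `Size_SC`, `PTA_D_AR4_SC`, `PTA_VS_AR4_SC`).

The published five rankings per track ship as data
(`cbr_reference_rankings()`, `pda_reference_rankings()`); feeding them
through `consensus_table()` reproduces the published occurrence counts
and average ranks exactly. Two quirks of the published listings are
resolved by arithmetic: one dynamic-track entry is printed under a name
that exists nowhere else but whose consensus cell identifies it as
`PTA_VS_AR4_SC`, and the dynamic logistic-regression list repeats an
entry at ranks 6 and 7 — the printed averages only reproduce when rank
7 is an empty slot, so ranked lists carry explicit ranks that may skip
positions.

## Decision trees with missing-value routing

A tree node holds a rule `(variable, comparator, threshold)`, two
children, and a `missing_to` side. Routing (`route()`) is a
deterministic root-to-leaf descent returning the full visited path —
the trace a clinician can audit — and the decision. Comparisons are
threshold-inclusive exactly as written (`>=`, `<`, `==`). A missing
input follows the node's `missing_to` side; at a node with no
designated side it raises an error naming the node and variable —
erring loudly was chosen over guessing, since the reference trees mark
N/A sides explicitly only on some rules.

Both published reference trees ship as code. The static tree
(13 nodes over the five expert variables) stores explicit true/false
child ids rather than trusting printed column order, because the two
published tabular layouts orient their child columns differently; the
orientation was validated against all eight published worked inferences
(full path and prediction). One printed threshold uses a decimal comma
("2,3"), read as 2.3. The dynamic tree implements: any Koos increase
since the previous checkup → treat; otherwise treat exactly when the
fitted size slope reaches 0.0064 mm/day.

`learn_tree()` grows trees greedily (chi-square statistic with the 3.84
significance gate, or Gini impurity decrease), evaluating midpoint
thresholds and sending missing training values with the majority
branch, which is recorded as the node's `missing_to` so learned trees
route future missing inputs consistently. Node ids are assigned
breadth-first with the false branch first, matching the reference
layout. `prune_tree()` applies reduced-error pruning against a held-out
partition, mirroring the design in which the training partition learns
and the validation partition optimizes; on the synthetic cohorts below
this is what keeps greedy induction from chasing noisy audiometric
slopes when the feature set is large relative to the sample.

## Evaluation

`confusion()` / `classification_metrics()` implement ACC, TPR
(sensitivity), TNR (specificity) and PPV with `Active`/`Yes` as the
positive class; any undefined denominator yields `NA`, never a silent
zero. `roc_auc()` is the Mann–Whitney pair-comparison probability with
ties counted one half (equal to the trapezoidal ROC integral), and
`ase()` is the mean squared difference between the 0/1 target and the
continuous classifier output.

`balanced_split()` first down-samples the majority class to the
minority count (seeded, without replacement), then partitions each
class 50:30:20 using largest-remainder rounding per class — exact
proportions where divisible, deterministic otherwise.
`grid_benchmark()` runs every selector × classifier combination
(classifiers delegate to `randomForest`, `xgboost`, `glm`,
`e1071::svm`, `nnet`, plus this package's tree learner) on one fixed
split, reporting per-cell test metrics, the average of the train- and
validation-partition metrics (averaged at the metric level, not by
pooling samples), and row/column mean accuracies. A failing cell is
recorded as missing and the run continues. Classifiers without a
continuous score fall back to the 0/1 class indicator for AUC, which is
flagged by construction (a two-point ROC). No multiple-testing
correction is applied anywhere, matching the source analysis design.

## The synthetic cohort generator

Real VS cohorts are not freely distributable, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and the whole pipeline is tested against *planted* effects rather than
against any real data. Defaults (`synthetic_config()`) emulate the
published cohort's headline shape: 93 patients, ~43% eventually treated
actively, 3--8 checkups (medians 3 active / 5 WaS) about 330 days
apart, worse hearing in the diseased ear with the loss rising toward
high frequencies, low Koos grades dominating the wait-and-scan group,
and slow growth concentrated in the treated group.

The planted mechanism is the generator's core contract: an active
patient is triggered by a Koos-grade increase at the final checkup
(probability 0.5) or otherwise by a tumor growth rate drawn above the
dynamic tree's 0.0064 mm/day threshold (truncated at 0.009 mm/day so
fitted slopes stay clear of it); wait-and-scan patients get neither
(growth truncated at 0.004 mm/day). With label noise switched off,
routing every patient's dynamic feature vector through the reference
tree reproduces the generated outcome exactly — this consistency is a
test. `label_noise` (default 0.05) then flips the observed outcome of a
random patient subset, leaving their measurements untouched.

Further generator choices, and what they mean for the tests:

* Koos is monotone non-decreasing (tumors are not modeled as
  shrinking) and, in the default model, changes only as the planted
  final-checkup jump.
* Size and Koos are present at every checkup (imaging is the core of a
  VS checkup by protocol); missingness (default 3% per block per
  checkup) hits the audiometric blocks — either ear's whole audiogram,
  SRT, SDS, MDL, MDR — so the dynamic tree's inputs never vanish by
  simulation accident.
* SRT is linked to the diseased ear's 0.5--2 kHz thresholds plus noise
  and clipped at the 110 dB ceiling with flagging. The true joint
  distribution of SRT and PTA in VS patients is unknown; this linkage
  is an assumption, stated as such.
* Audiogram noise is truncated normal, clipped to [-10, 110] dB.
* Group membership does **not** shift the baseline audiogram beyond the
  diseased-ear offset common to both groups; the groups differ through
  progression rate (4 vs 1.5 dB/year), Koos jumps and growth. A static
  group offset is available (`vs_offset_active_extra`) but defaults to
  zero: with it, static inter-ear averages dominate every ranking and
  mask the temporal signal the dynamic track exists to detect.

What passing tests do and do not show: the generator produces exactly
the correlation structure it plants, so recovery tests demonstrate that
the pipeline finds a signal that is there by construction — they say
nothing about effect sizes in real cohorts, and the generator does not
reproduce real-data descriptive statistics (sex, age, side) beyond its
configurable defaults.

## Problem sizes and numerical choices

The test suite works at deliberately small scales: worked-example
routing and consensus arithmetic are exact desk checks; metric formulas
are verified against brute-force oracles over 1000 random fixtures;
planted-rule recovery runs at 200 patients (where slope-fit standard
errors, ~0.0002 mm/day, sit more than 10 standard errors from the
0.0064 mm/day threshold) over 20 seeded replicates; the end-to-end
consensus-recovery property also runs at 200 patients — at the default
93 only about a dozen patients carry a Koos jump, and ensemble rankers
legitimately rank a feature touching 14% of samples below their top-10
in roughly a third of replicates, which is a finding about small-sample
ranking stability, not a defect.

Other numerics: half-up display rounding for average ranks; OLS through
closed-form normal equations with exactness asserted to 1e-9 on
constructed lines; split thresholds at midpoints of consecutive
observed values; split-score ties resolved toward the earlier column;
chi-square splits gated at the 0.05 critical value.

## Known limitations

* The learned-tree replicate experiment with default label noise shows
  an irreducible ceiling: flipped patients cannot be classified from
  their measurements, and because balanced down-sampling retains the
  minority class in full, the ~5% patient-level flips concentrate
  slightly in the balanced set. On a 34--38 patient test partition the
  flip count alone pushes test accuracy below 0.9 in a nontrivial
  fraction of replicates — visible in the replicate test, where even an
  oracle limited only by flipped labels does not clear the strictest
  replicate threshold. Mean test accuracy (~0.91) is the robust summary
  at this scale.
* Ranking stability at n ≈ 90 is poor for features that touch a small
  patient subset (see above); consensus selection should be read as a
  candidate screen, with the final minimal set an expert decision.
* The reference trees' per-node sample counts are annotations from the
  published fit; this package does not re-derive them, and no attempt
  is made to reproduce the original learning environment's split
  search, pruning or surrogate machinery beyond the printed inference
  behavior.
* ABR, OAE, vestibular testing and subjective symptoms are outside the
  data model by design.
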