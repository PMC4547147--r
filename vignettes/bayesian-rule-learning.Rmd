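---
title: "Bayesian rule learning for cMRI biomarker tables: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian rule learning for cMRI biomarker tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brlearn)
```

## The problem and the model

Pediatric cardiomyopathies are rare and heterogeneous; cardiovascular MRI
produces, per patient, a modest table of quantitative biomarkers
(ventricular volumes, ejection fractions, stroke volume index, wall
dimensions) and qualitative findings (myocardial delayed enhancement, MDE).
With cohorts of well under a hundred patients, black-box classifiers are
hard to justify clinically; what is wanted is a small set of readable
IF–THEN rules, each carrying its own evidence. `brlearn` implements a
Bayesian rule learner for exactly this setting: a binary diagnostic target
(`Pos`/`Neg`), mixed predictors, no missing values (missingness is treated
as a data-curation error, never imputed).

All structures are scored by the decomposable Dirichlet(1) marginal
likelihood of the target given a partition of the records. For one group
with class counts $n_1, \dots, n_C$ ($N = \sum_c n_c$):

$$\log P(\text{group}) = \log\frac{\Gamma(C)}{\Gamma(C+N)} + \sum_c \log \Gamma(1+n_c),$$

and a model's score is the sum over the groups it induces (the leaves of a
tree, or the cells of a parent-set cross-product). Uniform Dirichlet
hyperparameters were chosen over an equivalent-sample-size prior because
they are the simplest member of the family, they make every oracle test in
the suite an exact closed-form computation, and the learned structures are
insensitive to this choice at the cohort sizes targeted here.

## Discretization

Continuous predictors are discretized supervised, per variable, by a
dynamic program. Candidate cut-points are midpoints between consecutive
distinct values whose class multisets differ; the objective is

$$-(I-1)\log\lambda + \sum_{i=1}^{I} \text{score}(\text{interval}_i),$$

maximized exactly in $O(B^2)$ over the $B$ candidates. The geometric prior
$\lambda^{-(I-1)}$ penalizes each additional cut-point; $\lambda$ is the
only tuning parameter that matters in practice:

* `lambda = 3.5` (default) — a moderately conservative setting appropriate
  for n ≈ 83 cohorts; most pure-noise variables receive zero cut-points.
* `lambda_sweep()` evaluates the grid 0.5, 1.0, …, 4.0 by cross-validated
  accuracy (AUC breaks ties) and returns the *lowest* λ achieving the
  maximum, preferring simpler discretizations at equal performance.

Intervals are left-open right-closed, printed `"(a to b]"` with open ends
`"≤ a"` and `"> b"`, so a value exactly at a threshold belongs to the lower
interval. Score ties (within an absolute 1e-9, the resolution of the
lgamma arithmetic) are broken toward fewer intervals, then earlier cut
positions, making the procedure fully deterministic.

By default cross-validation refits the discretization inside each training
fold, so held-out rows never inform the cut-points. `pooled_cuts = TRUE`
instead fits once on the full table — a protocol some published analyses
use; it typically inflates CV estimates slightly and is off by default.

## Rule search

`brl_tree_search()` grows a decision tree greedily: a node is split on the
unused variable whose children raise the summed leaf score the most, and
only if the gain is strictly positive; nodes stop at purity or at
`max_depth = 8`. `brl_global_search()` instead grows a single parent set
(up to `max_parents = 8`) and emits one rule per observed value
combination. Both defaults equal the conventional parent cap for this
family of learners. Greedy ties are broken by score, then fewer levels,
then variable name. The tree's local structure usually gives the more
parsimonious model; the CLI's `--search auto` cross-validates both and
keeps the winner (ties go to the tree).

Two conventions keep rule sets mutually exclusive and exhaustive over
*all* possible records, not just training rows: global models append a
catch-all rule for unseen combinations, and tree leaves cover every level
of each split variable. A leaf covering no records predicts the training
majority class with posterior 0.5 and p = 1 — the model explicitly marks
regions where the data carry no evidence rather than extrapolating.
Prediction tie-breaks (equal leaf counts) go to the globally more frequent
class, then the negative label, reflecting that a positive call should
require positive evidence.

## Evidence statistics

Each rule reports TP/FP coverage, the Laplace posterior
$(TP+1)/(TP+FP+2)$ — the Beta(1,1) posterior mean of the rule's class
probability — and a Fisher exact p-value. The Fisher test is the
*one-sided upper tail* of the hypergeometric distribution of TP among
TP+FP draws from the class totals: the probability of covering at least
this many predicted-class records by chance. The one-sided convention is
the package's adopted standard for rule evidence (a rule is only ever
evidence *for* its predicted class); statistics are stored at full
precision and displayed to three decimals.

## Cross-validation

Folds are class-stratified and deterministic given the seed; within each
class, shuffled members are dealt to the currently least-filled folds, so
sizes differ by at most one both per class and overall. Pooled
(concatenated held-out prediction) metrics are primary, because per-fold
metrics are unstable at n ≈ 8 per fold; per-fold values are reported
alongside. AUC uses midrank tie handling. The default seed, 20150813, is
an arbitrary fixed date-like constant chosen for reproducible
demonstrations and always overridable.

## The synthetic cohort generator

No patient data ship with the package; every end-to-end test runs on
synthetic cohorts built to mirror the structure of a real 83-patient
pediatric cMRI table:

* exact class sizes 32 Pos / 51 Neg (composition is allocated, not
  sampled);
* MDE present in 17/32 positives and 1/51 negatives — the only
  class-conditional rates the printed reference model pins down — and male
  fractions 20/32 and 31/51;
* ages uniform on [0, 22] years; 30 predictors: demographics, MDE, 22
  continuous biomarkers, and 5 derived range variables. The derived ranges
  are counted among the 30, the roster being otherwise unconstrained;
* the five reference volumes (LVEDV, LVESV, RVEDV, RVESV, SV) are drawn
  from a synthetic age- and gender-specific reference table
  (`default_reference_table()`; means monotone in age, SDs 15–18% of the
  mean, female means at 90% of male). The published control tables are not
  reproduced; the synthetic table exists so that the ±2 SD range rule has
  something realistic to normalize against. The five age bands
  ([0,2), [2,6), [6,12), [12,18), [18,22]) are likewise fixture choices;
* positives are shifted by `default_effect_map()` in SD units (dilated
  volumes ≈ +1 SD, depressed ejection fractions ≈ −1 SD, SVI +0.5 SD) —
  magnitudes a clinician would call a moderate disease signal, set so the
  Bayes-optimal accuracy of the generative model is roughly 0.85 and
  chosen once when the generator was designed;
* continuous noise is Normal, matching the 2-SD range convention; values
  exactly at ±2 SD are `Normal` (the normal band is closed), a convention
  fixed so the band has positive measure on both boundaries.

`implant_rule_model()` converts a rule model into a generative mechanism:
per class, each rule region receives a record share equal to its scaled
(TP, FP) coverage via largest-remainder allocation (exact when the shares
are integral, as for the shipped 13-rule model at the 32/51 composition);
conditioned variables are drawn from truncated distributions satisfying
the conditions, and leftover records are rejection-sampled outside every
region. Mutual exclusivity of the rules guarantees a record forced into
one region cannot land in another, which is what makes the annotation of
the reference model on an implanted cohort reproduce its coverage counts
exactly.

What the generator does **not** emulate: correlations among biomarkers
beyond those induced by class and the forced rule regions (real EF, volume
and stroke measures are algebraically and physiologically coupled),
measurement error structure, site effects, the age distribution's real
skew (an option to down-weight ages over 18 is deliberately omitted for
simplicity), and cardiomyopathy subtypes (the target is binary). Passing
recovery tests therefore demonstrates algorithmic correctness and
statistical power under idealized independence, not clinical performance
on real cohorts.

## Numerical and degenerate-input choices

* Score comparisons use an absolute 1e-9 tolerance; all scores are sums of
  `lgamma` terms, so genuine ties agree to ~1e-12.
* A constant series has no candidate cut-points and yields the 1-interval
  scheme; λ → ∞ likewise.
* Non-finite values are rejected at discretization, never silently binned.
* A table with no predictors (or a pure-class table) degrades to a single
  unconditional majority rule.
* The Fisher p is computed by log-gamma summation of the exact
  hypergeometric tail — no asymptotic approximation at any n.

## Problem sizes in the test suite

The suite exercises: exhaustive-enumeration identities at n ≤ 14 (where
$2^B$ enumeration is exact), coverage and statistics at the native 83-record
scale, signal recovery at n = 2,000 over 100 generator seeds, rate
calibration at n = 10,000 per class, and cross-validation at n = 830
(ten times the native composition). These sizes were chosen as the
smallest at which each property is statistically decisive.

## Known limitations

* Greedy search carries no optimality guarantee beyond each local step;
  the exhaustive-oracle tests bound its behavior only at toy sizes.
* The Dirichlet(1) score and the Laplace posterior are fixed conventions,
  not fitted priors; informative clinical priors (e.g. forcing a positive
  prediction for severely depressed RVEF despite absent data) are not
  supported — zero-coverage regions simply fall back to the majority
  class.
* Only binary targets are supported; multi-class discretization and rule
  learning are out of scope.
* Rules condition on one interval per variable; disjunctive conditions
  ("low or high") never arise except through separate rules.
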