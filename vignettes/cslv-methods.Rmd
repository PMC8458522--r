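---
title: "Chromosome-scale length variation risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-scale length variation risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the signal

SNP arrays report, at every probe, the log2 ratio of observed to expected
(two-copy) hybridization intensity — the "l2r" value. Zero means diploid;
a heterozygous deletion shifts the expectation to log2(1/2) = −1 and a
single-copy duplication to log2(3/2) ≈ +0.585. Per-probe l2r is noisy, but a
copy-number change spanning many probes moves the *mean* l2r of the region
it covers. Averaging l2r over large chromosome segments therefore yields a
low-dimensional proxy for chromosome-scale length variation (CSLV): one
number per segment per person, capturing net gain or loss of genomic
material in that segment.

`cslvr` builds case-control genetic risk scores from these features. Each
chromosome (the 22 autosomes plus X) is split into *k* nominally equal
parts, the mean l2r within each part is one predictor, and binary
classifiers are trained to separate cases from matched controls. With
k ∈ {1, 4, 8} the feature table holds 23, 92 or 184 columns — small enough
for non-linear learners even when cohorts number in the thousands, which is
the point: per-SNP copy-number values (hundreds of thousands of columns)
preclude them.

## Splitting: what "nominally equal" means here

The package splits by **probe count**, not base pairs: a chromosome with
*n* probes is cut into *k* contiguous blocks whose sizes differ by at most
one, the earlier blocks taking the remainder (sizes `n %/% k + 1` for the
first `n %% k` blocks). Published coordinate tables for equal split indices
span base-pair intervals that vary several-fold, which is what equal probe
counts on a non-uniform probe map produce — dense pseudoautosomal coverage
makes the first X split physically short, for instance. An equal-base-pair
mode (`make_split_scheme(..., mode = "bp")`) is provided for comparison,
but probe-count splitting is the default and the tested configuration. The
remainder-to-front rule and the tie-break by stable person-ID order in
quintile assignment are the package's own deterministic conventions; the
underlying publications are silent on both.

Split boundaries are a pure function of the probe map and *k* — the l2r
values can never move a boundary. A split's genomic interval is reported as
the position of its first through its last probe (1-based inclusive;
BED export converts to 0-based half-open).

Missing l2r values are handled by masked averaging: a person's feature is
the mean of their *observed* probes in the split, and only an entirely
missing split yields `NA`. At the modelling step remaining `NA` cells are
median-imputed with medians learned on the training portion only. How the
original array releases handle missing probes is not documented; masked
averaging is this package's choice, made to keep I/O lossless.

## Cohorts: exact matching, replicates, holdout

Cases are compared against an equal number of controls whose **age multiset
is identical** — exact matching per integer year, not caliper matching —
drawn uniformly without replacement within each age stratum from the
non-case pool. With `match_sex = TRUE` the joint (age, sex) multisets are
equated instead; the main pipeline leaves it off and the X-only
permutation study turns it on, mirroring the two published configurations.
Because the control pool dwarfs the case set, the draw is repeated to give
many replicates, each with a *distinct* control set (distinct as a set;
overlap between replicates is allowed, since disjointness is neither
claimed nor feasible to verify from the publications). Replicate *r* draws
with a seed mixed deterministically from `(master_seed, r)`, so any single
replicate is reproducible in isolation.

Each replicate reserves a label-stratified 30% holdout *before*
cross-validation; the 5 CV folds partition only the remaining 70%. Whether
the original holdout was per-model or global is not stated; per-replicate
and exclusive is this package's resolution, chosen because it keeps every
reported holdout AUC independent of its own training data.

## Learners, AUC, importances

The roster covers the learner families used in AutoML comparisons on
tabular genomic data: a random forest (`ranger`), two gradient-boosted-tree
presets (`xgboost`: a shallow, slow-learning-rate configuration and a
deeper, faster one — both members of the boosted-tree family that
AutoML frameworks expose under two names), a ridge-penalized logistic
regression (`glmnet`, penalty chosen by internal cross-validation), and a
stacked ensemble: base learners produce out-of-fold predictions on the
training data, and a ridge meta-learner is fit on those predictions (the
super-learner construction). A proprietary AutoML grid search is not
reproducible from any publication; a fixed, documented roster is, and the
scientific claims being exercised are at the level of learner families, not
tuned instances.

AUC is computed as the Mann–Whitney statistic — the probability a random
case outscores a random control, ties counted one half — via midranks.
`cv_auc` is the mean of the five fold AUCs. All training-cohort scores used
downstream are **out-of-fold**, never resubstitution scores; holdout
persons are scored by a model refit on the full training portion.

Feature importances are max-normalized to [0, 1] per model. Boosted-tree
learners report the mean absolute exact tree-path (SHAP) attribution over
training persons; the random forest reports its native seeded permutation
importance; the linear learner reports |coefficient| × feature SD; stacked
ensembles report seeded permutation importance (mean AUC drop over 10
permutations per feature). One behavioural difference matters for
localization: when two splits carry the *same* planted signal (a CNV
spanning both), greedy boosting concentrates its attribution on whichever
near-duplicate feature it picked first, while permutation-based
importances credit both. The recovery analyses below therefore use the
random forest; the boosted SHAP view remains available and agrees on the
leading region, just not on how credit is shared within it.

## Quintile odds ratios

Out-of-fold scores are pooled (each person's score is their mean over the
replicates containing them — the provenance of the published stratification
cohort is ambiguous, and pooling is deterministic and documented), ranked,
and cut into quintiles. The odds ratio reported per quintile is the
within-quintile case:control odds divided by the cohort-wide odds, which
under a balanced 1:1 design reduces to `n_cases_q / n_controls_q`. This
definition reproduces the published point estimates from their printed
counts. Confidence intervals are Wald intervals on the log OR with
`SE = sqrt(1/n_cases + 1/n_controls)`; the published intervals deviate
slightly from Wald (their method is unidentified), so intervals are
reported but not treated as reference values. A 0.5 continuity correction
is available behind `correct = TRUE` for zero cells.

AUC distributions are summarised as mean, sample SD and a normal-theory
95% interval using z = 1.96 — the convention that reproduces the published
interval bounds from their printed moments (a t-quantile does not).
Split-scheme and real-vs-shuffled comparisons use the Welch two-sample
t-test (unequal variances, Welch–Satterthwaite df), available both from
raw samples and from printed summary moments. Replicates share the case
set, so their AUCs are positively dependent and these t-tests are
approximate; the package reports them as such.

## The synthetic cohort generator

No individual-level biobank data can ship with an analysis package, so the
generator provides cohorts with exactly the structure the pipeline assumes:

* per-probe Gaussian noise, default SD 0.15 — of the order seen in array
  l2r data, and large relative to a single probe's copy signal;
* a per-person baseline offset, default SD 0.02, emulating per-sample
  intensity normalization residue;
* planted CNV segments with phenotype-specific carrier frequencies and the
  physical effect sizes log2(1/2) / log2(3/2);
* a constant additive shift on male X probes, default −0.10. The
  biologically naive value would be −1 (one X copy), but real arrays are
  sex-normalized to an unknown degree; what is established is only that a
  male-female X CSLV difference exists. −0.10 makes the confound
  detectable but not dominant, which is the interesting regime for testing
  sex matching;
* ages uniform over 40–69 (a biobank recruitment window), independent of
  case status — so exact age matching is testable but never load-bearing.

What the generator deliberately omits: GC-content waves, batch and plate
effects, B-allele frequencies, genuine population structure, and
linkage between segments. CSLV features average dozens-to-hundreds of
probes, so only mean-level structure survives into the feature table;
passing tests therefore demonstrate that the pipeline recovers mean-level
copy-number signal under Gaussian noise, not that it is robust to every
artifact of real array data.

## Problem sizes used in the shipped analyses

The packaged checks run at sizes a laptop handles in minutes, chosen once:
planted-signal recovery uses a 640-probe X chromosome, 64 splits, a
duplication spanning exactly 2 splits (probes 191–210), carrier
frequencies 0.30 / 0.05, 500 cases with 500 matched controls, 10
replicates; null calibration uses 320 X probes, 200 cases, sex-matched
controls, 10 replicates plus a 6-vs-6 label-shuffled Welch comparison;
split refinement uses one 200-probe chromosome with the signal confined to
its first eighth, 250 cases, 20 replicates at k = 1 and k = 4. At these
sizes the planted-signal AUC ceiling (≈ 0.625 for perfect carrier
detection at 0.30/0.05 frequencies) sits well clear of the 0.60 recovery
bar, and the null arm's sampling SD keeps its mean inside [0.45, 0.55]
comfortably.

## Known limitations

Exact age matching fails loudly (with the deficient stratum named) rather
than degrading to nearest-neighbour matching; pools thinner than the case
age profile need coarser strata or caliper logic that this package does
not implement. The quintile-table provenance and the CI method of the
published stratification could not be pinned down, so the package fixes
its own (documented) conventions. Deciles and other quantile counts are
configurable but untested against published tables. Nothing here calls
copy-number variants per se — no segmentation, no per-probe association
testing; CSLV is an averaged signal and localization resolves only to the
split level.

## Worked example

```{r, eval = FALSE}
library(cslvr)

seg <- planted_segment("X", 2e7, 2.2e7, "duplication",
                       carrier_freq_cases = 0.30, carrier_freq_controls = 0.05)
cfg <- simulation_config(n_cases = 200, n_controls_pool = 800,
                         probes_per_chromosome = c(X = 320),
                         chromosome_length_bp = c(X = 64e6),
                         cnv_segments = list(seg), seed = 1)
pm <- simulate_probe_map(cfg)
co <- simulate_cohort(cfg, pm)

run <- run_experiment(run_config(
  pm, co$l2r, co$phenotypes, x_only = TRUE, k_x = 64,
  n_replicates = 10, roster = list(
    random_forest = learner_spec("random_forest"),
    regularized_linear = learner_spec("regularized_linear")),
  master_seed = 1))

glance(run)          # per-learner AUC summaries
run$quintile_table   # risk stratification of the pooled scores
localize(run, 3)     # where the signal lives
autoplot(run)        # AUC distributions
```
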