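---
title: "Methods: discovering sepsis/SIRS transcriptomic signatures with sepsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering sepsis/SIRS transcriptomic signatures with sepsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsig)
```

## The problem

Patients arriving in intensive care with severe systemic inflammation may
have sepsis (a dysregulated host response to infection) or a non-infectious
systemic inflammatory response syndrome (SIRS), such as after out-of-hospital
cardiac arrest. The two call for different treatment, yet their clinical
presentation and common protein markers (CRP, procalcitonin) overlap heavily
on the first day of admission. `sepsig` implements a blood-transcriptome
route to that differential: starting from a log2 expression matrix over
peripheral-blood leukocyte probes, it normalizes and filters the data, ranks
differentially expressed genes, selects small discriminative panels by two
complementary machine-learning routes, and scores those panels as signed
additive composites with full diagnostic (ROC / predictive value /
likelihood ratio) machinery.

The package follows a two-tier testing logic. *Indicators of inflammation*
(IoI) are genes strongly up-regulated in both SIRS and sepsis relative to
healthy controls (fold changes up to ~110x) and are used to recognise severe
inflammation per se. *SIRS-or-sepsis* (SoS) discriminators are genes
differentially expressed between SIRS and sepsis (~2-7x, both directions)
and are combined with signs into panels such as
`CETP+CMTM5+MIA-MPP3-PLA2G7` to separate the two conditions.

## Synthetic cohorts: what the generator emulates

Every stage is testable without any external download because
`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes:

* **Design.** Four groups at Day 1 — 30 healthy controls (CNTRL), 42 SIRS,
  59 abdominal (ABDM) and 84 pulmonary (PLMN) sepsis patients — followed at
  Day 2, Day 5 and discharge. Controls contribute an admission sample only.
  Follow-up is monotonically attritted: a sample present at a later
  timepoint is present at all earlier ones. Non-survivors (survival
  probabilities 61.11/74.51/78.38% for SIRS/ABDM/PLMN) drop out at a higher
  per-timepoint rate (0.25 vs 0.10), reflecting missingness caused by death.
* **Expression model.** Each probe has a baseline intensity drawn once
  (Normal, mean 0, SD 1 on the log2 scale) shared by all samples;
  measurements add independent Gaussian noise (SD 0.5 log2 units, a typical
  replicate spread for one-colour arrays after normalization). A planted
  effect adds `sign(FC) * log2(|FC|)` to its affected groups, scaled per
  timepoint by a declining profile (1.0, 0.9, 0.6, 0.3 by default) that
  mimics resolution of the inflammatory response towards discharge.
  Up-regulated SoS discriminators are planted in the sepsis groups and
  down-regulated ones in the SIRS group, so the signed sepsis-vs-SIRS fold
  change carries the catalogue's sign. Duplicate probes per gene
  (`probes_per_gene`) share the effect with independent noise.
* **Clinical covariates.** `simulate_clinical()` draws CRP, cell counts and
  severity scores log-normally, with parameters solved from per-group
  median/IQR targets by quartile matching on the log scale
  (`sdlog = (log(q3) - log(q1)) / (2 * 0.67449)`). Integer-valued variables
  are rounded; APACHE II exists at Day 1 only.

What the generator deliberately does **not** model: probe-level sequence
effects, batch/array effects, probe-probe correlation beyond shared group
structure, sex as a covariate (the sex-linked filter removes the genes where
it would matter most), and library/scanner artefacts. Passing recovery tests
on these cohorts therefore demonstrates that the algorithms behave correctly
under the assumed signal/noise model — not that real arrays are this clean.

## Normalization and filtering

`preprocess_cohort()` applies, in order:

1. **Percentile shift** — each sample's 75th percentile (linear-interpolation
   "type 7" quantile; the definition is configurable since array-processing
   tools do not agree on one) is subtracted, anchoring it at zero.
2. **Median baseline transform** — each probe's median across samples is
   subtracted. We interpret the "global median" baseline per probe, not as
   one scalar for the whole matrix: this produces the per-gene zero-centred
   scale on which the catalogue's negative score cut-offs (e.g. `-1.928` for
   ADM) are meaningful.
3. **Range filter** — a probe is removed if *any* value falls strictly
   outside [-7, 7]; the rule errs on the side of discarding a whole probe
   rather than masking single outlying values.
4. **Sex-linked blacklist** — all probes of DDX3Y, PSPHP1, XIST, RPS4Y1,
   RPS4Y2 and BTNL8 are dropped, so the cohort's sex imbalance cannot
   masquerade as disease signal.

Both transforms are idempotent, and filtering never alters retained values.

## Differential statistics

`fold_change()` uses the signed convention `+2^d` / `-2^(-d)` for
`d = mean(a) - mean(b)` on log2 data, so `|FC| >= 1` always and
down-regulation is negative. The t-test defaults to Welch (the
equal-variance variant is a flag, since the original tooling's choice is
unknowable); one-way ANOVA is the classical between/within F with the
conventions `F = 0, p = 1` for constant data and `F = Inf, p = 0` for zero
within-group variance. Multiple testing uses Benjamini-Hochberg step-up
adjustment (`stats::p.adjust`). Clinical covariates are compared by
Mann-Whitney U, exact by enumeration when the combined sample is at most 12
without ties (where an exact oracle is cheap) and by the tie- and
continuity-corrected normal approximation otherwise. PCA scores come from
`stats::prcomp` on probe-centred data with a deterministic sign convention
(largest-magnitude loading positive).

## Stepwise neural-network selection

The package's core algorithm is an exhaustive forward search over genes,
scored by a small multilayer perceptron under Monte-Carlo cross-validation:

* **Architecture.** Three layers; two logistic hidden units (deliberately
  tiny, to limit overfitting on ~10^2 samples); one logistic output coded 0
  for the negative class and 1 for sepsis (or whichever positive class the
  comparison defines). Weights initialise Normal(0, 0.1^2), biases zero.
* **Training.** Online (per-sample) backpropagation on squared error
  `0.5 (o - y)^2`, learning rate 0.1, momentum 0.5, samples visited in a
  fresh random order each epoch. Each fit watches a held-out test split and
  keeps the weights at the best test error, stopping after 20 epochs without
  improvement or at 300 epochs. Whether the original procedure early-stopped
  or trained a fixed budget cannot be determined; both modes exist and
  early stopping is the default because the test split's stated purpose is
  monitoring performance *during* training.
* **Monte-Carlo cross-validation.** For each candidate gene set,
  `mc_error()` repeats 50 times: a stratified 60/20/20
  train/test/validation split (splits that lose a class are redrawn), a
  fresh initialisation, training, and the validation-split MSE of the blind
  third. The mean over repeats is the candidate's score. MSE is the default
  ranking error; mean absolute error is available by flag.
* **Stepwise growth.** Step 1 scores every single gene and keeps the
  minimum; step *k* scores every remaining gene appended to the current
  panel. The search stops at a configurable panel-size cap (10) or when the
  best extension fails to improve the mean error by at least `1e-4` — the
  original's stopping rule is unstated, so both knobs are explicit.
  `stability_runs()` re-runs the whole search across master seeds and
  reports selection frequencies, which is how repeated stepwise runs are
  read as a stability assessment.

All randomness (weight draws, splits, epoch orders) flows from R's RNG, so a
`(data, config, seed)` triple reproduces the full selection bit-for-bit. The
training inner loop is compiled (Rcpp), as is conventional for perceptron
implementations in R.

A note on attainable error: with a single gene whose class means differ by
three noise SDs, the classes overlap, and the squared-error floor of any
probabilistic classifier is the Bayes limit (~0.05-0.08 at that gap). Tests
of "training drives error below 0.05" therefore use genuinely separated
fixtures; at the overlapping 3-sigma gap we assert the looser bound the
Bayes limit permits, and selection tests only require the planted gene to
*outrank* noise genes, which the overlap does not impede.

## Random-forest ranking and elimination

`rank_importance()` delegates the ensemble itself to the `randomForest`
package (2001 trees by default; `mtry` defaults to `floor(sqrt(p))` unless
set — panel-sized runs in the discovery workflow used 31 and 11) and adds
the protocol around it: a stratified 75/25 train/test split, the dual
importance report (permutation mean decrease in accuracy, selected as the
conventional reading of "decrease in accuracy", and mean decrease in Gini
impurity), the out-of-bag error and the held-out test error.
`iterative_eliminate()` repeatedly refits and removes the least important
gene (by mean decrease in accuracy, ties broken lexicographically for
reproducibility; one gene per round by default, a fractional schedule by
flag) until a target panel size remains, recording every round.

## Panel scoring and diagnostics

A panel is an ordered list of signed genes (`panel_def("A+B-C")`); its
composite score is the signed sum of normalized expression values, hence
linear in the data. Multiple probes of one gene are collapsed by the
panel's policy: `best_auc` (default — pick the probe with the best
single-probe AUC for the comparison, matching the practice of carrying the
best-performing probe), `mean`, or `first`.

The ROC machinery is implemented directly because its conventions are the
package's contract: AUC as the pair-counting statistic (ties half-counted),
thresholds as midpoints between consecutive distinct scores with open ends,
prediction "positive iff score > cutoff", Hanley-McNeil standard error with
`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, and normal-theory CIs (90% by default,
`z = 1.6449`) clipped to [0, 1]. `auc_ci()` takes the AUC and SE explicitly
so printed values can be verified directly. Cut-off selection maximises
accuracy, breaking ties by Youden's J and then by the smallest threshold;
`threshold_for_target()` finds rule-in (PPV >= 95%) and rule-out
(NPV >= 98%) cut-offs by scanning all thresholds and maximising the
complementary yield, returning `NA` when the target is unattainable. The
open interval between the two targeted cut-offs is reported as the
indeterminate zone. Proportion CIs are Clopper-Pearson exact
(`stats::binom.test`); the original tool's CI method is unknown, so these
CIs are verification aids, not reproduction targets. Likelihood ratios are
computed on the percent scale (`LR+ = sens/(100-spec)`), with `Inf` a
defined value at zero denominators.

`evaluate_panel()` refuses to score a panel with genes missing from the
matrix — the missing genes are reported and no AUC is emitted, because
silent imputation would fabricate performance. The shipped preset catalogue
(`panel_presets()`) includes the IoI combinations, the SoS discriminator
panels, and the published SeptiCyte Lab signature
(`PLAC8-PLA2G7+LAMP1-CEACAM4`) as an external comparator. The 5-gene SoS
signature is catalogued with MIA positive, plus a variant with MIA negated:
the two orientations both appear in print and we do not guess which
produced any given summary table.

## Reference tables

`reference_table()` ships the published Day-1 diagnostic summaries for the
IoI and SoS single markers and the SoS 5-gene signature (sensitivity,
specificity, likelihood ratios, AUC with standard error and 90% CI). They
are worked *inputs*: `recompute_likelihood_ratios()` re-derives every LR
from its printed sensitivity/specificity pair (agreeing to table rounding —
2 decimals for single markers, 4 for the panel), and `auc_ci()` re-derives
the CI bounds from printed AUC and SE. `reference_counts()` records the
array screen's bookkeeping (50,739 probes assessed, 50,728 retained after
filtering, 46,227 retained by group ANOVA at BH-FDR p <= 0.05, i.e. 91.13%).

## Numerical and design choices

* Quantile type 7 for the percentile shift; configurable.
* Fold changes computed on the normalized, per-probe median-centred scale.
* Exact-vs-approximate Mann-Whitney switch at combined n = 12.
* Stepwise stopping tolerance 1e-4; panel cap 10.
* Elimination removes one gene per round by default.
* Degenerate conventions: `t = 0, p = 1` for identical constant groups;
  `F = Inf, p = 0` for zero within-variance; NaN (flagged) for 0/0
  predictive values; `Inf` likelihood ratios at zero denominators.
* Seeds: every stochastic function takes a seed and restores the caller's
  RNG state; child seeds derive from master seeds via `sample.int`, keeping
  all derived seeds below 2^31.

## Simulation-study sizes

The recovery and calibration studies run at sizes chosen to give stable
rates on a single CPU: fold-change ranking on 300-probe cohorts over 200
seeds; stepwise-ANN first-pick on 20 genes x 240 samples x 50 resamples over
100 master seeds; forest elimination (500 trees per refit) from 12 genes to
2 over 100 seeds; ANOVA null calibration on 20 null cohorts of 300 probes;
Mann-Whitney type-I over 1,000 seeds; permuted-label forests over 30
permutations of a 100-sample cohort. The end-to-end run uses the full
default design (2,000 probes, 215 Day-1 samples) with the
inflammation-scale planted effects and evaluates the two-gene FAM20A+OLAH
panel.

## Known limitations

* The generator's independence assumptions make planted effects easier to
  recover than correlated real-array signals; recovery rates here are upper
  bounds on real-data behaviour.
* OOB error rates on synthetic cohorts do not reproduce any particular
  published value; they are checked for calibration (null) and signal
  retention (planted), not magnitude.
* The stepwise selector's cost grows as pool size squared; it is intended
  for curated candidate pools (tens of genes), not array-wide screens —
  use the differential table and forest ranking to shortlist first.
* No moderated-variance statistics, batch correction, survival modelling or
  pathway enrichment: those belong to neighbouring tools (limma, sva,
  survival), not this pipeline.

## A worked example

```{r, eval = FALSE}
co <- generate_cohort(cohort_design(seed = 101), ioi_effects())
co <- preprocess_cohort(co)
ev <- evaluate_panel(panel_presets("ioi_2gene"), co,
                     positive = c("SIRS", "ABDM", "PLMN"), negative = "CNTRL")
ev
```

The same end-to-end path, with stage outputs written to disk, is
`run_pipeline(pipeline_config(...))`; `scripts/acceptance.R` in the source
repository re-runs the full battery described above and writes the measured
rates as JSON.
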