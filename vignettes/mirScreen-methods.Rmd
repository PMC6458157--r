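---
title: "Circulating miRNA biomarker screening: models and methods"
author: "mirScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circulating miRNA biomarker screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirScreen)
library(SummarizedExperiment)
```

## The problem

Spontaneous preterm birth is preceded, often by many weeks, by asymptomatic
remodelling of the cervix that is visible on trans-vaginal ultrasound as
cervical shortening (a length below 25 mm in mid-pregnancy). A blood test
taken at the end of the first trimester that predicts later shortening and
preterm delivery would allow risk stratification long before any clinical
sign. Cell-free microRNAs circulate stably in plasma and carry
tissue-specific signatures, making them natural candidates.

`mirScreen` implements the two-phase analysis such a biomarker study needs:

1. **Discovery** on digital hybridisation counts (nCounter-style panels of
   ~800 miRNA probes): background thresholding from negative-control
   probes, haemolysis quality control, normalization to the most abundant
   species, prevalence filtering, and per-time-point differential
   expression with false-discovery-rate control, yielding a candidate
   marker panel.
2. **Validation** on RT-qPCR cycle-threshold (Ct) measurements of the
   candidates in an independent cohort: two-step median normalization
   against an inter-plate calibrator and spike-in controls, fold-change
   quantification, and ROC-based screening performance, including the
   specificity achieved at 100% detection rate.

Because patient-level cohort data of this kind are generally not shareable,
the package ships a synthetic cohort generator with known ground truth; all
calibration claims in the test suite are statements about that generator's
conditions, not about any patient cohort.

## Data containers

`MirnaExperiment` extends `SummarizedExperiment`: probes in rows (with a
`probeClass` of `ENDOGENOUS`, `NEG_CONTROL`, `POS_CONTROL` or `SPIKE_IN`),
samples in columns (with patient id, gestational time point A/B/C, outcome
group `TERM`/`PRETERM`/`SHORT`, and cervical lengths), plus the scale the
values are on (`RAW_COUNT`, `NORMALIZED_COUNT`, `RELATIVE_EXPRESSION`,
`NORMALIZED_CT`). `CtSet` holds replicate-level qPCR records (sample,
assay, plate, replicate, Ct, with `NA` meaning "undetected") together with
the calibrator and spike-in assay ids. Readers and writers for plain CSV
(a tab dialect is auto-detected) are provided; native instrument formats
are out of scope.

Outcome groups follow the clinical definitions: `PRETERM` is spontaneous
delivery before 34 weeks; `SHORT` is cervical shortening, a length below
25 mm at time point B or C when the length at A exceeded 25 mm. When the
outcome column is absent the reader derives `SHORT`/`TERM` from the
lengths using strict inequalities; a length of exactly 25 mm triggers
neither side of the rule and raises a warning rather than guessing, since
the boundary classification is not defined by the clinical rule.

## Count processing (discovery phase)

**Background.** Each sample's background is the mean of its
negative-control probes plus twice their sample standard deviation (n−1
denominator), subtracted from the endogenous counts and floored at zero.
Zero therefore means "not above background" downstream. The negative
controls ship with each lane, so the default is a per-sample threshold; a
pooled cohort-wide threshold is available behind an argument
(`perSample = FALSE`) since the choice is not dictated by the assay.

**Haemolysis QC.** Red-cell lysis floods plasma with erythrocyte miRNAs
(hsa-miR-16-5p, hsa-miR-25-3p, hsa-miR-93-5p). "Very high expression" is
operationalised as a robust z-score above 3 on log2 counts per marker
(median/MAD with the 1.4826 consistency factor); the cut-off is explicit
and configurable because no numeric rule is standard. Flagged samples are
removed before any statistics.

**Normalization.** Counts are scaled so each sample's mean over the
reference set — the 100 endogenous probes with the highest cohort-wide mean
count — equals the grand mean. A global reference set keeps scale factors
comparable across samples and continuous in the data; a per-sample top-100
alternative is provided. Note the compositional caveat below.

**Prevalence filter.** A marker is kept only if, in at least one outcome
group, it is above background in *strictly more than half* of that group's
samples (exactly half fails).

**Differential expression.** For each retained marker, time point, and
comparison (TERM vs PRETERM, TERM vs SHORT), the two groups are compared
with Student's unpaired t-test when both pass the D'Agostino–Pearson
omnibus normality test at α = 0.05, and the two-sided Mann–Whitney test
otherwise; with fewer than 8 samples per group the normality test is
undefined and the nonparametric branch is taken. A Welch t-test on
log2(count + 1) (the log-geometric-mean comparison, assuming unequal
variances) is available as `welchLogGeomeanTest()`. Longitudinal profiles
(3 time points per patient) use repeated-measures ANOVA with the
Greenhouse–Geisser ε correction followed by a two-sided linear-trend post
test when all time points look Gaussian, and otherwise a Friedman test
followed by Dunn's pairwise comparisons with Bonferroni adjustment over the
three pairs.

**FDR and the candidate panel.** Benjamini–Hochberg adjustment is applied
to *one family*: all (marker × time point × comparison) p-values of the
discovery run. The candidate panel is the set of markers with q < 0.05 at
one or more time points in either comparison. One family, rather than one
per comparison/time point, is what makes the complete-null guarantee hold:
when no marker carries signal, the probability that the panel is non-empty
is at most ≈ α. An option (`useFdr = FALSE`) selects on raw p < α instead,
which matches how per-figure annotations are commonly reported.

A property worth knowing: when true markers are present, BH at FDR 0.05
*permits* roughly `0.05/0.95 × (number of true rejections)` false
rejections in expectation. With nine strong markers tested at three time
points in two comparisons (~54 true rejections), about two falsely
selected markers per cohort are expected by construction. A user who needs
a purer panel should lower `fdr` or demand significance in both
comparisons; the default reproduces the conventional rule.

## Ct processing (validation phase)

Technical replicates are averaged per (sample, assay, plate); the
intra-assay coefficient of variation is reported and cells at or above 2%
are flagged (but kept — flagging is a lab QC signal, not an exclusion
rule). Undetected replicates are excluded from the mean rather than
imputed at a ceiling Ct, since ceiling imputation biases fold changes; a
cell is undetected only if all its replicates are.

Median normalization is two-step, in assay order: (1) subtract each
plate's offset, the plate's calibrator Ct minus the median calibrator Ct
across plates; (2) subtract each sample's technical offset, the median
over spike-in assays (extraction control cel-254, reverse-transcription
control UniSp6) of that sample's spike Ct minus the spike's cross-sample
median. With two spike-ins the median is their midpoint; the aggregation
rule is a package decision since only the two controls themselves are
standard. In the noiseless limit this chain exactly inverts any injected
plate offsets and any sample offsets (each up to its median, which is the
identifiable part), a property the test suite asserts against the
generator.

Fold change between groups is `2^−dG` with `dG` the difference in mean
normalized Ct (experimental − control); per-sample relative expression
`2^−ΔCt` is rescaled so the control-group mean is exactly 1. Because `dG`
averages Ct (log) values, `2^−dG` is the ratio of *geometric* means of
relative expression; the arithmetic group means reported alongside (as in
conventional result tables) are deliberately not forced to match it.

## Multivariate views

Profiles are unit-variance scaled (each variable centred and divided by
its standard deviation S_k; constant variables dropped with a warning).
PCA and PLS-DA use NIPALS iteration — the algorithm of the chemometrics
software that popularised Q²Y — with convergence to a relative score
tolerance of 1e−10 and a 5000-iteration cap per component (power
iteration converges slowly when singular values nearly tie; the cap
covers ratios up to ~0.998, and non-convergence is an error, not a
silent result). Scores and loadings are verified against the singular
value decomposition in the tests. PLS-DA is PLS1 against a centred 0/1
response; R²Y is the cumulative training variance explained. Q²Y is
1 − PRESS/TSS from a seven-round cross-validation: samples are assigned
round-robin over a seed-shuffled order (a deterministic venetian-blind
assignment is also offered), a model is refit without each fold, and
held-out responses predicted. Q²Y ≤ R²Y in practice, and permuted labels
give median Q²Y ≤ 0 — both asserted over simulation in the tests.

## ROC screening

ROC curves sweep thresholds over unique score values; test-positivity is
"at or above threshold" after orientation (`AUTO` picks the direction with
AUC ≥ 0.5). The trapezoid AUC equals the Mann–Whitney concordance with
ties counted one half — asserted as an exact identity on random instances
— and its p-value against 0.5 is the Mann–Whitney test's. The screening
threshold is the most stringent cut-off that keeps every case positive
(the minimum case score); a control exactly at the threshold counts as
screen-positive, the conservative choice for a rule-out screen.
Specificity there is the proportion of controls strictly below, with an
exact Clopper–Pearson 95% interval from beta quantiles — arithmetic that
reproduces published screening-table cells exactly (e.g. 54/84 controls
→ 64.29%, CI 53.08–74.45%).

Marker panels are combined by a maximum-likelihood two-class logistic
model on the per-marker log2 relative expressions, evaluated in-sample,
which is the standard reading when no combination rule is published; the
in-sample AUC of the combination is therefore optimistic and is never
compared across panels of different sizes in the package's own outputs.
Under perfect separation the logistic MLE diverges, so an L2-ridge
penalised fit (λ = 0.01) is substituted with a warning; a model-free
rank-sum combination is available behind `method = "ranksum"`.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with defaults mirroring the discovery design: 16 TERM, 13
PRETERM and 24 SHORT patients, each sampled at three gestational windows;
800 endogenous probes of which 55 are consistently expressed; 6
negative-control probes.

- **Counts** are negative binomial (dispersion 0.1) around per-probe
  baselines × a group/time fold effect × a per-patient, per-probe
  log-normal random effect (log2 sd 1, constant across a patient's time
  points). The patient effect dominates the technical noise, reproducing
  the patient-wise clustering these profiles show in practice.
- **Baselines** are heavy-tailed lognormal: a few very abundant stable
  species carry most of the top-100 normalizer mass, as in real plasma,
  while the nine differential markers sit in a modest-abundance stratum.
  This matters: if strongly differential markers dominated the reference
  set, normalization itself would shift every null marker between groups
  (a compositional artifact the generator exposed during development and
  that real analyses of this design are equally subject to).
- **Background**: every endogenous probe carries a nonspecific-binding
  floor at the negative-control mean, so non-expressed probes sit at
  background and the mean+2sd subtraction is centred.
- **Fold effects** default to the 4–24× scale reported for this marker
  class, rising across time points, for both non-TERM groups.
- **Haemolysis** contaminates a fixed fraction (default 5%) of samples
  with a 20× spike on the three haemolysis markers — a deliberately large
  multiplier so that QC detectability is by construction, since only
  "very high expression" is stated in practice.
- **qPCR** (`simulateQpcr()`): Ct = 30 − log2(expression) + plate offset
  + sample offset + replicate noise (duplicates, default sd 0.15 cycles,
  consistent with <2% intra-assay CV at Ct ≈ 25); the calibrator is
  constant per plate up to its offset; both spike-ins carry the sample
  offset so the normalization chain can remove it.
- All randomness flows from a single seed; sub-streams (cohort, qPCR) use
  fixed documented offsets from it, so identical seeds give identical
  bytes.

What the generator does **not** emulate: batch/lot effects, gestational
drift within a time window, correlated marker modules, assay saturation,
or any fit to a real cohort's distributions. Passing tests therefore
demonstrate the pipeline's statistical behaviour under its stated
assumptions, not clinical performance.

## Numerical and edge-case choices

- Friedman test: for k = 3 untied designs with ≤ 12 subjects the p-value
  is the *exact* permutation tail, computed by dynamic programming over
  within-subject rank permutations (the chi-square approximation is poor
  exactly where such assays operate); all-tied designs return statistic 0,
  p = 1; larger or tied designs use the standard asymptotic test.
- Greenhouse–Geisser ε is clipped into its analytic bounds
  [1/(k−1), 1].
- D'Agostino–Pearson requires n ≥ 8 and non-constant input; callers fall
  back to nonparametric branches below that.
- Background-subtracted zeros get the log2(count + 1) offset in the
  log-geometric-mean test; the offset is an argument.
- Scale validity: count matrices must be complete and non-negative;
  normalized-Ct matrices may contain `NA` (undetected), which every
  consumer excludes explicitly with a warning.

## Problem sizes in the test suite

The suite's simulation checks use cohorts of 20 patients per group for
discovery calibration (100 seeds for recovery, 300 for the complete-null
panel), 2 × 2000 draws for test size, 200 seeds for the permuted-label
Q²Y null, and 1000 random instances for the AUC/concordance identity —
sizes chosen to give Monte Carlo standard errors comfortably below the
asserted margins.

## Known limitations

- The ≈2 expected falsely-selected markers per discovery cohort under the
  default FDR rule (see above) are a property of BH step-up selection, not
  a bug; they are visible in the package's own Monte Carlo output.
- Top-100 normalization is compositional: it is only as good as the
  stability of the high-abundance reference species.
- Combined-panel AUCs are in-sample; no nested cross-validation is
  provided for panel selection.
- The per-marker choice between t and Mann–Whitney follows the normality
  gate, so which test produced a given p-value is data-dependent;
  `testUsed` is always recorded.
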