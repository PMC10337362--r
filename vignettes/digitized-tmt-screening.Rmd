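---
title: "Screening cognitive impairment from digitized Trail Making Test trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cognitive impairment from digitized Trail Making Test trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtrace)
```

## The measurement setting

The Trail Making Test (here in its Shape Trail Test form, which replaces
letters by circle/square shapes so no Latin-alphabet knowledge is needed)
asks a subject to connect numbered targets in ascending order with a pen.
Part A presents each number once; part B shows every number except 1 twice,
once in a circle and once in a square, and the subject must alternate
enclosing shapes, which loads set shifting. Each part has a warm-up block
(numbers 1–8) and a scored block (numbers 1–25). When the printed sheet
lies on an electromagnetic digitizing tablet, the familiar paper test
additionally yields a sampled pen trace: position `(x, y)` on a
0–21000 x 0–29700 device grid (100 units per millimetre of an A4 sheet),
a pen pressure that is exactly zero whenever the pen is lifted, and a
timestamp. `tmtrace` turns such traces into features and into
cross-validated pairwise classifiers for the three screening classes —
healthy controls (HC), mild cognitive impairment (MCI) and Alzheimer
disease (AD).

The pressure-zero convention is load-bearing: it partitions each block's
duration into *execution* time (pen down, drawing) and *preparation* time
(pen up, searching/thinking), and it defines the strokes on which pressure
and smoothness statistics are computed.

## Feature families

**Time.** Per block: completion time (last minus first timestamp),
execution time (sum of inter-sample intervals whose earlier sample is
pen-down), preparation time (their difference). Across blocks: the A2-B2
difference and ratio. The ratio follows the convention that a zero
denominator (a block coded as failed, completion 0) is replaced by -1, so
the value becomes the negated numerator; the result is flagged, because
the substitution deliberately introduces a discontinuity. An absent or
failed block is treated as time 0 only when the input explicitly codes it
so; otherwise its features are missing values.

**Pressure.** Mean, minimum and maximum over pen-down samples only.
Including pen-up zeros would pin every minimum at zero and dilute the
mean, turning a muscle-tone measure into a lift-count proxy.

**Jerk.** Jerk is the third time derivative of position; smooth practised
movement keeps it small, tremor and corrective jolts inflate it. The trace
is an unevenly sampled polyline, so the estimator (a documented, swappable
strategy — the scalar is not standardised) is: per pen-down stroke,
resample x and y linearly onto a uniform grid at the trajectory's median
sampling interval; apply the five-point central third difference; take the
RMS of the jerk-vector magnitude; aggregate strokes by duration-weighted
mean. Strokes shorter than five resampled points cannot support a third
difference and are skipped. The estimator is exactly zero on linear and
quadratic motion, which the tests assert, and is strictly monotone in
superimposed tremor amplitude on noiseless synthetic segments.

**Template similarity.** Healthy traces are assumed to resemble the ideal
connecting path, so a reference trace is chosen from the HC training pool:
a seeded subset of 10 trajectories is drawn, all pairwise dynamic time
warping distances (DTW; sum of Euclidean local costs along the optimal
monotone alignment, no band, no path-length normalisation) are computed,
and the subset member with the smallest row sum is the template, ties going
to the lowest subject id. Every trajectory — template included — is then
compressed to *key points*: Gaussian smoothing (sigma 0.1, in sample-index
units; effectively an identity at that value, kept configurable), k-means
on the pen-down `(x, y)` cloud with codebook size 40 (k-means++-style
seeded initialisation, restart on empty clusters), then *temporal
restructuring*: clusters are ordered by mean timestamp and, in a single
pass using the original neighbour means, member points earlier than the
previous cluster's mean time or later than the next cluster's are removed;
centers and mean times are recomputed from the survivors. This matters
because spatial clustering is blind to time: where the path crosses itself
a cluster can absorb points from two different passes, dragging its center
off both. Three features per block compare a trajectory's key points with
the template's: the DTW distance between the two center sequences, and the
mean Euclidean distance over temporally index-paired key points, unweighted
and weighted by the trajectory's relative cluster weights (member count
over pen-down sample count, renormalised over the paired prefix).

Design points that the procedure description leaves open, and the choices
made here:

* *Strictly increasing key-point times.* Restructuring almost always
  yields strictly increasing mean times, but adversarial inputs can tie
  interior clusters. After recomputation the sequence is stably re-sorted
  and exact ties merged, so the invariant holds for all inputs.
* *Pairing unequal counts.* Restructuring can drop clusters, so the two
  key-point sequences may differ in length; index pairing runs over the
  shorter prefix (DTW needs no pairing).
* *Whose weights.* The weighted distance uses the evaluated trajectory's
  weights, renormalised, keeping the feature a length-scale quantity.
* *One pass, not a fixed point.* The removal rule is applied once with the
  original neighbour means; an iterated variant would be a different
  algorithm and is not the default.
* *Raw-trace vs key-point DTW.* The template DTW feature is computed on
  key-point sequences; a full-trajectory DTW column can be added by
  calling `dtw_distance()` on the traces directly.

The exact dynamic program is the reference implementation and the oracle
in tests; a multilevel FastDTW approximation (coarsen by pairwise
averaging, solve, project the optimal path, inflate by a radius, re-solve
in the band) is the production default inside cross-validation, with
radius 1. With a radius at least the longer sequence length the band covers
the whole matrix and FastDTW *is* the exact algorithm, which the suite
asserts; at radius 10 on 100-point pairs it stays within 5% of exact in
over 95% of random trials. Template selection defaults to the exact
program — pools of 10 are cheap, and selection then agrees bit-for-bit
with a brute-force row-sum argmin.

## Screening models

Features assemble into a subject-by-feature table in three variants:
`conventional` (the four completion times, sex/age/education, and the six
examiner interaction counts — what a paper form plus an examiner yields),
`proposed` (all kinematic, cross-block and template features plus
demographics, *excluding* interaction counts, since the digitised test is
meant to remove the examiner from the loop), and `all`. Follow-up mode
drops sex, age and education so that a model trained at baseline cannot
recognise returning individuals through identity-linked columns.

Each pairwise task (HC vs MCI, HC vs AD, MCI vs AD, AD vs others) is a
binary classification whose positive class is always the more impaired
group; sensitivity therefore always means "detecting impairment".
Stratified 5-fold cross-validation is the evaluation protocol, and the
template machinery is honoured fold by fold: the reference template is
re-selected from the *training* fold's HC subjects only, so no test-fold
information can leak through the template. Key-point extraction itself
depends only on the trajectory and its own derived seed — never on the
fold — so key points are computed once and reused. Missing features are
imputed by training-fold medians with missingness-indicator columns.
Classifiers run at library defaults with pinned seeds: random forest
(`randomForest`, the reference model), an RBF support vector classifier
(`e1071`, decision values as scores), and gradient boosted trees
(`xgboost`). Metrics (accuracy, AUC, sensitivity, specificity) are means
over folds.

Feature importance uses a permutation backend: each column is permuted
several times and the importance is the mean absolute change of the
predicted positive-class score. Per-feature values are summed within
named families (completion/preparation/execution time, the three pressure
statistics, jerk, DTW distance, VQ with and without weights, demographics,
interaction counts), so a family's value is exactly the sum of its
members, mirroring additive attribution schemes. The backend is pluggable;
nothing downstream depends on how per-feature attributions are produced.

The per-feature screening statistic is a one-way ANOVA F test per group
pair, reported raw; a Benjamini–Hochberg column is available behind
`adjust = TRUE` and is clearly an extension, not the default report.

## The synthetic cohort generator

No public tablet-TMT cohort exists, so the package ships a generator that
makes every stage testable against known ground truth. A sheet layout
places non-overlapping targets (radius 500 units = 5 mm) inside 20 mm
margins by rejection sampling; part B layouts carry the duplicate-shape
distractors and the square-anchored alternation (odd numbers in squares).
A simulated subject draws each consecutive segment as a minimum-jerk
point-to-point movement — chosen because it is the analytic
smoothness baseline against which the jerk estimator can be
calibrated — optionally preceded by a pen-up dwell (truncated-normal
pause, plus occasional longer attentional lapses), with sinusoidal tremor
superimposed and per-sample truncated-normal pressure, all sampled at
100 Hz.

Event durations are quantised to the sampling grid, so pen-state
transitions coincide with sample boundaries. This is a deliberate
generator property: it makes the recorded ground truth (total duration,
total pause and draw time) recoverable from the sampled trace exactly, to
within one sample interval, and the validation suite asserts that per
subject. Pressure recovery is necessarily statistical: each block's mean
pen-down pressure is an unbiased estimate of the subject's profile mean
with standard error `sd/sqrt(n)`, so across hundreds of blocks a
per-block 3-standard-error bound must occasionally fail by construction
(about 0.27% of blocks). The suite therefore checks calibration — at
least 99% of blocks within 3 SE and a simultaneous bound on the largest
standardized error — rather than asserting an impossible per-draw bound.

Group profiles encode the clinical directions: slower movement, longer
and more variable pauses, lower and less stable pressure, larger tremor
and more lapses with increasing impairment. Magnitudes are anchored to
published group-level block statistics (e.g. healthy controls completing
the scored part-A block in under a minute at writing pressure around
1700 device units, AD subjects taking substantially longer at markedly
lower pressure), with segment speed near 3600 units/s for HC, 2700 for
MCI and 2200 for AD, pre-target pauses of 0.05/0.13/0.45 s, and tremor
amplitudes 10/25/40 units. Subjects get log-normal random effects on
speed and pause and an additive effect on pressure. These defaults define
*directions and plausible scales*, not a reproduction of any clinical
cohort's numbers: the generator draws pressures i.i.d. per sample (real
pressure series are autocorrelated and skewed), its tremor is a pure
sinusoid, it never simulates wrong-target errors by default (interaction
counts are zeros unless `simulate_interactions = TRUE`, which draws
Poisson counts without altering the trace), and its search/decision
process is a pause distribution rather than a cognitive model. Passing
tests on this cohort therefore demonstrate that the pipeline measures
what the generator planted — time structure, pressure level, smoothness,
spatial conformity — not that clinical accuracies would reach any
particular level.

## Problem sizes and numerical choices

The validation suite and the acceptance script run the full protocol on
cohorts of 20–60 subjects per group (the package's chosen study sizes for
synthetic validation), 5-fold cross-validation, codebook 40, template
subsets of 10. Tolerances: exact dynamic-programming DTW is compared to
path enumeration at 1e-12; jerk on polynomial motion is required below
1e-6 of the coordinate scale; k-means restarts cap at 10 before empty
clusters are dropped; the FastDTW radius defaults to 1. Degenerate inputs
are defined, not crashed on: an all-pen-up trajectory has zero execution
time and missing pressure/jerk features; a trajectory equal to the
template scores zero on all three template features; a feature constant
within both groups is flagged as degenerate by the ANOVA screen rather
than producing an F statistic.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(c(HC = 20, MCI = 20, AD = 20), seed = 1)
report <- cross_validate(cohort, task = "HCvsAD", folds = 5, seed = 1)
report
#> <tmt_report> HCvsAD / random_forest (5-fold CV)
#>    accuracy         auc sensitivity specificity
#>           1           1           1           1
```

On well-separated synthetic profiles the classifier is at ceiling; the
informative number is the shuffled-label control, which sits at chance
(`scripts/acceptance.R` recomputes both, along with the oracle agreement
rates and recovery errors).

## Known limitations

Sampling rate and time units are not standardised by the tablet protocol
and must be declared at read time. The jerk scalar is this package's
definition of a derivative-of-acceleration smoothness index, not a field
standard. The simulator's realism limits are listed above; in particular,
classifier metrics on synthetic cohorts say nothing quantitative about
clinical performance. Attribution is permutation-based; tree-path SHAP
values would differ in scale though not in the additivity contract.
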