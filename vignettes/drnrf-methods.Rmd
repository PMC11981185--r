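---
title: "Methods: landmark-based mental fatigue detection with DRN-RF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based mental fatigue detection with DRN-RF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Control-room operators doing monotonous monitoring work drift into mental
fatigue, and fatigue shows in the face: drooping eyelids and brows, sagging
facial contour, yawning. This package classifies an operator's fatigue
level on a simplified five-level Karolinska Sleepiness Scale (KSS; 1 very
alert ... 5 extremely sleepy) from 68-point facial-landmark coordinates —
the kind of per-frame output a standard landmark detector produces from a
webcam image. A frame is a 136-vector `x1..x68, y1..y68` in pixel units
(iBUG numbering, origin top-left, y downward).

The pipeline has three stages:

1. **Repair and normalisation.** Per participant and per coordinate,
   values outside three standard deviations of the mean are treated as
   occlusion artifacts and replaced by the mean of their nearest intact
   neighbours in time; each frame is then mapped to a translation- and
   scale-invariant representation; finally every feature is min-max
   normalised to `[0, 1]`.
2. **Stability feature selection.** Recursive feature elimination with
   cross-validated size choice (RFECV), repeated under independent random
   partitions (Monte-Carlo), retains the coordinates selected in at least
   a fraction `threshold` of repetitions.
3. **Stacked classification.** A deep residual network (DRN) base learner
   produces out-of-fold class-probability vectors that train a
   random-forest (RF) meta-learner; the forest's vote is the final level.

## Repair and normalisation

*Outlier band.* The band uses the **population** standard deviation over
the finite entries, and values **exactly on** the three-sigma edge are
kept — the band is read as a closed interval, so only values strictly
outside are outliers. Non-finite cells (missing coordinates from failed
detection) are always flagged. Statistics are computed within each
participant's own recording, not pooled: occlusions and camera placement
are session-specific, and pooling would let one participant's geometry
contaminate another's band.

*Imputation.* A flagged cell takes the mean of the nearest preceding and
nearest following unflagged values; at the sequence boundary the single
nearest unflagged value is used. Only original unflagged values feed the
repair, so repairing twice changes nothing.

*Relativisation.* Each frame is centred on its 68-point centroid and
divided by its bounding-box diagonal. This is one concrete choice among
several that achieve "relative positional relationships"; it is exactly
invariant to translation and uniform scaling, which is what varying seat
position and camera distance introduce. It does couple coordinates weakly
(every coordinate shares the centroid and diagonal), which the selection
stage tolerates.

*Min-max.* `(m - min) / (max - min)` per feature. The state is fitted on
**training rows only** and reused for validation and test rows, which may
therefore fall outside `[0, 1]` and are deliberately not clipped; fitting
on all rows would leak evaluation data into the training representation.
A zero-range feature raises an error naming the feature rather than
silently producing non-finite values.

## Stability feature selection

`rfe()` implements classic recursive elimination: fit the estimator, drop
the `step` least important features (mean impurity decrease), repeat until
the target size, then fit once more on the survivors — with `step = 1` on
`p` features that is exactly `p - n_target + 1` fits.

`rfecv()` scores the elimination path by stratified K-fold
cross-validation (K = 5, accuracy): within each fold an elimination path
is fitted on the training part and each intermediate model is scored on
the held-out part; the size with the best mean score wins, ties going to
the **smaller** size. A final elimination on all rows yields the selected
set.

Two internals are deliberately leaner than the classifier defaults. The
per-iteration drop defaults to 20% of the remaining features (a geometric
path, fine-grained exactly where it matters, at small sizes), and the
selection forest uses 50 trees instead of the classifier's 100. The
stability of the procedure comes from aggregating selection **frequencies
across Monte-Carlo repetitions** — each repetition re-randomises the fold
partition and every forest seed — not from the precision of any single
forest fit; lighter per-fit estimators buy more repetitions for the same
computation, which is the better trade for a frequency estimator. This
mirrors the general design of stability selection, where subsampled light
estimators are standard.

A feature is retained when its frequency is **at least** the threshold
(the inclusive reading keeps `threshold = 1` meaningful). The retained set
is monotone non-increasing in the threshold. `select_threshold()` scores
candidate thresholds by K-fold accuracy of the forest on each candidate's
retained set; an empty retained set scores 0 and is flagged; ties resolve
toward the smaller threshold, which retains more features — the
documented preference when hunting for unexpected fatigue-related
features. The published candidate scores bundled with the package give
0.1, and their retained-feature table expands to 83 of the 136
coordinates.

The published protocol repeats RFECV 100 times; `n_reps` is configurable
and the package's own experiments use 20 repetitions, which on the default
synthetic conditions already drives every planted feature's frequency to
1.0 and the noise median to 0.

Seeding: one master seed expands through a counter-based derivation
(`derive_seed()`) into an independent (fold seed, estimator seed, predict
seed) triple per repetition, so any repetition can be replayed in
isolation and repetitions never share randomness.

## The DRN base learner

No deep-learning framework is assumed: the residual multilayer perceptron
is implemented in base-R linear algebra, which keeps training
single-threaded and bit-reproducible under a seed. The published
architecture — 15 trainable dense layers of width 32 — is decomposed as:

* 1 input projection (dense + ReLU),
* 6 residual blocks of 2 dense layers each,
* 1 pre-output dense layer (ReLU),
* 1 softmax output layer.

Each block computes `F(X) + X`: dense(32) → batch normalisation → ReLU →
dropout → dense(32), plus the identity shortcut. With all-zero weights and
identity normalisation the block is exactly the identity and its Jacobian
is the identity matrix — the property that lets gradients pass through
deep stacks unattenuated. No activation is applied after the addition, so
the identity holds exactly rather than only on the positive orthant. The
precise placement of normalisation and activation inside a block is not
standardised in the literature; this layout was chosen for that exact
identity property. `drn_config(shortcut = FALSE)` removes the shortcuts,
giving an equally deep plain MLP for degradation-ablation experiments.

Training minimises softmax cross-entropy plus an L2 penalty with Adam.
The published values are epochs 100 and batch size 32; activation (ReLU),
dropout (0.2), L2 (1e-4) and learning rate (1e-3) are not published and
are set to field-standard defaults, all exposed in `drn_config()`. Batch
normalisation uses batch statistics (population variance) during training
and running averages (momentum 0.9) at inference; dropout is inverted, so
inference needs no rescaling. Labels are treated as nominal during
fitting; the ordinal structure of the KSS is used only by the deviation
metric.

## Stacking

`drnrf()` partitions the training rows into 5 stratified folds. Each
fold's DRN is trained on the other 4 folds and predicts class
probabilities for its held-out fold, so every training row's meta-features
come from a network that never saw it — the no-leakage property the test
suite audits on every fit. The stacked `n x 5` probability matrix trains
the RF meta-learner (100 fully grown trees).

Meta-features are class **probabilities**, not hard labels: probabilities
preserve the base learner's uncertainty, which is exactly the information
the meta-forest exploits. At prediction time, new rows are scored by all 5
fold networks and the averaged probabilities go to the forest; averaging
the retained fold models reuses what was actually fitted rather than
refitting a sixth network on all rows, and gives a mild ensemble benefit
for free. The stacked model consumes the selected features, not all 136.

## Baselines

The comparison methods run at their published hyperparameters: ANN (one
hidden layer of 32 units, 100 iterations), GBM (learning rate 5, 300
rounds, unbounded depth), KNN (3 neighbours, Manhattan distance), RF (100
fully grown trees). The GBM learning rate of 5 is far outside the usual
(0, 1] range; applied literally in a gradient-boosting implementation it
makes boosting diverge to chance-level accuracy, and `fit_baseline()`
flags this with a warning while still honouring the printed value. The
parameter is exposed for users who want a conventional rate.

## Evaluation protocol

`run_comparison()` repeats, for each of `n_trials` trials under derived
seeds: a fresh stratified 70/15/15 split, preprocessing with the
normalisation fitted on the training part, fitting every method, and test
metrics — overall and restricted to the two highest levels ("Sleepy" and
"Extremely Sleepy"), whose detection is the safety-relevant part. Both the
partition and every model's internal randomness vary across trials. Means,
pairwise one-way ANOVA of the reference method against each competitor
(two groups at a time, significance 5%; for two groups F equals the
squared pooled t statistic), and improvement columns (differences of the
reported means; deviation improvements as absolute differences) complete
the report.

*Deviation* is the mean signed ordinal error `mean(pred - true)`: positive
means systematic over-prediction of sleepiness. It is a bias measure, not
a spread measure — the sign conventions of reported reference results
(KNN's negative entry) identify it as such.

Splits are stratified by label, **not** grouped by participant, matching
the reference protocol; `split_mfd(group_by_participant = TRUE)` is
available, with the caveat that label-stratified splitting lets the same
participant appear in training and test, so reported accuracies include an
identity-recognition component and overstate cross-person generalisation.

Per-class metrics are one-vs-rest: accuracy `(TP + TN)/n` (which is why
per-class accuracies can exceed overall accuracy), precision, and recall
(= sensitivity). A zero denominator reports 0 with an explicit flag rather
than NaN, keeping tables total. Confusion matrices orient rows as
reference and columns as prediction.

## The synthetic generator

`generate_dataset()` emulates the structure of the pilot-study data — it
is a test bed, not a face model. Defaults (10 participants × 200 frames,
class mix proportional to the published per-level sample sizes
278:1305:3463:2497:396) give a 2,000-frame desk-scale dataset; the
full-scale ~8,000-frame setting is one configuration change.

Signal is planted across four facial regions, mirroring the finding that
fatigue information is not confined to eyes and mouth: the primary
informative set (recorded in the ground truth) comprises the four
upper-eyelid y's, two brow-centre y's, the lower-lip-centre y and the chin
y, each shifted by `1.2 px × (level − 1) × effect_scale` times a per-frame
jitter; weaker cosmetic co-movement affects neighbouring lids, brows, jaw
and lips, and a stochastic yawn (probability rising with level) widens the
mouth aperture. The magnitudes are artifact-defined knobs chosen so that,
against 1.5 px Gaussian sensor noise, adjacent levels overlap but the
five levels are clearly separable from several coordinates jointly — no
quantitative deformation sizes exist to copy. Participant placement
offsets (translation σ 20 px, mild scaling) are removed by relativisation
by construction; a small fixed per-participant template perturbation
survives it, as in real faces. Occlusion corruption alternates strictly
between missing cells and extreme excursions so both branches of the
outlier detector are exercised. With `effect_scale = 0` every association
between labels and coordinates vanishes — the null condition under which
no classifier should beat the majority class.

What the generator does **not** model: photorealistic appearance, temporal
autocorrelation of drowsiness (frames are conditionally independent given
the level), head pose, and lighting. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers planted structure of the
assumed kind; they do not certify accuracy on real video.

## Numerical choices and degenerate inputs

* Ties in RFECV size choice → smaller size; in threshold choice → smaller
  threshold; in forest votes → pinned internal RNG so prediction is a pure
  function of its inputs (several backends otherwise break ties through
  the global RNG).
* ANOVA with zero within-group variance: equal means → statistic reported
  as `NA` (undefined), different means → `Inf` with p = 0.
* All-flagged imputation input, all-coincident landmarks, zero-range
  min-max features, classes with fewer samples than folds: typed errors,
  never silent NaN.
* Batch-norm epsilon 1e-5, Adam epsilon 1e-8; inverse min-max reproduces
  inputs to 1e-9; probability rows sum to 1 within 1e-6.

## Problem sizes in the test suite

The suite validates numeric primitives against brute-force oracles (100
randomised cases each, agreement to 1e-9) and runs the full
generate–select–stack pipeline at the default 2,000-frame conditions with
20 Monte-Carlo repetitions; the null calibration uses 10 seeds of a
384-frame dataset with shortened network training (the null property does
not depend on training length); reproducibility is checked by
byte-comparing two complete comparison reports under one master seed.
These sizes are the package's chosen desk-scale experiment; all of them
scale up by configuration.

## Known limitations

* Accuracy on label-stratified splits includes participant identity; use
  grouped splits to estimate cross-person performance.
* The GBM baseline at its published learning rate is divergent by
  construction; comparisons against it mainly document that fact.
* The residual MLP is CPU-bound base R; it is sized for tabular landmark
  vectors (tens of features), not for image-scale inputs.
* The deviation metric averages signed errors, so balanced over- and
  under-prediction cancel; read it together with accuracy, never alone.
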