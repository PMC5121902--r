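---
title: "Matrix-level quality control for combination screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-level quality control for combination screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqc)
```

## The problem

High-throughput pairwise drug-combination screening lays each combination
out as an N x N checkerboard: two agents crossed over descending dose
ladders, single-agent responses on the bottom row and right column, and an
untreated (DMSO) control in the bottom-right corner. Downstream synergy
analysis — excess over Bliss independence, highest-single-agent scaling —
consumes the whole matrix at once, so a response matrix corrupted by a
dispense error, dying cells, or a signal gradient across the plate yields a
confidently wrong synergy call rather than an obviously missing value.

Classical plate-level statistics (Z', SSMD) only watch the control wells.
On a 1536-well plate with a cost-efficient combination layout, controls
occupy four columns (128 wells, about 8%) on one side of the plate; a drift
or sample-field artifact can leave them untouched. The package therefore
grades every deconvoluted response matrix on its own evidence: seven
block-derived features feed a boosted-tree classifier that assigns Good,
Medium or Bad with a calibrated confidence, and screen-level acceptance
combines that grade distribution with the plate statistics.

## The seven features

For a block of normalized responses `V(i, j)` (% of negative control, 100 =
untreated level for both readout polarities):

* `dmso.v` — the response at the control corner (re-oriented as
  `100 - V` for signal-increasing readouts such as Caspase-Glo). Far from
  100 means the in-block control itself failed: dead cells, wrong plate
  position, drift.
* `sa.min`, `sa.max` — the smaller and larger relative standard deviation
  (100·sd/|mean|) of the two single-agent edges. A credible dose response
  has variance; a flat edge is either inactivity or a dead assay.
* `sa.matrix` — the same RSD over the (N−1)×(N−1) combination submatrix.
* `moran.p` — a one-sided spatial-autocorrelation test (Moran's I with
  row-standardized rook weights on the combination submatrix). Small p =
  spatially organized landscape; large p = spatial noise.
* `smoothness.p` — a surface-smoothness test, described below. Small p =
  smooth.
* `mono.v` — the likelihood of monotone dose response: over all ordered
  pairs of combination wells where the second well has at least the first's
  dose of both agents (one strictly higher), the fraction moving in the
  pharmacologically expected direction (ties count 1/2). A perfectly
  monotone landscape scores 1, a perfectly inverted one 0, and random
  responses 0.5 in expectation, which the `t2` acceptance target checks at
  n = 10,000. Because every comparable pair votes, local violations —
  synergy pockets, mild noise — are tolerated.

RSDs with a numerically zero mean are capped (default 1000) rather than
raised, so one degenerate block cannot abort a screen run; the resampling
p-values return 1 with a warning on constant input for the same reason.

### The smoothness test

The full block is fitted with a tensor-product penalized spline over the
integer grid coordinates (`mgcv::gam`, smoothing by GCV; marginal basis
dimension `min(5, N-1)`). The statistic is the RMSD between fitted and
observed responses — near zero for a landscape the smoother can explain.
The null distribution comes from resampling the observed cell values with
replacement onto grid positions and refitting; the p-value is the
probability (add-one smoothed) that such a scrambled, usually rugged,
landscape fits at least as well as the observed one.

Refitting a GCV smooth thousands of times per block is the only expensive
step in feature extraction, so by default the null resamples are pushed
through the smoother matrix estimated on the observed block (a single
linear projection; 10,000 resamples cost one matrix multiplication). The
shortcut is mildly anticonservative under a truly random block — the GCV
smoother adapts to the observed grid, so the null p-value averages ~0.38
rather than 0.50 in our checks — a monotone distortion that is irrelevant
for a classifier that learns its own thresholds, but worth knowing if the
p-value is interpreted in isolation. `features_control(smooth_refit =
TRUE)` re-runs the full GCV fit per resample and is calibrated (null mean
~0.5), at roughly 100x the cost.

### Orientation choices

Small `moran.p` and small `smoothness.p` both mean "organized landscape".
The classifier is indifferent to the orientation as long as it is
consistent; both are documented here and switchable where it matters
(`moran_alternative`). The monotonicity direction flips with the readout
polarity, which every block carries (`readout_direction`).

## The classifier

`mqc()` fits a SAMME-style multiclass AdaBoost: depth-3 CART trees on the
seven features, 100 stages, learning rate 0.5, stage weight
`lr * (log((1-err)/err) + log(K-1))`. Class probabilities are the
alpha-weighted vote shares across stages. The weak learner is a small
purpose-built weighted-Gini CART (exhaustive vectorized threshold search,
deterministic tie-breaking: first feature, lowest threshold): the
validation protocol below refits several thousand ensembles, and a fitter
that works directly on matrices keeps that inside minutes on one CPU.
Trees are stored as plain node tables, so a model persists losslessly to a
self-describing JSON document (`write_mqc()`/`read_mqc()`).

Defaults were chosen for stability at the training scale the method is
designed for (one-to-two hundred expert-labeled blocks); all are exposed
as arguments.

### Confidence

A three-class probability vector's population standard deviation ("spread")
ranges from 0 (maximal uncertainty, probabilities 1/3 each) to
`sqrt(2)/3 ≈ 0.4714` (a unanimous vote). Confidence is calibrated, not
assumed: held-out predictions (5-fold seeded cross-validation inside
`mqc()`, or any external set via `mqc_calibrate()`) give pairs of (spread,
0/1 error); a local polynomial regression of error on spread is evaluated
at the observed spreads, clipped to [0, 1], made monotone non-increasing by
isotonic projection, and extended constantly beyond the observed spread
support (local regression extrapolates wildly and there is no data out
there). Confidence is one minus that expected error. Screen-level analysis
drops predictions with confidence below 0.6 before computing proportions,
mirroring production practice.

### Validation protocol

`mqc_validate()` draws 200 stratified random splits at each of 16 test-set
proportions (5% to 80%) and reports the multiclass Matthews correlation
(Gorodkin's K-category generalization) plus per-class recall and precision
per split, with pooled confusion matrices. `y_randomization()` re-runs the
identical protocol after a seeded label permutation; informative features
show a collapse of the MCC toward zero. A split that loses a class from its
training part is redrawn and counted.

## Plate-level statistics

`zprime()` is `1 - 3(sd_p + sd_n)/|mu_p - mu_n|`; `ssmd_robust()` is
`(median_n - median_p)/sqrt(MAD_n^2 + MAD_p^2)` with 1.4826-scaled MADs
(normal-consistent; the scale choice only rescales magnitudes, not ranks)
and the sign convention that healthy viability assays score positive.
`sample_plate_qc()` recomputes both with the per-block DMSO corners as the
negative group: those wells are scattered through the sample field, so
layout-dependent artifacts that one-sided control columns cannot see (the
drift failure mode) degrade the sample variants first. With fewer than 12
blocks the sample variants are returned flagged as not meaningful.

## Synergy statistics

`bliss_dbnorm()` converts responses to inhibition fractions
`f = clamp(1 - V/100, 0, 1)`, builds the Bliss expectation
`C = fA + fB - fA*fB` from the single-agent edges, and averages
`delta = C - f` over the combination submatrix. With this orientation
negative DBNorm is synergy (more killing than expected) and positive is
antagonism, and a block of i.i.d. uniform responses has expectation exactly
1/4 (`E[C] - E[f] = 3/4 - 1/2`), the closed-form anchor behind the `t3`
acceptance target. The clamp keeps DBNorm in [−1, 1]; an unclamped
diagnostic mode exists. The source material describes the sign of this
statistic inconsistently in two places; this package fixes the orientation
by the 1/4 random-center anchor, which only one choice satisfies.

`hsa_gamma()` scales the observed combination surface against the
highest-single-agent reference `P(i,j) = min(V_A(i), V_B(j))` by least
squares, `gamma = sum(V*P)/sum(P^2)`: gamma < 1 synergy, 1 non-interaction,
> 1 antagonism. The original estimator behind this statistic is not fully
specified in print; the least-squares scale is a documented surrogate with
the same fixed points and orientation.

## The simulator

The generator is the package's testbed: every archetype produces blocks
that pass `validate_block()` and are bit-reproducible under a seed.

Single agents follow four-parameter logistic curves on a 1:2 geometric
ladder whose last dose is zero; combinations follow Bliss independence
plus an archetype deviation (Gaussian synergy/antagonism bump, bell-shaped
non-monotone single agents, a collapsed dead-control baseline at 25% of
signal, or a noise-dominated low-activity landscape for `rugged_noise`).
The error model acts on the inhibition scale —
`f_obs = clamp(f_true + delta_block + N(0, sigma_eps^2), 0, 1)` with
`delta_block ~ N(0, sigma_db^2)` — plus per-well uniform replacement with
probability `p_random` and an optional per-column linear drift in percent
per column. The exact published simulation equations are not recoverable
from the source text; this reconstruction is pinned down by three printed
behaviors it must (and does) reproduce:

* `sigma_db` alone keeps the DBNorm distribution normal and symmetric;
* growing `sigma_eps` skews it positive *when the block population is
  heterogeneous in activity* — the zero-inhibition clamp inflates observed
  inhibition twice in the Bliss expectation but once in the observed well,
  and the size of that bias depends on how inactive the block is, so
  low-activity blocks stretch the antagonism-ward tail. (With a single
  fixed base block the within-block averaging symmetrizes the statistic
  and no skew appears; `simulate_dbnorm()` therefore draws per-block
  maximal inhibition from a range by default.)
* `p_random = 1` centers DBNorm at 1/4 regardless of the original
  distribution.

`gen_screen()` assembles 1536-well plates in the cost-efficient layout
(controls in the four left columns — 128 wells — and twelve 10 x 10 blocks
in the sample field) and applies drift plate-wide, reproducing the failure
mode where plate Z' stays excellent while the blocks degrade from left to
right.

### Intended labels

Classifier tests need ground truth, so the generator carries a documented
label rule: Bad for dead controls, `sigma_eps >= 0.15`, `p_random >= 0.3`
or drift `>= 3%/column`; Medium from `sigma_eps >= 0.06`, `p_random >=
0.1` or drift `>= 1.5`; Good otherwise. `gen_training_blocks()` emulates
the expert-consensus training collection (24 Good, 24 Medium, 78 Bad by
default) by drawing noise magnitudes from bands *inside* those label
regions rather than hugging the boundaries: the collection it stands in
for was assembled from cluster prototypes, so its items are characteristic
examples of each grade, not borderline cases. Grade overlap then comes
from the features' own sampling noise, which keeps the Medium class
genuinely ambiguous — in the bundled validation runs Medium recall sits
near 0.6 while Good and Bad exceed 0.8 at moderate test proportions, the
same asymmetry the expert survey shows.

### The synthetic survey

The original crowdsourcing table is not redistributable, so
`synthetic_survey()` (and the bundled fixture
`inst/extdata/survey_synthetic.csv`) emulates it: 9 raters, 133 items,
consensus composition 78 Bad / 24 Medium / 24 Good with 7 ambiguous items
enforced by construction, and per-rater accuracy 0.75 with
adjacent-grade-heavy confusion. The accuracy constant was calibrated once
against the reported inter-rater agreement level (Fleiss' kappa ≈ 0.35;
the fixture realizes 0.352) and is not a tuning knob. What passing
survey-based tests shows is that the consensus machinery (majority vote
with strict-plurality ties, kappa) is correct — not anything about real
rater behavior.

## Screen-level analysis

`aggregate_screen()` filters predictions at confidence ≥ 0.6 and computes
%Good and %Good-or-Medium; `guideline_verdict()` applies the combined
rule — Z' > 0.5, Good% > 60, Good-or-Medium% > 90, all strict — and labels
failures plate-level (control problem or biased layout) or matrix-level
(cell health, readout, handling). The verdict is monotone: improving any
input never flips pass to fail.

`paired_compare()` matches blocks across a factor (readout, matrix size)
on all other keys and tests the ordinal outcome counts (better/equal/worse
on Good > Medium > Bad) against an exchangeable null where each pair lands
in the three outcomes with probability 1/3. The p-value is the exact tail
`P(X+ − X− ≥ observed)` computed by dynamic-programming convolution of the
m ±1/0 steps (exact to m = 5000, then a continuity-corrected normal
approximation). This tail definition reproduces the published benchmark
comparison — counts (949, 1944, 191) give p = 1.180 x 10^-63, matching the
printed value — which is how the ambiguity in the printed formula was
resolved. Families of comparisons are adjusted with Benjamini-Hochberg
(`bh_adjust()`, a thin wrapper over `p.adjust`).

## Numerical and design notes

* All resampling features take explicit seeds; `qc_features()` is
  bit-reproducible given a `features_control()`.
* Permutation/bootstrap p-values use add-one smoothing and so live in
  `[1/(1+R), 1]`; they never return 0.
* Hill fits (`fit_hill()`) use Levenberg-Marquardt with bounded
  parameters, initialized at the data envelope and the geometric
  mid-concentration; `valid` additionally requires the IC50 inside the
  tested range, the classic usable-curve heuristic.
* The legacy five-criterion heuristic score (`mott_qc()`) has its
  unpublished constants exposed as arguments (default weights all 5, DMSO
  acceptance range 80–120), so the conventional "score > 10 is bad" reading
  equals "three or more violations".
* Problem sizes in the test suite: permutation/bootstrap depths of 99–999,
  126-block training sets, 200-split validation, 10,000-block Monte Carlo
  for the two analytic anchors. These were chosen as the smallest scales at
  which the statistical assertions are stable.

## Known limitations

* The classifier is only as good as the label source; with the synthetic
  stand-in, test performance measures internal consistency of the
  pipeline, not transferability to any particular laboratory's data.
* Replicate consistency across blocks (a matrix-level analogue of the
  minimum significant ratio) is out of scope.
* The smoothness feature's fast null is anticonservative as noted; the
  Moran permutation test on very small submatrices (N−1 ≤ 3) has a coarse
  p-value lattice.
* Only pairwise (surface-format) combinations are covered; higher-order
  mixtures need a different data model.
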