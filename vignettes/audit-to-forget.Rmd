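---
title: "Auditing and forgetting training data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and forgetting training data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `afs`, the parameters
that matter, the synthetic fixtures the package validates itself on, and the
places where the design was genuinely open and a choice had to be made.

## 1. The auditing model

The audit decides, from model outputs alone, whether a query dataset
$Q = \{(x_i, y_i)\}_{i=1}^N$ was part of a classifier's training data. It
builds on per-sample membership inference: a model trained on $x$ tends to
classify it correctly, assign it high true-class probability, and produce a
low-entropy predictive distribution. For each sample three indicators are
computed from the predicted class probabilities $F(x)$:

* **correctness** $\mathbf{1}\{\arg\max_i F(x)_i = y\}$,
* **confidence** $\mathbf{1}\{F(x)_y \ge \tau_y\}$,
* **entropy** $\mathbf{1}\{-\sum_i F(x)_i \log F(x)_i \le \hat\tau_y\}$,

and the sample is voted a member if **any** indicator fires (OR rule). The
dataset-level statistic compares the vote vector $v \in \{0,1\}^N$ with the
all-one vector via a pooled-variance two-sample Student's t-test with
$2N - 2$ degrees of freedom, two-tailed. A large $p$ means the votes are
indistinguishable from "all members"; given a user-defined level $\alpha$
(default 0.05), $p < \alpha$ supports the conclusion that the query was not
used for training.

Assumptions worth making explicit:

* The target model must *overfit to some measurable degree*: if it
  generalises perfectly, members and non-members produce identical score
  distributions and no membership signal exists. The test then loses power
  rather than producing false certainty (votes saturate, $p$ is large for
  everything).
* The calibration data must come from the same distribution as the query
  and be disjoint from the target's training set; leakage inflates the
  thresholds' member side.
* Votes are treated as i.i.d. Bernoulli draws by the t-test. At small $N$
  the normal approximation is poor, so results with $N < 20$ carry a
  `low_power` flag.

### Threshold calibration

Thresholds are inferred from known member/non-member populations that the
target model itself cannot provide. A *shadow* (calibration) model of the
student architecture is trained on a random half of the calibration set;
its own training half then plays the member role and the untouched half the
non-member role. For each metric and class, the chosen threshold maximises
balanced accuracy $(\mathrm{TPR}(t) + \mathrm{TNR}(t))/2$.

Numerical choices, all deterministic:

* **Candidate grid.** Midpoints between consecutive sorted unique pooled
  scores, plus one sentinel below the minimum and one above the maximum.
  This grid is finite and complete: every achievable confusion table is
  realised by some candidate. Among ties the smallest candidate wins.
* **Per-class thresholds with a pooled fallback.** The confidence and
  entropy thresholds are indexed by class, but a class with fewer than
  `min_per_side = 5` calibration samples on either side falls back to the
  pooled-over-classes threshold. Small calibration sets (the protocol goes
  as low as 100 samples) cannot support ten class-conditional thresholds.
* **Correctness is a fixed binary vote** (threshold 0.5): the indicator is
  already 0/1 and defines no tunable cut.
* **Arg-max ties** resolve to the lowest class index; ties are
  measure-zero for trained models but the rule keeps the pipeline
  deterministic.
* **Entropy uses the natural logarithm.** The base only rescales the
  threshold, which is calibrated anyway; `log C` is then the exact maximum.
* **Shadow architecture = student architecture** by default, configurable.
  The audit is most often applied to student-sized models (in the
  forgetting loop it always is), and calibration cost scales with the
  shadow model.

### The t-test and its degenerate cases

The reference vector has zero variance, so a Welch test is unavailable and
the classic pooled form is the natural two-sample variant. Degenerate
inputs are defined explicitly rather than left to the statistics routine:
a vote vector identical to the reference (all ones) gives $p = 1$; zero
pooled variance with unequal means (all zeros) gives $p = 0$. At $N = 1$
the statistic is undefined and the same rule applies; single-sample queries
are flagged low-power and should not be interpreted — individual-level
membership claims are outside the audit's design.

## 2. The forgetting model (knowledge purification)

Given a teacher trained on $D$, a forget set $QF \subset D$, and a retained
fraction $k$ of $D_r = D \setminus QF$, the student is trained with

$$\mathcal{L} = (1-\alpha_{KD})\,\mathrm{CE}(s(x), y) +
\alpha_{KD}\, T^2\, \mathrm{KL}\!\left(t_T(x) \,\|\, s_T(x)\right) +
\beta \left(\log C - H(s(x_{QF}))\right)$$

where $s_T, t_T$ are temperature-softened student/teacher distributions.
The first two terms are standard distillation; the third pushes the
student's predictions on the forget set towards uniform ignorance.

**Why a surrogate forget term?** The audit p-value is a function of
thresholded indicators and is therefore piecewise constant in the model
parameters — it has no useful gradient. The negative-feedback design puts
the audit where it can act: after each epoch the forget set is audited on
the current student (against thresholds calibrated once up front and frozen,
since per-epoch recalibration would retrain the shadow model fifty times
for no stated benefit), and the result drives the weight $\beta$:

* $p > \mathrm{target}_p$ (still member-like): $\beta \leftarrow
  \min(\beta \cdot m, \beta_{cap})$ — push harder;
* $p \le \mathrm{target}_p$ (forgotten): $\beta \leftarrow
  \max(\beta / m, \beta_{init})$ — relax and let utility recover.

Early stopping fires when the forget set has audited as forgotten for
`patience` consecutive epochs *and* (when a test set is supplied) test
accuracy is within `acc_budget` of the teacher's.

Defaults and why: $\alpha_{KD} = 0.5$ (equal weight to labels and teacher;
no protocol value exists), $T = 2$ (mild softening, the common distillation
choice), $\beta_{init} = 1$, multiplier $m = 2$, cap 64 (a geometric
schedule reaches the cap in six escalations — fast enough to matter within
50 epochs, bounded so a hard case cannot blow up the objective),
$\mathrm{target}_p = 0.05$ (matching the default audit level), patience 3,
accuracy budget 0.05. All are `forget_config()` fields.

Reduction contracts hold by construction and are tested: $\beta = 0$ gives
standard knowledge distillation with an identical trajectory;
$\beta = 0, \alpha_{KD} = 0$ gives plain supervised training.

## 3. Training engine and optimisation

The package carries its own minimal neural-network engine: dense and
convolutional layers (im2col), max-pooling, ReLU, softmax, exact
backpropagation, and Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). Gradients are verified against central finite
differences in the test suite. He-scaled Gaussian initialisation is drawn
under a model seed, so a `(spec, seed)` pair is bitwise reproducible and
every determinism contract can be asserted on md5 fingerprints of the
parameter arrays. The registry also instantiates the standard ResNet-18/34
basic-block plans (inference and parameter accounting; their totals with a
two-class head are 11,177,538 and 21,285,698).

Mini-batch order depends only on `(seed, epoch)`; the forget-batch stream
draws from an independently derived seed so that adding a forget set never
perturbs the retain batches — this is what makes the reduction contracts
exact rather than approximate.

**Learning rate.** The experiment protocol trains with Adam at `lr = 0.01`
for 50 epochs. The protocol this package scales down prescribes 50 epochs
at `1e-5` for GPU-scale models on 10k-sample tasks; at desk scale Adam's
per-step movement is bounded by roughly the learning rate, so 50 epochs of
~30 minibatches at `1e-5` could move weights by at most a few hundredths —
no fixture model could fit, let alone memorise. Since the fixtures exist
precisely to create measurable memorisation, the package treats the epoch
budget and optimiser as protocol and the learning rate as a scale-dependent
choice, fixed once at 0.01.

## 4. Synthetic fixtures and what they show

`gen_gaussian_blobs(n, C, d, separation, seed)` draws balanced classes
centred at `separation * e_c` with unit isotropic noise. The experiment
protocol (`blob_protocol()`) uses $C = 3$, $d = 50$, separation 2, and a
2600-sample pool split into train 1000 / test 500 / calibration 500 with
the 600-sample remainder as the held-out non-member pool. Two properties
matter and motivate these numbers:

* **Capped generalisation.** With centre distance $2\sqrt{2}$ against unit
  noise, the pairwise Bayes error is $\Phi(-\sqrt{2}) \approx 8\%$ per
  class pair, so held-out accuracy plateaus in the mid-0.8s.
* **Easy memorisation.** In 50 dimensions the nearest-neighbour distance
  between training points ($\approx \sqrt{2d} \approx 10$) dwarfs the class
  separation, so an over-parameterised MLP (hidden width 256, ~14k
  parameters for 1000 samples) interpolates its training split.

Together they produce exactly the overfitting gap the audit exploits:
training samples are all classified correctly with near-one confidence
while held-out samples are not. The test suite asserts the gap with margin
over five replicate seeds.

`gen_toy_images()` (oriented-bar classes plus pixel noise) exercises the
convolutional path, and `gen_ehr_table()` (mixed Bernoulli/Gaussian
features with a logistic outcome, shaped like a ~1000-row, 20-feature
screening table) the tabular/EHR path end to end.

What the fixtures do *not* emulate: natural-image statistics, class
imbalance, label noise, distribution shift between query and calibration
data, and feature correlation structure of real EHR. Passing the suite
shows the machinery is correct and that the audit/forgetting dynamics
behave as designed in the memorisation regime; it does not certify
real-data operating characteristics, which depend on how strongly the
target model overfits.

Problem sizes throughout (1000-sample training splits, 200-sample queries,
100-sample forget sets, 5 replicate seeds) were chosen so that every
end-to-end experiment trains in seconds on one CPU core while keeping the
vote-vector tests well powered.

## 5. Query construction conventions

* `round(k * N)` members of a QM query are computed by rounding half away
  from zero, and the *realised* fraction is stored, keeping the overlap
  invariant exact for awkward `k * N`.
* Non-members for QNO/QM come from a dedicated held-out partition never
  used for training, testing, or calibration. Disjointness from the
  calibration set avoids leaking non-member structure into the thresholds.
* All sampling is without replacement, matching the non-overlapping
  construction of the splits.
* Five-replicate averaging is the default reporting convention for every
  stochastic quantity; replicate seeds are explicit arguments everywhere.

## 6. Baseline conventions

* **SISA**: seeded uniform shard assignment (default 10 shards), persisted
  with the model so unlearning can locate the affected shards; only those
  are retrained, with their original per-shard seeds, making unlearning
  idempotent. Aggregation is majority vote over shard arg-maxes with vote
  shares as the probability output — the canonical rule; the vote-share
  output is coarse (multiples of 1/S), which slightly blunts
  confidence/entropy signals when auditing a sharded model.
* **CF-k / EU-k**: "layer" means a parameterised layer group in registry
  order. Frozen groups are bitwise unchanged (asserted via fingerprints);
  EU-k re-initialises the trailing groups from the seed before training, so
  EU-depth coincides exactly with independent retraining under the same
  seed.

## 7. Known limitations

* Dataset-level only: the two-sample design needs a batch of query samples;
  it cannot certify forgetting of an individual record.
* Classification only: the membership signals are defined on predictive
  distributions over classes.
* No certified-removal guarantee: the audit is an empirical test, and the
  forget term shapes behaviour, not information content in a provable
  sense.
* An honest audit requires an overfitting target model; against a
  well-regularised model the test is conservative.
* The residual networks in the registry are inference/accounting entries;
  the trainable families are the MLP and the small CNN.
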