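# afs — dataset-level membership auditing and audit-guided machine unlearning

Privacy regulations give patients the right to have their data deleted — not
only from storage, but from the deep-learning models trained on it. That
raises two coupled questions for anyone operating a clinical classifier:

* **Auditing** — was this query dataset used to train the model? `afs`
  answers with a dataset-level p-value: large p means the query behaves like
  training data (member-like), small p means it does not.
* **Forgetting** — if it was, remove its influence. `afs` implements
  *knowledge purification*: a smaller student model is distilled from the
  teacher on a retained fraction of the training data while an audit-driven
  forget term pushes the student to be ignorant of the forget set, with the
  per-epoch audit p-value steering the forget pressure in negative feedback.

## The method

**Auditing.** For a classifier `F` and a labeled sample `(x, y)`, three
membership signals are computed from the predicted class probabilities:

* correctness: `1{argmax_i F(x)_i = y}`,
* confidence: `1{F(x)_y >= tau_y}`,
* entropy: `1{-sum_i F(x)_i log F(x)_i <= tau_hat_y}`.

The per-class thresholds `tau_y`, `tau_hat_y` are calibrated on a *shadow
model*: a model of the student architecture trained on half of a calibration
set disjoint from the target's training data. Its training half provides
known member scores, the untouched half known non-member scores, and each
threshold is chosen to maximise balanced accuracy `(TPR(t) + TNR(t)) / 2`
over a candidate grid (midpoints of the sorted pooled scores). A sample is
voted a member when **at least one** signal lands on the member side (OR
rule). The dataset verdict is a two-tailed pooled-variance Student's t-test
(df = 2N − 2) of the vote vector against an all-one reference vector.

**Forgetting.** The student is trained on a `k`-fraction of the retain set
(training data minus the forget set QF) with

```
loss = (1 - a) * CE(student, labels) + a * T^2 * KL(teacher_T || student_T) + beta * (log C - H(student(QF)))
```

The last term pushes the student's predictions on QF towards the uniform
distribution. Because the audit p-value is piecewise constant in the
parameters, it cannot be differentiated; instead it modulates `beta` after
every epoch: while QF still audits member-like (`p > target_p`) `beta`
doubles (capped), once forgotten it decays. Training stops early when QF has
audited as forgotten for a few consecutive epochs and test accuracy is
within a budget of the teacher's.

Baselines included for comparison: independent retraining at fraction `k`,
SISA sharded unlearning (only shards containing QF are retrained), and the
last-k-layer methods CF-k (fine-tune) and EU-k (retrain from scratch).

## Worked example

```r
library(afs)

# a synthetic cohort: 3 classes in 50 dimensions, memorisable but noisy
pool   <- gen_gaussian_blobs(2600, C = 3, d = 50, separation = 2, seed = 1)
splits <- make_splits(pool, train_n = 1000, test_n = 500, cal_n = 500, seed = 1)

teacher <- train_independent(model_spec("mlp", 50, 3, hidden = 256),
                             splits$train, seed = 1)

# audit a member query (drawn from train) and a non-member query
student_spec <- model_spec("mlp", 50, 3, hidden = 64)
qo  <- build_query(splits, "QO",  size = 200, seed = 2)
qno <- build_query(splits, "QNO", size = 200, seed = 3)
audit_dataset(teacher, qo,  splits$calibration, arch = student_spec, seed = 1)
#> <afs_audit> N = 200 | member fraction = 1.000 | p = 1
#>   verdict: member-like (alpha = 0.05)
audit_dataset(teacher, qno, splits$calibration, arch = student_spec, seed = 1)
#> <afs_audit> N = 200 | member fraction = 0.840 | p = 1.816e-09
#>   verdict: non-member-like (alpha = 0.05)

# forget 100 training samples by knowledge purification
qf <- build_query(splits, "QF", size = 100, seed = 4)
kp <- afs_train(teacher, student_spec, splits$train, qf, splits$calibration,
                config = forget_config(k = 0.5, seed = 1), test = splits$test)
kp
#> <afs_kp> student: mlp ( 3,459 params )
#>   transfer set: 450 samples | forget set: 100
#>   epochs run: 3 (forgotten_within_budget)
#>   final forget-set p: 3.697e-13
#>   final test accuracy: 0.8060 (teacher: 0.8420 )
```

The teacher memorised its training split, so the member query audits at
p = 1 while the held-out query is rejected at p ≈ 2e-09. After three epochs
of purification the forget set audits at p ≈ 4e-13 on the student — it no
longer looks like training data — at a ~4-point accuracy cost against the
teacher. Auditing QF on the teacher still gives p = 1.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/afs.R simulate --type blobs --n 2600 --out pool.csv
Rscript inst/cli/afs.R audit --model teacher.rds --query q.csv \
    --calibration cal.csv --num-classes 3 --out report.json
Rscript inst/cli/afs.R forget --teacher teacher.rds --train train.csv \
    --forget qf.csv --calibration cal.csv --k 0.5 --out-dir run/
```

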