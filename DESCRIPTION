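Package: afs
Title: Dataset-Level Membership Auditing and Audit-Guided Machine Unlearning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits whether a query dataset was used to train a probabilistic
    classifier and, when it was, forgets it. Auditing computes three per-sample
    membership signals (correctness, true-label confidence, prediction entropy),
    calibrates per-class decision thresholds on a shadow model by maximising
    balanced accuracy, aggregates per-sample votes with an OR rule, and reports
    a dataset-level p-value from a pooled two-sample t-test against an all-one
    reference vector. Forgetting implements knowledge purification: a student
    model is distilled from the teacher on a retained fraction of the training
    data while an entropy-maximising forget term, modulated in negative feedback
    by the per-epoch audit p-value on the forget set, suppresses the forget
    set's information. Sharded (SISA), last-k-layer fine-tuning (CF-k) and
    last-k-layer retraining (EU-k) unlearning baselines, seeded synthetic data
    generators, and a small neural-network engine are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
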