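Package: qfoa
Title: Quantum-Inspired Fruit Fly Optimization for SVM Hyperparameter Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes the penalty factor C and RBF kernel width gamma of a
    soft-margin support vector machine with a quantum-inspired fruit fly
    optimization algorithm (QFOA). Candidate parameters are encoded as
    quantum phase angles that decode to complementary cosine and sine
    solutions, perturbed by swarm search, mutated with a quantum NOT gate
    and accepted under a Boltzmann annealing rule. The fitness is the
    k-fold cross-validated mean of a weighted sum of the false negative
    and false positive rates, so missed diagnoses can be penalized more
    heavily than false alarms, as computer-aided diagnosis requires.
    Includes the classic fruit fly optimizer and an exhaustive grid search
    as baselines, confusion-matrix diagnostics, repeated-run comparison
    harnesses, and a synthetic generator that emulates a small imbalanced
    CT-feature cohort with a controllable class-separation knob.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
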