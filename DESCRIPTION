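Package: arithpop
Title: Single-Neuron and Population Analysis of Arithmetic Operation Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit activity recorded while a subject
    performs incremental numerical addition and subtraction with left/right
    manipulanda under reversible device rules. Implements the trial/condition
    data model for a numerical operation task and an instructed operation task,
    behavioural statistics (selection-rate matrices, exact binomial tests,
    Gaussian tuning fits and the numerical size effect, exact McNemar tests,
    reaction-time congruency contrasts), per-cell binwise factor regression in
    100 ms windows with coding-history classification, sliding-window ROC (AUC)
    selectivity with population ellipse and relative-variance dynamics and the
    simultaneous arithmetic-by-hand coder analysis, pseudopopulation linear SVM
    decoding with temporal cross-training, permutation significance and
    cross-operation classifier reuse, and a synthetic Poisson spike-train
    generator that plants ground-truth selectivity so every stage is verifiable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
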