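---
title: "Methods: models, parameters and design choices in arithpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in arithpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`arithpop` analyses single-unit activity from a numerical operation task in
which a subject transforms a displayed numerosity (0–6 items) into a
remembered target (1–4 items) by incremental device use, under two reversible
device rules, plus an instructed variant in which a +/− cue replaces the
target. This vignette documents the models the package implements, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the design decisions taken where the procedure was
genuinely open.

## The task model

Each trial advances through fixation (800 ms), target or pre-instruction cue
(700 ms), delay 1 (1000 ms), preoperational numerosity or instruction
(700 ms), delay 2 (1000 ms) and a Go signal. The analysis epoch (the *concern
period*) spans preoperational onset to 700 ms after the Go signal: 2400 ms,
split into 24 half-open 100 ms bins `[t, t+100)`; bins 1–17 are aligned to
the preoperational onset and bins 18–24 to the Go signal, so recordings with
variable delays splice seamlessly at the Go event.

Three factors label every analysed trial: *arithmetic* = sign(target −
preoperational), *hand* = the device the current rule requires for that
operation (rule 1: addition→left; rule 2 reversed), *step* = |target −
preoperational| restricted to {1, 2}. Only correct trials executed with the
minimum number of device uses are analysed; matched-numerosity "hold" trials
carry no operation and are excluded from labelled analyses.

**The 19 condition pairs.** The recorded condition set is shown only
graphically in the source material. Enumerating all (target, preoperational)
pairs with |Δ| ≤ 2 *including* the four matched pairs — hold trials are an
explicit part of the task — yields exactly 19 conditions
(15 operation pairs + 4 holds), which is the default of
`enumerate_conditions()`. Restricting to 1 ≤ |Δ| ≤ 2 would give only 15, so
the matched pairs are the only enumeration consistent with the reported
count. The set is configurable (`delta_range`, or a user-supplied table) for
alternative reconstructions.

## The synthetic generator

The generator's role is to plant *known* structure so each analysis stage can
be validated against ground truth.

**Behaviour.** Chosen numerosity is the nearest integer in [0, 6] to a draw
from Normal(target, σ(target)) with σ(t) = a + b·t (defaults a = 0.4,
b = 0.2 numerosities), producing the numerical size effect; the instructed
task steps one unit in the cued direction with a 5% lapse. Reaction times are
Gaussian (400 ± 50 ms) minus a 30 ms congruency advantage on addition-right /
subtraction-left trials. Note that rounding to the numerosity grid inflates a
fitted Gaussian SD by roughly √(σ² + 1/12)/σ (≈ +11% at σ = 0.6); recovery
checks therefore use a ±20% band rather than the nominal sampling error.

**Spiking.** Each cell fires Poisson counts per 100 ms bin at
`max(0, baseline · (1 + Σ_f gain_f · sign_f(trial)))`, where `sign_f` is ±1
for the trial's level of factor *f* (positive = addition / right / one step /
standard stimulus) and each factor's effect is confined to a temporal window
within the concern period. Defaults: baseline 10 spikes/s, |gain| 0.5.
Multiplicative rectified-linear mixing was chosen for transparency — the
planted "coefficient" of a factor is exactly 2·gain·baseline spikes/s inside
its window and 0 outside, which the regression oracle tests exploit. Coding
*transitions* (arithmetic → hand → step) are expressed by giving successive
factors successive windows.

**Presets.** `study_like` plants a mixed population at study scale (539
cells): arithmetic-only coders (8%), simultaneous arithmetic+hand coders (5%,
80% of them sign-coupled addition↔right), arithmetic→hand (6%) and
arithmetic→step (4%) transition cells, comparison-only cells whose arithmetic
code does not follow the instruction (13%), hand-only (10%), step-only (16%),
remainder unselective. Factor windows stagger arithmetic (100–1000 ms,
sustained to 1700 ms in simultaneous coders), hand (1400–2100 ms;
100–2100 ms in simultaneous coders) and step (2100–2400 ms), so the
population code moves arithmetic → hand → step across the trial. `null`
plants nothing and calibrates every significance procedure. `snarc_reuse`
gives every cell an arithmetic code over bins 1–17 that is re-expressed with
matched sign (addition↔right) as a hand code over bins 18–24; `static_code`
holds one arithmetic code over all 24 bins. `uncoupled` matches
`snarc_reuse` but with *exactly half* the cells congruent: an i.i.d. random
assignment of hand signs would leave a residual Σᵢ s^arith_i·s^hand_i of
order √n that a reused classifier genuinely detects, so a meaningful
"no-coupling" control must zero the net coupling by construction.

**What the generator does not emulate.** Session-to-session drift,
correlated trial-to-trial noise across simultaneously recorded cells,
non-Poisson spiking statistics, reaction-time jitter of the Go-aligned bins
(the Go signal is fixed at 1700 ms so the 24 bins tile the epoch
contiguously), eye movements, and switching behaviour sequences. Passing
recovery tests on this generator therefore demonstrates the *pipeline's*
correctness, not robustness of the biological conclusions to those features.

## Encoding classification

Per cell and bin, ordinary least squares of firing rate (counts / 0.1 s) on
four 0/1 dummies (addition / right / one step / standard = 1; only the
significance pattern matters, and it is invariant to the assignment), with
two-sided t tests per coefficient at α = 0.01 and no correction across bins
— the any-bin rule defines the coding history. Because every cell and bin
shares one design matrix, the whole population is fit in a single pass of
matrix algebra. Factors with fewer than 5 trials at either level (the
configurable estimability floor) are excluded as unestimable rather than
imputed.

A consequence of the any-bin rule worth stating: a cell with a purely static
arithmetic code still loses "exclusively arithmetic" status whenever any of
the 34 post-preoperational hand/step bin tests false-fires
(P ≈ 1 − 0.99³⁴ ≈ 29%). The static-code calibration test checks that the
loss equals this chance rate; the planted dynamic population loses far more,
and that contrast — not a literal "no change" — is the meaningful check on
the exclusive-coding McNemar test.

The instructed-task filter refits `rate = β₀ + β₅·instruction` over the seven
bins after instruction onset; candidates keep arithmetic selectivity only if
β₅ is significant in at least one bin, which removes cells whose numerical-
task "arithmetic" signal reflects magnitude comparison (a null cell survives
with probability 1 − 0.99⁷ ≈ 6.8%, and the recovery tests account for that).

## ROC dynamics

AUC is the Mann–Whitney statistic computed from rank sums (ties count half),
with the positive class fixed as addition / right / one step. Population
summaries per bin: the 95% confidence ellipse of the per-cell (AUC_f1,
AUC_f2) cloud — sample mean and covariance, contour at Mahalanobis² =
χ²₀.₉₅(2) = 5.991, θ folded into [0°, 90°] relative to the first axis — and
the relative variance (across-cell AUC variance per bin normalised by its
period mean, so the series always averages 1).

Simultaneous arithmetic×hand coders are selected by permutation: the per-cell
statistic is the concern-period maximum |AUC − 0.5| per factor; the null
shuffles that factor's trial labels 1000 times (shared across cells, which
leaves each cell's ranks untouched and is therefore computed by one matrix
product per cell); selection requires both factors to exceed their null 95th
percentiles strictly. Permutation p-values use (1 + #{null ≥ obs})/(1 + N).
At each bin the selected cells partition by AUC sign on each factor; cells
sitting exactly at 0.5 are excluded from that bin (ties carry no preference).
Per-bin binomial tests ask whether each hand group over-represents its
congruent operation (chance 0.5), and the series-level test counts
significant bins against a 5% per-bin rate.

## Decoding

Pseudopopulations require ≥10 trials per target×arithmetic×hand condition
per cell and sample 10 per condition without replacement, condition-matched
across cells (160 pseudotrials in the full design). Decoding uses a linear
SVM (LIBSVM through `e1071`, cost 1, no kernel) with tenfold
condition-stratified cross-validation; the same fold partition serves all
576 (train bin × test bin) pairs so pixels are comparable, and features are
z-scored per cell with training-split statistics of the *training* bin only
(no leakage). Predictions are evaluated through the explicit decision
function w·x − ρ, which lets one matrix product score all 24 test bins per
fitted classifier.

Within-system permutation significance refits the classifiers on shuffled
labels, one shuffle per replicate reused across all pixels; a pixel is
significant when its accuracy strictly exceeds the 50th-highest of 1000 null
values (ties non-significant). Cross-operation grids reuse the fitted
classifiers without refitting — predictions are mapped through the
addition↔right / subtraction↔left bijection and scored against the other
label system — so their permutation null shuffles the *tested* labels and
re-scores the stored predictions, which is exactly the null of the reported
quantity at a fraction of the cost. Region summaries (diagonal 24,
prospective 276, retrospective 276) are evaluated with the exact binomial
tail test at a per-pixel chance rate of 0.05.

Cross-operation grids support two permutation nulls, and the choice is not
cosmetic. Shuffling the *tested* labels against the fixed classifiers (the
default, and the cheap option) tests "predictions carry no information about
the tested labels" — but a classifier fit on one label system carries
weight-sampling noise whose overlap with any *other* code present at the
tested window is random yet fixed across the cross-validation (the folds
share most of their training data). On a population whose arithmetic and
hand codes are genuinely uncoupled, this inflates reuse-pixel accuracies
symmetrically about 50% (we observe spreads of ±0.18 at study-scale effect
sizes), and a null blind to it marks far more than 5% of prospective pixels.
The `refit` null re-runs the whole procedure on shuffled training labels each
replicate — the classical full-pipeline permutation — and absorbs that
variance; the package's no-coupling control is therefore evaluated with the
refit null, while coupled populations give the same verdict under either
(their reuse accuracies sit far above both thresholds, and the retrospective
region is immune because the early windows contain no hand code at all).

## Numerical choices and degenerate inputs

* Exact upper-tail binomial tests throughout (`P(X ≥ k)`), exact two-sided
  McNemar on discordant pairs with p = 1 when none exist.
* Gaussian tuning fits by Levenberg–Marquardt least squares with free
  amplitude, mean and SD; rows with <3 occupied numerosity bins or
  non-convergent fits are flagged and excluded from the size-effect
  regression.
* Singular AUC covariance marks the ellipse degenerate with θ defined by the
  non-zero axis; all-zero cells regress to a zero coefficient with an NA
  p-value (0/0 t statistic), never a significance flag.
* Per-cell SDs of zero during z-scoring are replaced by 1, leaving the
  feature constant and uninformative.
* One master seed drives trials, choices and spikes through R's RNG in a
  fixed order, so identical (config, seed) pairs give bit-identical outputs,
  including pipeline manifests.

## Problem sizes used in the shipped checks

The generator defaults are study-scale (539 cells, 19 conditions,
160-pseudotrial decoding design). The automated checks exercise the same
code at the population sizes their statistics need rather than at full
scale: calibration suites use 200-cell null populations and 24-cell decode
subsets with 200-shuffle nulls; recovery suites use 120-cell mixed
populations over 50 replicates and 36-cell reuse populations over 20 (the
no-coupling control: 3 pooled runs on a 12×12 window grid under the refit
null); the dynamics check runs a single full 539-cell population. These sizes are
stated here as the package's validation design; all thresholds (α = 0.01
regression, α = 0.05 permutation, 10 folds, 10 trials/condition) are the
analysis defaults, never adjusted per run.

## Known limitations

* The regression treats 100 ms Poisson counts as Gaussian; at a 1 spike/bin
  baseline the t test is mildly conservative in the extreme tail, which the
  α-calibration suite bounds but does not remove.
* Cells are simulated (and pseudotrials resampled) independently;
  noise-correlation structure between simultaneously recorded cells, which
  can change decoding accuracy substantially, is out of scope.
* The quadrant analysis requires factors to be co-expressed within a bin;
  populations whose arithmetic and hand codes never overlap in time (the
  pure-reuse limit) have no simultaneous coders to partition, and the
  package reports an empty selection rather than inventing one.
* The instructed task's step and hand labels describe the executed action;
  multi-action instructed trials are excluded rather than modelled.
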