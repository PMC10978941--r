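# Synthetic task, behaviour and spike-count generator.
#
# The generator emulates the study conditions: the numerical operation task
# (targets 1-4, preoperational numerosities 0-6, 19 condition pairs, two
# device rules switched in blocks), the instructed task (+/- instruction,
# preoperational 1-3), 50/50 standard/control stimulus counterbalancing,
# behavioural choices with a numerical size effect, and Poisson spike counts
# from cells with planted factor selectivity and coding transitions.

#' Behavioural choice model
#'
#' Gaussian numerosity representation whose standard deviation grows linearly
#' with the target (the numerical size effect): sigma(target) = a + b * target.
#' Reaction times carry a congruency advantage for addition-by-right-hand and
#' subtraction-by-left-hand responses (a SNARC-like association).
#'
#' @param sigma_intercept,sigma_slope Size-effect parameters a > 0, b >= 0
#'   (numerosity units). Defaults 0.4 and 0.2.
#' @param lapse Instructed-task lapse probability (wrong-direction step).
#' @param rt_mean_ms,rt_sd_ms Reaction-time distribution (ms).
#' @param snarc_advantage_ms RT advantage (ms) on congruent hand-operation
#'   trials.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(sigma_intercept = 0.4, sigma_slope = 0.2,
                           lapse = 0.05, rt_mean_ms = 400, rt_sd_ms = 50,
                           snarc_advantage_ms = 30) {
  stopifnot(sigma_intercept > 0, sigma_slope >= 0,
            lapse >= 0, lapse <= 1, rt_mean_ms > 0)
  structure(list(sigma_intercept = sigma_intercept, sigma_slope = sigma_slope,
                 lapse = lapse, rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 snarc_advantage_ms = snarc_advantage_ms),
            class = "behavior_model")
}

#' Generate a trial table for one task
#'
#' Conditions are drawn uniformly from [enumerate_conditions()]; the device
#' rule alternates in blocks (rule switches roughly every
#' `rule_block_length` trials during recording sessions); the stimulus is the
#' standard or the circumference/area-counterbalanced control signal in 50% of
#' trials each. Choices and outcomes are left unfilled until
#' [simulate_choices()].
#'
#' @param task `"numerical_operation"` or `"instructed"`.
#' @param n_trials Number of trials.
#' @param rule_block_length Trials per rule block (default 250).
#' @param seed Optional RNG seed for reproducibility.
#' @param conditions Optional condition data.frame overriding the default set.
#' @return A trial data.frame (see [validate_trials()]); event-time columns
#'   give onsets in ms from trial start, with `t_preop_on` the onset of the
#'   preoperational numerosity (numerical task) or of the instruction
#'   (instructed task) and `t_go` the Go signal.
#' @export
generate_task_trials <- function(task = c("numerical_operation", "instructed"),
                                 n_trials, rule_block_length = 250,
                                 seed = NULL, conditions = NULL) {
  task <- match.arg(task)
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions)) conditions <- enumerate_conditions(task)
  idx <- sample.int(nrow(conditions), n_trials, replace = TRUE)
  tl <- event_timeline()
  block <- ((seq_len(n_trials) - 1L) %/% rule_block_length) %% 2L
  trials <- data.frame(
    trial_id = seq_len(n_trials),
    task = task,
    rule = ifelse(block == 0L, "rule1", "rule2"),
    target_numerosity = if (task == "numerical_operation")
      conditions$target_numerosity[idx] else NA_integer_,
    preoperational_numerosity = conditions$preoperational_numerosity[idx],
    instruction = if (task == "instructed")
      conditions$instruction[idx] else "none",
    stimulus_type = sample(c("standard", "control"), n_trials, replace = TRUE),
    actions = "",
    chosen_numerosity = NA_integer_,
    correct = NA,
    reaction_time_ms = NA_real_,
    stringsAsFactors = FALSE
  )
  trials$t_fixation <- 0L
  trials$t_target_on <- tl$fixation_ms
  trials$t_delay1 <- tl$fixation_ms + tl$target_on_ms
  trials$t_preop_on <- trials$t_delay1 + tl$delay1_ms
  trials$t_delay2 <- trials$t_preop_on + tl$preop_on_ms
  trials$t_go <- trials$t_delay2 + tl$delay2_ms
  trials
}

#' Simulate behavioural choices, actions, outcomes and reaction times
#'
#' Numerical operation task: the chosen numerosity is the nearest integer in
#' 0-6 to a draw from Normal(target, sigma(target)), which produces the
#' numerical size effect. Instructed task: one step in the instructed
#' direction, with a lapse probability of stepping the wrong way. Actions are
#' filled in as the minimum-step device sequence from the preoperational to
#' the chosen numerosity under the trial's rule. Reaction times are Gaussian
#' with the congruency advantage subtracted on addition-right / subtraction-
#' left trials.
#'
#' @param trials Output of [generate_task_trials()].
#' @param model A [behavior_model()].
#' @param seed Optional RNG seed.
#' @return `trials` with `chosen_numerosity`, `actions`, `correct` and
#'   `reaction_time_ms` filled.
#' @export
simulate_choices <- function(trials, model = behavior_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  num <- trials$task == "numerical_operation"
  chosen <- integer(n)

  if (any(num)) {
    tg <- trials$target_numerosity[num]
    sig <- model$sigma_intercept + model$sigma_slope * tg
    chosen[num] <- pmin(6L, pmax(0L, as.integer(round(rnorm(sum(num), tg, sig)))))
  }
  if (any(!num)) {
    dir <- ifelse(trials$instruction[!num] == "plus", 1L, -1L)
    flip <- runif(sum(!num)) < model$lapse
    dir[flip] <- -dir[flip]
    chosen[!num] <- pmin(6L, pmax(0L, trials$preoperational_numerosity[!num] + dir))
  }

  preop <- trials$preoperational_numerosity
  delta <- chosen - preop
  inc_dev <- ifelse(trials$rule == "rule1", "L", "R")
  dec_dev <- ifelse(trials$rule == "rule1", "R", "L")
  trials$actions <- vapply(seq_len(n), function(i) {
    if (delta[i] > 0) strrep(inc_dev[i], delta[i])
    else if (delta[i] < 0) strrep(dec_dev[i], -delta[i])
    else ""
  }, character(1))
  trials$chosen_numerosity <- chosen
  trials$correct <- ifelse(num, chosen == trials$target_numerosity,
                           ifelse(trials$instruction == "plus",
                                  chosen > preop, chosen < preop))

  # executed operation / hand for the RT congruency effect
  op <- ifelse(delta > 0, "addition", ifelse(delta < 0, "subtraction", NA))
  first_dev <- substr(trials$actions, 1, 1)
  hand_used <- ifelse(first_dev == "L", "left",
                      ifelse(first_dev == "R", "right", NA))
  congruent <- !is.na(op) & !is.na(hand_used) &
    ((op == "addition" & hand_used == "right") |
       (op == "subtraction" & hand_used == "left"))
  rt <- rnorm(n, model$rt_mean_ms, model$rt_sd_ms) -
    ifelse(congruent, model$snarc_advantage_ms, 0)
  trials$reaction_time_ms <- pmax(50, rt)
  trials
}

#' Planted selectivity profile of one synthetic cell
#'
#' Firing rate in each 100 ms bin of the concern period is
#' `max(0, baseline * (1 + sum_f gain_f * sign_f(trial)))` over the factors
#' whose temporal window covers the bin, where `sign_f(trial)` is +1 when the
#' trial is at the factor's positive level (addition / right hand / one step /
#' standard stimulus) and -1 otherwise. A signed `gain` therefore encodes both
#' effect size and preferred level. Coding transitions (e.g. arithmetic early,
#' hand late) are expressed through per-factor windows.
#'
#' @param cell_id Identifier.
#' @param baseline_rate Baseline firing rate, spikes/s (> 0).
#' @param effects Named list over factors `arithmetic`, `hand`, `step`,
#'   `stimulus_type`; each element `list(gain = <signed fraction>,`
#'   `window = c(onset_ms, offset_ms))` within the 0-2400 ms concern period.
#' @param instructed_arithmetic Does the arithmetic effect follow the
#'   instruction in the instructed task? `FALSE` plants a "comparison-only"
#'   cell that fails the instructed-task filter.
#' @param category Ground-truth category label carried through to recovery
#'   tests.
#' @return An object of class `cell_profile`.
#' @export
cell_profile <- function(cell_id, baseline_rate = 10, effects = list(),
                         instructed_arithmetic = TRUE,
                         category = "unselective") {
  stopifnot(baseline_rate > 0)
  for (f in names(effects)) {
    stopifnot(f %in% .FACTORS, length(effects[[f]]$window) == 2)
  }
  structure(list(cell_id = cell_id, baseline_rate = baseline_rate,
                 effects = effects,
                 instructed_arithmetic = instructed_arithmetic,
                 category = category),
            class = "cell_profile")
}

# trial sign matrix: +1 positive level, -1 other level, 0 unlabelled
.trial_signs <- function(trials) {
  s <- matrix(0, nrow(trials), length(.FACTORS),
              dimnames = list(NULL, .FACTORS))
  for (f in .FACTORS) {
    lev <- trials[[f]]
    s[, f] <- ifelse(is.na(lev), 0, ifelse(lev == .POSITIVE_LEVEL[f], 1, -1))
  }
  s
}

#' Evaluate a cell's planted rate over the concern period
#'
#' @param profile A [cell_profile()].
#' @param trials Labelled trial data.frame (columns `arithmetic`, `hand`,
#'   `step`, `stimulus_type`; see [derive_labels()]).
#' @param instructed Apply instructed-task semantics (arithmetic effect only
#'   for cells with `instructed_arithmetic = TRUE`).
#' @return A trials x 24 matrix of rates (spikes/s).
#' @export
simulate_cell_rates <- function(profile, trials, instructed = FALSE) {
  tl <- event_timeline()
  signs <- .trial_signs(trials)
  bin_start <- (seq_len(tl$n_bins) - 1L) * tl$bin_width_ms
  mod <- matrix(0, nrow(trials), tl$n_bins)
  for (f in names(profile$effects)) {
    if (instructed && f == "arithmetic" && !profile$instructed_arithmetic) next
    eff <- profile$effects[[f]]
    active <- bin_start >= eff$window[1] & bin_start < eff$window[2]
    if (any(active))
      mod[, active] <- mod[, active] + eff$gain * signs[, f]
  }
  rates <- pmax(profile$baseline_rate * (1 + mod), 0)
  if (all(rates == 0))
    stop("invalid profile: planted gains drive the mean rate to zero")
  rates
}

#' Population composition specification
#'
#' Category fractions parameterise the planted population. Categories:
#' `arithmetic_only` (arithmetic coding in the preoperational window),
#' `arith_hand` (simultaneous arithmetic and hand coding over overlapping
#' windows, sign-coupled addition-to-right-hand for a `snarc_fraction` of
#' cells), `arith_to_hand` and `arith_to_step` (transition cells whose
#' arithmetic code gives way to hand or step coding later in the trial),
#' `comparison_only` (arithmetic coding in the numerical task that does not
#' follow the instruction), `hand_only`, `step_only`; the remainder is
#' unselective. Fractions must sum to at most 1.
#'
#' @param n_cells Population size (study scale: 539).
#' @param fractions Named category fractions.
#' @param gain Absolute planted gain (fraction of baseline), default 0.5.
#' @param baseline_rate Baseline rate, spikes/s, default 10.
#' @param snarc_fraction Fraction of hand-coding arithmetic cells whose hand
#'   sign matches their arithmetic sign under the addition-right convention.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 539,
                            fractions = c(arithmetic_only = 0.08,
                                          arith_hand = 0.05,
                                          arith_to_hand = 0.06,
                                          arith_to_step = 0.04,
                                          comparison_only = 0.13,
                                          hand_only = 0.10,
                                          step_only = 0.16),
                            gain = 0.5, baseline_rate = 10,
                            snarc_fraction = 0.8) {
  stopifnot(sum(fractions) <= 1, n_cells >= 1, gain >= 0)
  structure(list(n_cells = n_cells, fractions = fractions, gain = gain,
                 baseline_rate = baseline_rate,
                 snarc_fraction = snarc_fraction),
            class = "population_spec")
}

# planted factor windows (ms within the concern period)
.WINDOWS <- list(
  arith_preop = c(100, 1000),    # arithmetic code during preop presentation
  arith_sustained = c(100, 1700),# sustained arithmetic code (simultaneous coders)
  hand_simultaneous = c(100, 2100),
  hand_late = c(1400, 2100),     # hand code emerging before/through operation
  step_late = c(2100, 2400)      # step code at the end of the operation period
)

# deterministic (given RNG state) profile construction from a spec
.build_profiles <- function(spec) {
  counts <- round(spec$fractions * spec$n_cells)
  categories <- c(rep(names(counts), counts),
                  rep("unselective", spec$n_cells - sum(counts)))
  g <- spec$gain
  W <- .WINDOWS
  lapply(seq_len(spec$n_cells), function(i) {
    cat <- categories[i]
    sa <- sample(c(-1, 1), 1)            # arithmetic sign (+ = addition)
    coupled <- runif(1) < spec$snarc_fraction
    sh <- if (coupled) sa else sample(c(-1, 1), 1)
    ss <- sample(c(-1, 1), 1)
    eff <- switch(cat,
      arithmetic_only = list(arithmetic = list(gain = g * sa,
                                               window = W$arith_preop)),
      arith_hand = list(arithmetic = list(gain = g * sa,
                                          window = W$arith_sustained),
                        hand = list(gain = g * sh,
                                    window = W$hand_simultaneous)),
      arith_to_hand = list(arithmetic = list(gain = g * sa,
                                             window = W$arith_preop),
                           hand = list(gain = g * sh,
                                       window = W$hand_late)),
      arith_to_step = list(arithmetic = list(gain = g * sa,
                                             window = W$arith_preop),
                           step = list(gain = g * ss,
                                       window = W$step_late)),
      comparison_only = list(arithmetic = list(gain = g * sa,
                                               window = W$arith_preop)),
      hand_only = list(hand = list(gain = g * sh, window = W$hand_late)),
      step_only = list(step = list(gain = g * ss, window = W$step_late)),
      unselective = list()
    )
    cell_profile(cell_id = i, baseline_rate = spec$baseline_rate,
                 effects = eff,
                 instructed_arithmetic = cat != "comparison_only",
                 category = cat)
  })
}

.ground_truth_table <- function(profiles) {
  gt <- do.call(rbind, lapply(profiles, function(p) {
    gains <- setNames(numeric(length(.FACTORS)), .FACTORS)
    for (f in names(p$effects)) gains[f] <- p$effects[[f]]$gain
    data.frame(cell_id = p$cell_id, category = p$category,
               baseline_rate = p$baseline_rate,
               arithmetic_gain = gains["arithmetic"], hand_gain = gains["hand"],
               step_gain = gains["step"],
               stimulus_gain = gains["stimulus_type"],
               instructed_arithmetic = p$instructed_arithmetic,
               stringsAsFactors = FALSE)
  }))
  rownames(gt) <- NULL
  gt
}

#' Simulate binned spike counts for a planted population
#'
#' Counts per cell, trial and 100 ms bin are Poisson with mean
#' `rate * 0.1 s`, the rate coming from each cell's planted profile.
#'
#' @param profiles A list of [cell_profile()]s, or a [population_spec()] (in
#'   which case profiles are drawn from it).
#' @param trials Labelled trial data.frame.
#' @param seed Optional RNG seed; identical seeds give identical counts.
#' @param instructed Instructed-task semantics, see [simulate_cell_rates()].
#' @return A list with `pop` (a [binned_population()]), `ground_truth`
#'   (per-cell planted category and gains) and `profiles`.
#' @export
simulate_population_spikes <- function(profiles, trials, seed = NULL,
                                       instructed = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(profiles, "population_spec")) profiles <- .build_profiles(profiles)
  tl <- event_timeline()
  n_cells <- length(profiles)
  counts <- array(0L, dim = c(n_cells, nrow(trials), tl$n_bins))
  for (i in seq_len(n_cells)) {
    rates <- simulate_cell_rates(profiles[[i]], trials, instructed = instructed)
    counts[i, , ] <- rpois(length(rates), rates * tl$bin_width_ms / 1000)
  }
  pop <- binned_population(counts, trials,
                           alignment = if (instructed) "instruction_onset"
                                       else "preop_onset|go_spliced")
  list(pop = pop, ground_truth = .ground_truth_table(profiles),
       profiles = profiles)
}

#' Build a complete synthetic fixture dataset
#'
#' Presets plant qualitatively different populations:
#' \describe{
#'   \item{study_like}{539 cells (by default) with the full category mixture of
#'     [population_spec()]: arithmetic, hand and step coders, simultaneous
#'     arithmetic+hand coders, arithmetic-to-hand/step transition cells, and
#'     comparison-only cells that fail the instructed-task filter.}
#'   \item{null}{no planted effects (calibration preset; default 200 cells).}
#'   \item{snarc_reuse}{every cell carries an arithmetic code over the
#'     preoperational and delay-2 bins that is re-expressed, with matched sign
#'     under the addition-right convention, as a hand code over the operation
#'     bins (default 72 cells).}
#'   \item{static_code}{a constant arithmetic code across all 24 bins.}
#'   \item{uncoupled}{as `snarc_reuse` but with exactly half the cells
#'     congruent (addition-right) and half incongruent, so the population
#'     carries no net arithmetic-hand coupling (control for the coupling).}
#' }
#'
#' @param preset Preset name.
#' @param seed RNG seed governing trials, choices and spikes.
#' @param n_cells Population size override (default: preset-specific).
#' @param n_trials Numerical-task trial count before filtering (default 1000;
#'   instructed task gets half).
#' @param gain,baseline_rate Effect size and baseline overrides.
#' @param dir Optional directory: when given, all dataset files are written
#'   there via [save_dataset()].
#' @return A list with labelled, analysis-filtered `trials` and
#'   `trials_instructed` (the unfiltered tables, for behavioural statistics,
#'   as `trials_all` / `trials_instructed_all`), the matching
#'   [binned_population()]s `pop` and `pop_instructed`, `ground_truth`,
#'   `profiles` and `preset`.
#' @export
make_fixture_dataset <- function(preset = c("study_like", "null",
                                            "snarc_reuse", "static_code",
                                            "uncoupled"),
                                 seed = 1, n_cells = NULL, n_trials = 1000,
                                 gain = 0.5, baseline_rate = 10, dir = NULL) {
  preset <- match.arg(preset)
  set.seed(seed)
  tl <- event_timeline()
  full <- c(0, tl$concern_ms)

  spec_or_profiles <- switch(preset,
    study_like = population_spec(n_cells = n_cells %||% 539, gain = gain,
                                 baseline_rate = baseline_rate),
    null = population_spec(n_cells = n_cells %||% 200,
                           fractions = c(arithmetic_only = 0), gain = 0,
                           baseline_rate = baseline_rate),
    snarc_reuse = ,
    uncoupled = ,
    static_code = {
      nc <- n_cells %||% 72
      # uncoupled control: exactly balanced congruency, so no residual
      # arithmetic-hand sign overlap survives in a finite population
      congr <- if (preset == "uncoupled")
        sample(rep(c(1, -1), length.out = nc)) else rep(1, nc)
      lapply(seq_len(nc), function(i) {
        sa <- sample(c(-1, 1), 1)
        sh <- sa * congr[i]
        eff <- if (preset == "static_code")
          list(arithmetic = list(gain = gain * sa, window = full))
        else
          list(arithmetic = list(gain = gain * sa, window = c(0, tl$go_ms)),
               hand = list(gain = gain * sh,
                           window = c(tl$go_ms, tl$concern_ms)))
        cell_profile(i, baseline_rate = baseline_rate, effects = eff,
                     category = switch(preset, static_code = "static_arithmetic",
                                       snarc_reuse = "snarc_reuse",
                                       uncoupled = "uncoupled"))
      })
    })

  trials_all <- generate_task_trials("numerical_operation", n_trials)
  trials_all <- derive_labels(simulate_choices(trials_all))
  trials <- suppressMessages(filter_analysis_trials(trials_all))
  trials <- trials[trials$valid, , drop = FALSE]

  trials_ins_all <- generate_task_trials("instructed", max(50, n_trials %/% 2))
  trials_ins_all <- derive_labels(simulate_choices(trials_ins_all))
  trials_ins <- suppressMessages(filter_analysis_trials(trials_ins_all))
  trials_ins <- trials_ins[trials_ins$valid, , drop = FALSE]

  sim <- simulate_population_spikes(spec_or_profiles, trials)
  sim_ins <- simulate_population_spikes(sim$profiles, trials_ins,
                                        instructed = TRUE)

  out <- list(preset = preset, seed = seed, trials = trials,
              trials_all = trials_all, trials_instructed = trials_ins,
              trials_instructed_all = trials_ins_all, pop = sim$pop,
              pop_instructed = sim_ins$pop, ground_truth = sim$ground_truth,
              profiles = sim$profiles)
  if (!is.null(dir)) save_dataset(out, dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
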