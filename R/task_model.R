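# Trial data model for the two numerical operation tasks.
#
# A trial table is an ordinary data.frame, one row per trial, with the columns
# documented in `validate_trials()`. Device actions are encoded as a string
# over {L, R} in execution order; event times are integer milliseconds from
# trial start.

#' Task event timeline
#'
#' Fixed epoch durations of both tasks: fixation 800 ms, target (or
#' pre-instruction) cue 700 ms, delay 1 1000 ms, preoperational numerosity (or
#' instruction) 700 ms, delay 2 1000 ms, then the Go signal. The analysis epoch
#' of interest (the "concern period") runs from preoperational-numerosity onset
#' to 700 ms after the Go signal: 2400 ms, i.e. 24 bins of 100 ms. Within that
#' epoch the Go signal falls at 1700 ms.
#'
#' @return A list with epoch durations (ms), the concern-period length,
#'   bin width, number of bins, and per-period bin indices (1-based):
#'   preoperational bins 1-7, delay-2 bins 8-17, operation bins 18-24.
#' @export
#' @examples
#' event_timeline()$n_bins
event_timeline <- function() {
  tl <- list(
    fixation_ms = 800, target_on_ms = 700, delay1_ms = 1000,
    preop_on_ms = 700, delay2_ms = 1000, operation_window_ms = 700,
    bin_width_ms = 100
  )
  tl$concern_ms <- tl$preop_on_ms + tl$delay2_ms + tl$operation_window_ms
  tl$go_ms <- tl$preop_on_ms + tl$delay2_ms      # Go at 1700 ms into the epoch
  tl$n_bins <- tl$concern_ms %/% tl$bin_width_ms # 24
  tl$periods <- list(
    preoperational = 1:7,
    delay2 = 8:17,
    operation = 18:24
  )
  tl
}

#' Device required for an operation under a rule
#'
#' Under rule 1 the left device increments the displayed numerosity by one and
#' the right device decrements it; rule 2 reverses the device-operation
#' mapping. Hence rule 1 demands the left hand for addition and the right hand
#' for subtraction, and flipping the rule flips the hand.
#'
#' @param arithmetic `"addition"` or `"subtraction"` (vectorised).
#' @param rule `"rule1"` or `"rule2"` (vectorised).
#' @return Character vector, `"left"` or `"right"`.
#' @export
#' @examples
#' required_hand("addition", "rule1")  # "left"
required_hand <- function(arithmetic, rule) {
  stopifnot(all(arithmetic %in% c("addition", "subtraction")),
            all(rule %in% c("rule1", "rule2")))
  add_left <- rule == "rule1"
  is_add <- arithmetic == "addition"
  ifelse(is_add == add_left, "left", "right")
}

#' Numerosity increment of one device use
#'
#' @param device `"L"` or `"R"` (vectorised).
#' @param rule `"rule1"` or `"rule2"`.
#' @return Integer vector of +1 / -1.
#' @export
device_increment <- function(device, rule) {
  stopifnot(all(device %in% c("L", "R")), all(rule %in% c("rule1", "rule2")))
  ifelse((device == "L") == (rule == "rule1"), 1L, -1L)
}

#' Replay a trial's device actions
#'
#' Applies the actions string to the preoperational numerosity under the
#' trial's rule and returns the final displayed numerosity. Used as the
#' round-trip check that `chosen_numerosity` is consistent with the recorded
#' actions.
#'
#' @param actions Character vector of strings over `{L, R}` (may be `""`).
#' @param preop Integer starting numerosities.
#' @param rule Rules, recycled as needed.
#' @return Integer vector of final numerosities.
#' @export
replay_actions <- function(actions, preop, rule) {
  n <- max(length(actions), length(preop), length(rule))
  actions <- rep_len(actions, n); preop <- rep_len(preop, n)
  rule <- rep_len(rule, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    devs <- strsplit(actions[i], "")[[1]]
    out[i] <- preop[i] +
      if (length(devs)) sum(device_increment(devs, rule[i])) else 0L
  }
  out
}

#' Enumerate task conditions
#'
#' For the numerical operation task, the default condition set is every
#' (target, preoperational) pair with target 1-4, preoperational 0-6 and
#' |target - preop| within `delta_range`. The default `delta_range = 0:2`
#' yields the 19 pairs used during recording: 15 one- and two-step pairs plus
#' the four matched ("hold") pairs in which the preoperational numerosity
#' already equals the target and must simply be maintained. For the instructed
#' task, the 6 combinations of instruction (+/-) by preoperational numerosity
#' (1-3).
#'
#' @param task `"numerical_operation"` or `"instructed"`.
#' @param delta_range Allowed |target - preop| values (numerical task only).
#' @return A data.frame of condition records.
#' @export
#' @examples
#' nrow(enumerate_conditions("numerical_operation"))  # 19
enumerate_conditions <- function(task = c("numerical_operation", "instructed"),
                                 delta_range = 0:2) {
  task <- match.arg(task)
  if (task == "numerical_operation") {
    grid <- expand.grid(target_numerosity = 1:4, preoperational_numerosity = 0:6)
    grid <- grid[abs(grid$target_numerosity - grid$preoperational_numerosity)
                 %in% delta_range, , drop = FALSE]
    grid <- grid[order(grid$target_numerosity, grid$preoperational_numerosity), ]
    rownames(grid) <- NULL
    grid
  } else {
    grid <- expand.grid(instruction = c("plus", "minus"),
                        preoperational_numerosity = 1:3,
                        stringsAsFactors = FALSE)
    grid[order(grid$instruction, grid$preoperational_numerosity), c(1, 2)]
  }
}

.TRIAL_COLUMNS <- c(
  "trial_id", "task", "rule", "target_numerosity",
  "preoperational_numerosity", "instruction", "stimulus_type", "actions",
  "chosen_numerosity", "correct", "reaction_time_ms"
)

#' Validate a trial table
#'
#' Checks column presence, enum levels, the action alphabet, and the
#' action-replay invariant (replaying `actions` from the preoperational
#' numerosity under the trial's rule must reproduce `chosen_numerosity`).
#'
#' @param trials A trial data.frame.
#' @param check_replay Verify the action-replay round trip (default `TRUE`).
#' @return `trials`, invisibly; stops with a row-indexed message on violation.
#' @export
validate_trials <- function(trials, check_replay = TRUE) {
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!grepl("^[LR]*$", trials$actions))
  if (length(bad))
    stop("malformed actions string at row(s) ", paste(head(bad, 5), collapse = ", "))
  if (!all(trials$task %in% c("numerical_operation", "instructed")))
    stop("unknown task label")
  if (!all(trials$rule %in% c("rule1", "rule2")))
    stop("unknown rule label")
  if (!all(trials$stimulus_type %in% c("standard", "control")))
    stop("unknown stimulus_type label")
  num <- trials$task == "numerical_operation"
  if (any(num & !is.na(trials$instruction) & trials$instruction != "none"))
    stop("numerical_operation trials must have instruction = 'none'")
  if (any(!num & (is.na(trials$instruction) |
                  !trials$instruction %in% c("plus", "minus"))))
    stop("instructed trials must have instruction 'plus' or 'minus'")
  if (any(num & is.na(trials$target_numerosity)))
    stop("numerical_operation trials must have a target numerosity")
  if (check_replay && !all(is.na(trials$chosen_numerosity))) {
    done <- !is.na(trials$chosen_numerosity)
    replayed <- replay_actions(trials$actions[done],
                               trials$preoperational_numerosity[done],
                               trials$rule[done])
    bad <- which(replayed != trials$chosen_numerosity[done])
    if (length(bad))
      stop("action replay does not reproduce chosen_numerosity at row(s) ",
           paste(head(which(done)[bad], 5), collapse = ", "))
  }
  invisible(trials)
}

#' Derive operation labels for each trial
#'
#' Labels every trial with the three analysed factors: arithmetic (addition
#' vs subtraction), hand (the device the current rule requires for that
#' operation) and step (one vs two). For the numerical operation task the
#' arithmetic label is the sign of target minus preoperational numerosity and
#' the step label is their absolute difference; matched-numerosity hold trials
#' (difference 0) and steps outside {1, 2} are marked invalid. For the
#' instructed task the arithmetic label follows the instruction and the step
#' label is the number of executed device uses; trials with more than one
#' action are marked invalid.
#'
#' @param trials A trial data.frame.
#' @return `trials` with columns `arithmetic`, `hand`, `step`
#'   (`"one"`/`"two"`) and `valid` appended.
#' @export
derive_labels <- function(trials) {
  n <- nrow(trials)
  arithmetic <- rep(NA_character_, n)
  step_n <- rep(NA_integer_, n)
  num <- trials$task == "numerical_operation"

  d <- trials$target_numerosity - trials$preoperational_numerosity
  arithmetic[num] <- ifelse(d[num] > 0, "addition",
                            ifelse(d[num] < 0, "subtraction", NA))
  step_n[num] <- abs(d[num])

  ins <- !num
  arithmetic[ins] <- ifelse(trials$instruction[ins] == "plus",
                            "addition", "subtraction")
  step_n[ins] <- nchar(trials$actions[ins])

  valid <- !is.na(arithmetic) & step_n %in% c(1L, 2L)
  hand <- rep(NA_character_, n)
  hand[valid] <- required_hand(arithmetic[valid], trials$rule[valid])
  step <- ifelse(step_n == 1L, "one", ifelse(step_n == 2L, "two", NA))
  step[!valid] <- NA

  trials$arithmetic <- arithmetic
  trials$hand <- hand
  trials$step <- step
  trials$valid <- valid
  trials
}

#' Filter trials for analysis
#'
#' Retains correct trials executed with the minimum number of steps: for the
#' numerical operation task the action count must equal |target - preop| (so
#' trials with switching behaviour are dropped); for the instructed task
#' exactly one action. Optionally drops trials with extreme preoperational
#' numerosities (0, 5, 6), whose correct operation is forced. Input order is
#' preserved and the filter is idempotent.
#'
#' @param trials A trial data.frame with outcomes filled in.
#' @param exclude_extremes Drop preoperational numerosities 0, 5 and 6.
#' @return The retained trials; the number dropped is reported via `message()`.
#' @export
filter_analysis_trials <- function(trials, exclude_extremes = FALSE) {
  num <- trials$task == "numerical_operation"
  min_steps <- ifelse(num,
                      abs(trials$target_numerosity -
                            trials$preoperational_numerosity),
                      1L)
  keep <- !is.na(trials$correct) & trials$correct &
    nchar(trials$actions) == min_steps
  if (exclude_extremes)
    keep <- keep & !(trials$preoperational_numerosity %in% c(0L, 5L, 6L))
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " trial(s) dropped by analysis filter")
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
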