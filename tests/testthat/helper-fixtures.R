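# Shared synthetic fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# mid-sized mixed population for encoding/ROC recovery checks
fx_study_small <- function() cached_fixture("study_small", function()
  make_fixture_dataset("study_like", seed = 42, n_cells = 120,
                       n_trials = 1000))

# null population for calibration checks
fx_null <- function() cached_fixture("null", function()
  make_fixture_dataset("null", seed = 99, n_cells = 200, n_trials = 1200))

# small dynamic-reuse population for decoding checks
fx_snarc <- function() cached_fixture("snarc", function()
  make_fixture_dataset("snarc_reuse", seed = 7, n_cells = 36,
                       n_trials = 1200))

# balanced 2x2x2x2 labelled trial table (n_rep per condition), no noise hooks
balanced_label_trials <- function(n_rep = 5) {
  g <- expand.grid(arithmetic = c("addition", "subtraction"),
                   hand = c("left", "right"), step = c("one", "two"),
                   stimulus_type = c("standard", "control"),
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  g$task <- "numerical_operation"
  g$valid <- TRUE
  g
}
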