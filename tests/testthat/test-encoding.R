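# Binwise regression, coding histories, the instructed filter, categories.

# build a noiseless binned population whose counts equal rate * 0.1 exactly
noiseless_population <- function(profiles, trials) {
  counts <- array(0, dim = c(length(profiles), nrow(trials), 24))
  for (i in seq_along(profiles))
    counts[i, , ] <- simulate_cell_rates(profiles[[i]], trials) * 0.1
  binned_population(counts, trials)
}

# fake regression object from a cells x bins x factors flag array
flags_to_reg <- function(flags) {
  structure(list(flags = flags, bins = seq_len(dim(flags)[2]),
                 factors = dimnames(flags)[[3]],
                 cell_ids = seq_len(dim(flags)[1])),
            class = "bin_regression")
}

test_that("regression coefficients on noiseless rates equal direct mean contrasts", {
  trials <- balanced_label_trials(5)
  prof <- list(
    cell_profile(1, 10, list(arithmetic = list(gain = 0.5,
                                               window = c(0, 700)))),
    cell_profile(2, 20, list(hand = list(gain = 0.25,
                                         window = c(1700, 2400)))),
    cell_profile(3, 10)
  )
  pop <- noiseless_population(prof, trials)
  reg <- binwise_regression(pop)
  # independent oracle: difference of class means of the planted rates
  rates1 <- simulate_cell_rates(prof[[1]], trials)
  add <- trials$arithmetic == "addition"
  contrast <- colMeans(rates1[add, ]) - colMeans(rates1[!add, ])
  expect_equal(unname(reg$coef[1, , "arithmetic"]), unname(contrast),
               tolerance = 1e-8)
  expect_equal(unname(reg$coef[2, 18, "hand"]), 2 * 0.25 * 20,
               tolerance = 1e-8)
  expect_equal(unname(reg$coef[2, 5, "hand"]), 0, tolerance = 1e-8)
  # constant cell: all factor coefficients zero, nothing significant
  expect_true(all(abs(reg$coef[3, , c("arithmetic", "hand", "step",
                                      "stimulus_type")]) < 1e-8))
  expect_false(any(reg$flags[3, , ], na.rm = TRUE))
})

test_that("binwise regression detects planted effects and holds its alpha on nulls", {
  pl <- fx_study_small()
  reg <- binwise_regression(pl$pop, bins = 1:7)
  gt <- pl$ground_truth
  arith_cells <- which(gt$arithmetic_gain != 0)
  hit <- apply(reg$flags[arith_cells, , "arithmetic", drop = FALSE], 1,
               any, na.rm = TRUE)
  expect_gte(mean(hit), 0.9)
  # alpha calibration on the null preset, all bins and factors
  nul <- fx_null()
  regn <- binwise_regression(nul$pop)
  rate <- mean(regn$flags, na.rm = TRUE)
  n_tests <- sum(!is.na(regn$flags))
  ci <- 2.58 * sqrt(0.01 * 0.99 / n_tests)
  expect_lt(abs(rate - 0.01), ci + 1e-9)
})

test_that("coding histories follow the any-bin rule and accumulate monotonely", {
  flags <- array(FALSE, dim = c(3, 24, 3),
                 dimnames = list(NULL, NULL, c("arithmetic", "hand", "step")))
  flags[1, 4, "arithmetic"] <- TRUE                   # one bin is enough
  flags[2, 2, "arithmetic"] <- TRUE
  flags[2, 20, "hand"] <- TRUE                        # later transition
  hist <- build_coding_history(flags_to_reg(flags))
  expect_true(hist$per_period[1, "preoperational", "arithmetic"])
  expect_false(hist$per_period[1, "operation", "arithmetic"])
  expect_true(hist$cumulative[1, "operation", "arithmetic"])  # carried forward
  expect_true(hist$cumulative[2, "operation", "hand"])
  expect_false(hist$per_period[2, "preoperational", "hand"])
  expect_false(any(hist$cumulative[3, , ]))           # empty history
  # monotone non-decreasing across periods
  expect_true(all(hist$cumulative[, 3, ] >= hist$cumulative[, 1, ]))
})

test_that("instructed-task filter keeps true arithmetic cells, drops comparison-only ones", {
  pl <- fx_study_small()
  pass <- instructed_task_filter(pl$pop_instructed)
  gt <- pl$ground_truth
  true_arith <- gt$category %in% c("arithmetic_only", "arith_hand",
                                   "arith_to_hand", "arith_to_step")
  expect_gte(mean(pass[true_arith], na.rm = TRUE), 0.9)
  comparison <- gt$category == "comparison_only"
  expect_lte(mean(pass[comparison], na.rm = TRUE), 0.15)
  # null cells pass at roughly the 1 - 0.99^7 family-wise alpha
  nul <- fx_null()
  pass0 <- instructed_task_filter(nul$pop_instructed)
  expected <- 1 - 0.99^7
  ci <- 2.58 * sqrt(expected * (1 - expected) / length(pass0))
  expect_lt(abs(mean(pass0) - expected), ci + 0.01)
})

test_that("categorisation counts overlaps and recovers the planted composition", {
  flags <- array(FALSE, dim = c(2, 24, 3),
                 dimnames = list(NULL, NULL, c("arithmetic", "hand", "step")))
  flags[1, 3, "arithmetic"] <- TRUE
  flags[1, 5, "hand"] <- TRUE                         # overlap within preop
  hist <- build_coding_history(flags_to_reg(flags))
  cat <- categorize_cells(hist)
  expect_true(cat$arithmetic_related[1] && cat$hand_related[1])
  expect_equal(unname(attr(cat, "counts")["arithmetic_related"]), 1)
  # full recovery on the planted mixed population
  pl <- fx_study_small()
  enc <- encoding_stage(pl$pop, pl$pop_instructed)
  gt_arith <- pl$ground_truth$category %in%
    c("arithmetic_only", "arith_hand", "arith_to_hand", "arith_to_step")
  sel <- enc$categories$arithmetic_selective
  expect_gte(sum(sel & gt_arith) / sum(gt_arith), 0.9)       # sensitivity
  expect_lte(sum(sel & !gt_arith) / max(1, sum(sel)), 0.1)   # FDR
})

test_that("exclusive-arithmetic tracking distinguishes static from dynamic coding", {
  # constructed: cell 1 transitions arithmetic -> hand, cell 2 stays exclusive
  flags <- array(FALSE, dim = c(2, 24, 3),
                 dimnames = list(NULL, NULL, c("arithmetic", "hand", "step")))
  flags[1:2, 3, "arithmetic"] <- TRUE
  flags[1, 20, "hand"] <- TRUE
  hist <- build_coding_history(flags_to_reg(flags))
  trk <- period_selectivity_tracking(hist, 1:2)
  expect_equal(trk$fraction_from, 1)
  expect_equal(trk$fraction_to, 0.5)
  expect_equal(trk$b, 1); expect_equal(trk$c, 0)
  # static coding preset: no planted transitions, so exclusivity is lost only
  # at the alpha-level false-flag rate of the 34 post-preop bin tests
  st <- make_fixture_dataset("static_code", seed = 12, n_cells = 60,
                             n_trials = 800)
  enc <- encoding_stage(st$pop, st$pop_instructed)
  trk <- enc$tracking
  expect_gt(trk$fraction_from, 0.75)
  p_chance_loss <- 1 - 0.99^34
  n_from <- round(trk$fraction_from * trk$n)
  ci <- 2.58 * sqrt(p_chance_loss * (1 - p_chance_loss) * n_from)
  expect_lt(abs(trk$b - n_from * p_chance_loss), ci + 1)
  expect_lte(trk$c, 2)
  # the dynamic population, by contrast, loses most of its exclusive coders
  pl <- fx_study_small()
  encd <- encoding_stage(pl$pop, pl$pop_instructed)
  expect_lt(encd$tracking$fraction_to / encd$tracking$fraction_from, 0.55)
  expect_lt(encd$tracking$p_value, 0.01)
})

test_that("spike binning is half-open, go-spliced and count-conserving", {
  tr <- generate_task_trials("numerical_operation", 2, seed = 1)
  on <- tr$t_preop_on[1]; go <- tr$t_go[1]
  spikes <- list(list(c(on + 99.9, on + 100.0, go + 0.0, go + 699.9),
                      numeric(0)))
  pop <- bin_spike_counts(spikes, tr)
  expect_equal(pop$counts[1, 1, 1], 1)      # 99.9 ms -> first bin
  expect_equal(pop$counts[1, 1, 2], 1)      # 100.0 ms -> second bin
  expect_equal(pop$counts[1, 1, 18], 1)     # go onset -> first operation bin
  expect_equal(pop$counts[1, 1, 24], 1)     # end of operation window
  # conservation: uniformly scattered spikes are each counted exactly once
  set.seed(2)
  st <- sort(runif(200, on, on + 2400 - 1e-6))
  pop2 <- bin_spike_counts(list(list(st, numeric(0))), tr)
  expect_equal(sum(pop2$counts), 200)
  # trials without alignment events are dropped with a warning
  tr$t_go[2] <- NA
  expect_warning(pop3 <- bin_spike_counts(spikes, tr), "alignment")
  expect_equal(dim(pop3$counts)[2], 1)
})
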