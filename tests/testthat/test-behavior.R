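# Behavioural statistics: exact tests, tuning fits, size effect, RT contrast.

test_that("binomial tail test matches exhaustive mass summation and edge cases", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.99)
    oracle <- sum(dbinom(k:n, n, p))            # exhaustive summation
    expect_equal(binomial_tail_test(k, n, p), oracle, tolerance = 1e-12)
  }
  expect_equal(binomial_tail_test(0, 20, 0.3), 1.0)
  expect_error(binomial_tail_test(21, 20, 0.3))
})

test_that("McNemar exact test handles symmetric, one-sided and empty discordance", {
  expect_equal(mcnemar_consistency(5, 5), 1)
  expect_equal(mcnemar_consistency(10, 0), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(mcnemar_consistency(0, 0), 1)
  tab <- matrix(c(30, 10, 0, 25), 2, 2, byrow = TRUE)
  expect_equal(mcnemar_consistency(tab), 2 * 0.5^10, tolerance = 1e-12)
})

test_that("selection matrices count choices and always row-normalise", {
  tr <- data.frame(task = "numerical_operation", target_numerosity = 2L,
                   chosen_numerosity = c(2L, 2L, 3L, 1L))
  sel <- selection_rates(tr)
  expect_equal(as.numeric(sel$proportions[1, c("1", "2", "3")]),
               c(0.25, 0.5, 0.25))
  expect_error(selection_rates(tr[0, ]))
  big <- simulate_choices(generate_task_trials("numerical_operation", 2000,
                                               seed = 21))
  sel2 <- selection_rates(big)
  expect_true(all(abs(rowSums(sel2$proportions) - 1) < 1e-12))
})

test_that("Gaussian tuning fit is self-consistent and recovers planted sigma", {
  x <- 0:6
  y <- exp(-(x - 3)^2 / 2); y <- y / sum(y)     # discretised N(3, 1)
  sel <- list(proportions = matrix(y, 1, 7,
                                   dimnames = list(NULL, as.character(0:6))),
              n_trials = 100, conditions = "3", empty = FALSE)
  fit <- fit_gaussian_tuning(sel)
  expect_true(fit$converged)
  expect_equal(fit$sigma, 1, tolerance = 0.05)
  expect_equal(fit$mu, 3, tolerance = 0.05)
  # recovery of the planted size effect from simulated choices
  tr <- simulate_choices(generate_task_trials("numerical_operation", 2e4,
                                              seed = 31),
                         behavior_model(sigma_intercept = 0.4,
                                        sigma_slope = 0.2))
  fits <- fit_gaussian_tuning(selection_rates(tr))
  planted <- 0.4 + 0.2 * (1:4)
  expect_true(all(fits$converged))
  expect_true(all(abs(fits$sigma - planted) / planted < 0.2))
})

test_that("size-effect regression recovers exact lines and degenerates safely", {
  fit <- data.frame(condition = 1:4, sigma = c(0.5, 0.7, 0.9, 1.1),
                    converged = TRUE)
  res <- suppressWarnings(size_effect_regression(fit))  # exact fit warns
  expect_equal(res$slope, 0.2, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  flat <- data.frame(condition = 1:4, sigma = rep(0.8, 4), converged = TRUE)
  expect_equal(suppressWarnings(size_effect_regression(flat))$slope, 0,
               tolerance = 1e-10)
  one <- data.frame(condition = rep(2, 4), sigma = c(0.5, 0.7, 0.9, 1.1),
                    converged = TRUE)
  expect_error(size_effect_regression(one))
})

test_that("RT congruency contrast recovers the planted hand-operation coupling", {
  tr <- simulate_choices(generate_task_trials("numerical_operation", 4000,
                                              seed = 41),
                         behavior_model(snarc_advantage_ms = 30))
  tr <- derive_labels(tr)
  tr <- suppressMessages(filter_analysis_trials(tr))
  res <- rt_congruency_contrast(tr[tr$valid, ])
  expect_true(all(res$evaluable))
  # right hand faster for addition, left hand faster for subtraction
  expect_lt(res$rt_diff_ms[res$hand == "right"], 0)
  expect_gt(res$rt_diff_ms[res$hand == "left"], 0)
  expect_true(all(res$p_value < 0.05))
  # identical RT distributions give a zero contrast
  same <- data.frame(hand = rep(c("left", "right"), each = 20),
                     arithmetic = rep(c("addition", "subtraction"), 20),
                     reaction_time_ms = rep(300, 40))
  res0 <- rt_congruency_contrast(same)
  expect_true(all(res0$rt_diff_ms == 0))
})

test_that("full behavioural stage shows above-chance performance and a size effect", {
  tr <- simulate_choices(generate_task_trials("numerical_operation", 6000,
                                              seed = 51))
  tr_i <- simulate_choices(generate_task_trials("instructed", 2000,
                                                seed = 52))
  st <- behavior_stage(derive_labels(tr), derive_labels(tr_i))
  expect_true(all(st$performance$p_value < 0.01))
  expect_gt(st$size_effect$slope, 0)
  expect_lt(st$size_effect$p_value, 0.05)
  expect_true(all(st$performance_instructed$p_value < 0.01))
})
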