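# Pseudopopulation assembly, cross-temporal decoding, classifier reuse.

test_that("pseudopopulation enforces the 10-per-condition criterion and is reproducible", {
  sn <- fx_snarc()
  pp <- build_pseudopopulation(sn$pop, seed = 11)
  expect_equal(pp$n_pseudotrials, 160)
  expect_equal(length(unique(pp$labels$condition)), 16)
  expect_true(all(table(pp$labels$condition) == 10))
  pp2 <- build_pseudopopulation(sn$pop, seed = 11)
  expect_identical(pp$activity, pp2$activity)
  # a starved condition (below 10 trials but present) blocks assembly
  tr <- sn$pop$trials
  cond <- interaction(tr[c("target_numerosity", "arithmetic", "hand")],
                      drop = TRUE)
  victim <- names(which.min(table(cond)))
  drop_rows <- which(cond == victim)[-(1:5)]     # leave 5 trials
  starved <- binned_population(sn$pop$counts[, -drop_rows, , drop = FALSE],
                               tr[-drop_rows, ])
  expect_error(build_pseudopopulation(starved, seed = 1), "criterion")
})

test_that("cross-training grids have the exact 24/276/276 geometry", {
  sn <- fx_snarc()
  pp <- build_pseudopopulation(sn$pop, seed = 11)
  grid <- crosstemporal_decode(pp, "arithmetic", seed = 13)
  expect_equal(dim(grid$accuracy), c(24, 24))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  fake <- grid
  fake$mask <- matrix(FALSE, 24, 24)
  summ <- prospective_retrospective_summary(fake)
  expect_equal(summ$n_windows, c(24, 276, 276))
  expect_equal(sum(summ$n_windows), 576)
  expect_equal(summ$n_significant, c(0, 0, 0))
  expect_equal(summ$p_value, c(1, 1, 1))
  expect_error(prospective_retrospective_summary(grid), "mask")
})

test_that("a static code decodes across all window pairs, a dynamic one only in its window", {
  st <- make_fixture_dataset("static_code", seed = 17, n_cells = 24,
                             n_trials = 1200)
  pp <- build_pseudopopulation(st$pop, seed = 3)
  grid <- crosstemporal_decode(pp, "arithmetic", seed = 5)
  expect_gt(min(diag(grid$accuracy)), 0.85)
  expect_gt(min(grid$accuracy), 0.75)            # off-diagonal square region
  # the dynamic-reuse population decodes arithmetic only before the Go signal
  sn <- fx_snarc()
  ppd <- build_pseudopopulation(sn$pop, seed = 3)
  gd <- crosstemporal_decode(ppd, "arithmetic", seed = 5)
  expect_gt(mean(diag(gd$accuracy)[1:17]), 0.9)
  expect_lt(mean(diag(gd$accuracy)[18:24]), 0.62)
})

test_that("identity-mapped classifier reuse reproduces the source grid bit-for-bit", {
  sn <- fx_snarc()
  pp <- build_pseudopopulation(sn$pop, seed = 11)
  grid <- crosstemporal_decode(pp, "arithmetic", seed = 13)
  ident <- cross_operation_decode(pp, "arithmetic", "arithmetic",
                                  mapping = c(addition = "addition",
                                              subtraction = "subtraction"),
                                  grid = grid, n_perm = 0)
  expect_identical(ident$accuracy, grid$accuracy)
  # complementing the mapping reflects every accuracy about 0.5
  comp <- cross_operation_decode(pp, "arithmetic", "arithmetic",
                                 mapping = c(addition = "subtraction",
                                             subtraction = "addition"),
                                 grid = grid, n_perm = 0)
  expect_equal(comp$accuracy, 1 - grid$accuracy, tolerance = 1e-12)
  expect_error(cross_operation_decode(pp, "arithmetic", "hand",
                                      mapping = c(addition = "right",
                                                  subtraction = "right"),
                                      grid = grid, n_perm = 0),
               "bijection")
})

test_that("classifier reuse predicts future hand use in the dynamic-reuse population", {
  sn <- fx_snarc()
  pp <- build_pseudopopulation(sn$pop, seed = 11)
  grid <- crosstemporal_decode(pp, "arithmetic", seed = 13)
  xop <- cross_operation_decode(pp, "arithmetic", "hand", grid = grid,
                                n_perm = 500, seed = 15)
  summ <- prospective_retrospective_summary(xop)
  expect_lt(summ$p_value[summ$region == "prospective"], 0.01)
  expect_gt(summ$p_value[summ$region == "retrospective"], 0.05)
  expect_false(any(diag(xop$mask)))
})

test_that("shuffled labels decode at chance", {
  sn <- fx_snarc()
  pp <- build_pseudopopulation(sn$pop, seed = 11)
  nn <- shuffled_accuracy_null(pp, "arithmetic", train_bin = 8,
                               n_perm = 100, seed = 19)
  expect_lt(abs(nn$null_mean - 0.5), 0.02)
  expect_gt(nn$observed, 0.9)                    # the real labels do decode
})
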