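# ROC selectivity, population ellipses, relative variance, quadrant analysis.

# exhaustive pairwise AUC oracle
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

test_that("Mann-Whitney AUC equals exhaustive pair enumeration", {
  expect_equal(auc_mann_whitney(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc_mann_whitney(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_mann_whitney(c(2, 3), c(1, 3)), 0.625)
  set.seed(8)
  for (i in 1:200) {
    pos <- sample(0:5, sample(1:8, 1), replace = TRUE)   # ties likely
    neg <- sample(0:5, sample(1:8, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg), auc_oracle(pos, neg))
  }
  expect_error(auc_mann_whitney(numeric(0), 1:3))
})

test_that("ROC trajectories track planted windows and obey label-flip symmetry", {
  pl <- fx_study_small()
  gt <- pl$ground_truth
  cell <- which(gt$category == "arithmetic_only" & gt$arithmetic_gain > 0)[1]
  traj <- roc_trajectories(pl$pop, cells = cell)
  expect_true(all(traj$auc[1, "arithmetic", 2:9] > 0.55))   # planted window
  expect_lt(abs(mean(traj$auc[1, "arithmetic", 18:24]) - 0.5), 0.12)
  # complementing the class mapping reflects the AUC about 0.5
  flipped <- pl$pop
  flipped$trials$arithmetic <- ifelse(flipped$trials$arithmetic == "addition",
                                      "subtraction", "addition")
  traj_f <- roc_trajectories(flipped, cells = cell)
  expect_equal(traj_f$auc[1, "arithmetic", ],
               1 - traj$auc[1, "arithmetic", ], tolerance = 1e-12)
  # unselective population stays at 0.5 on average
  nul <- fx_null()
  traj0 <- roc_trajectories(nul$pop, cells = 1:50)
  expect_lt(abs(mean(traj0$auc[, "arithmetic", ]) - 0.5), 0.01)
})

test_that("confidence ellipses recover orientation, axis ratio and symmetry", {
  set.seed(3)
  pts <- MASS::mvrnorm(400, c(0.5, 0.5), diag(c(4, 1)), empirical = TRUE)
  e <- fit_confidence_ellipse(pts)
  expect_equal(e$theta_deg, 0, tolerance = 1e-6)
  expect_equal(e$axis_ratio, 2, tolerance = 1e-6)
  expect_equal(unname(e$radii[1]), sqrt(qchisq(0.95, 2) * 4),
               tolerance = 1e-6)
  # diagonal cloud points at 45 degrees
  x <- rnorm(500)
  diag_pts <- cbind(x, x + rnorm(500, sd = 0.05))
  expect_equal(fit_confidence_ellipse(diag_pts)$theta_deg, 45, tolerance = 3)
  # exchanging the axes maps theta to 90 - theta
  e2 <- fit_confidence_ellipse(diag_pts[, 2:1])
  expect_equal(e2$theta_deg,
               90 - fit_confidence_ellipse(diag_pts)$theta_deg,
               tolerance = 1e-6)
  expect_error(fit_confidence_ellipse(diag_pts[1:2, ]))
})

test_that("relative variance is unit-mean, scale-invariant and flat when constant", {
  make_traj <- function(auc) structure(
    list(auc = auc, cells = seq_len(dim(auc)[1]), factors = "arithmetic"),
    class = "roc_trajectory")
  set.seed(4)
  base <- matrix(rnorm(40, 0.5, 0.1), 40, 1)
  auc <- array(rep(base, 24), dim = c(40, 1, 24),
               dimnames = list(NULL, "arithmetic", NULL))
  rv <- relative_variance(make_traj(auc), "arithmetic")
  expect_equal(rv, rep(1, 24), tolerance = 1e-12)
  # doubling all deviations from 0.5 leaves the normalised series unchanged
  auc2 <- array(rnorm(40 * 24, 0.5, 0.1), dim = c(40, 1, 24),
                dimnames = list(NULL, "arithmetic", NULL))
  rv1 <- relative_variance(make_traj(auc2), "arithmetic")
  auc3 <- 0.5 + 2 * (auc2 - 0.5)
  rv2 <- relative_variance(make_traj(auc3), "arithmetic")
  expect_equal(rv1, rv2, tolerance = 1e-12)
  expect_equal(mean(rv1), 1, tolerance = 1e-12)
})

test_that("permutation selection finds planted dual coders, spares nulls, is deterministic", {
  pl <- fx_study_small()
  gt <- pl$ground_truth
  dual <- which(gt$category == "arith_hand")
  sel <- select_simultaneous_coders(pl$pop, cells = dual, n_perm = 300,
                                    seed = 21)
  expect_gte(mean(sel$selected), 0.8)
  sel2 <- select_simultaneous_coders(pl$pop, cells = dual, n_perm = 300,
                                     seed = 21)
  expect_identical(sel, sel2)
  # conjunction of two alpha = 0.05 tests keeps almost no null cells
  nul <- fx_null()
  sel0 <- select_simultaneous_coders(nul$pop, cells = 1:100, n_perm = 300,
                                     seed = 22)
  expect_lte(sum(sel0$selected), 3)
})

test_that("quadrant time course recovers a planted addition-right coupling", {
  # simultaneous, fully congruent arithmetic+hand coders over a long overlap
  set.seed(31)
  trials <- fx_snarc()$trials
  profiles <- lapply(1:40, function(i) {
    s <- sample(c(-1, 1), 1)
    cell_profile(i, 10,
                 list(arithmetic = list(gain = 0.5 * s, window = c(100, 2100)),
                      hand = list(gain = 0.5 * s, window = c(100, 2100))))
  })
  sim <- simulate_population_spikes(profiles, trials, seed = 32)
  sel <- select_simultaneous_coders(sim$pop, n_perm = 300, seed = 33)
  traj <- roc_trajectories(sim$pop)
  quad <- quadrant_fraction_timecourse(sel, traj)
  expect_gt(sum(sel$selected), 10)
  mid <- quad$table$bin %in% 3:20
  expect_true(all(quad$table$frac_add_right[mid] > 0.5, na.rm = TRUE))
  expect_true(all(quad$table$frac_add_left[mid] < 0.5, na.rm = TRUE))
  expect_lt(quad$right$series_p, 0.01)
  expect_lt(quad$left$series_p, 0.01)
  # cells exactly at 0.5 are excluded from a bin's partition
  fake_sel <- data.frame(cell = 1:6, selected = TRUE)
  auc <- array(0.5, dim = c(6, 2, 24),
               dimnames = list(NULL, c("arithmetic", "hand"), NULL))
  auc[1:5, , 1] <- 0.7                      # five informative cells in bin 1
  fake_traj <- structure(list(auc = auc, cells = 1:6,
                              factors = c("arithmetic", "hand")),
                         class = "roc_trajectory")
  quad2 <- quadrant_fraction_timecourse(fake_sel, fake_traj)
  expect_equal(quad2$table$n_right[1] + quad2$table$n_left[1], 5)
})
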