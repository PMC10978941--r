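# Behavioural statistics: selection-rate matrices, exact binomial tail tests,
# Gaussian tuning fits, the numerical size effect, exact McNemar tests, and
# the reaction-time congruency contrast.

#' Exact one-sided binomial tail test
#'
#' Upper-tail probability P(X >= successes) for X ~ Binomial(n, p_chance).
#' This is the shared test for "better than chance" performance and for
#' whether more time windows are significant than the nominal rate predicts
#' (e.g. 13 of 276 windows at p_chance = 0.05 gives p = 0.63).
#'
#' @param successes,n Observed count and number of trials.
#' @param p_chance Chance probability in (0, 1).
#' @return The exact upper-tail p-value.
#' @export
#' @examples
#' binomial_tail_test(13, 276, 0.05)  # 0.626
binomial_tail_test <- function(successes, n, p_chance) {
  stopifnot(successes >= 0, successes <= n, p_chance > 0, p_chance < 1)
  pbinom(successes - 1, n, p_chance, lower.tail = FALSE)
}

#' Exact McNemar test on paired binary outcomes
#'
#' Two-sided exact test on the discordant pairs: with b and c the two
#' discordant counts, the p-value is the two-sided binomial probability of a
#' split at least as extreme as (b, c) under p = 1/2. Zero discordant pairs
#' give p = 1 by convention.
#'
#' @param b,c Discordant pair counts. Alternatively `b` may be a 2x2 table,
#'   in which case the off-diagonal entries are used.
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' mcnemar_consistency(10, 0)  # ~0.002
mcnemar_consistency <- function(b, c = NULL) {
  if (is.matrix(b) || is.table(b)) {
    stopifnot(all(dim(b) == c(2, 2)))
    cc <- b[2, 1]; b <- b[1, 2]
  } else cc <- c
  stopifnot(b >= 0, cc >= 0)
  if (b + cc == 0) return(1)
  stats::binom.test(b, b + cc, 0.5)$p.value
}

#' Selection-rate matrix
#'
#' Proportions of each chosen numerosity (0-6) per condition: per target
#' numerosity for the numerical operation task, per instruction x
#' preoperational numerosity for the instructed task. Rows are normalised to
#' sum to one; per-row trial counts are attached.
#'
#' @param trials Trial data.frame with `chosen_numerosity` filled.
#' @return An object of class `selection_matrix`: list with `proportions`
#'   (conditions x 7), `n_trials` per row, and the condition key.
#' @export
selection_rates <- function(trials) {
  if (nrow(trials) == 0) stop("no trials")
  num <- trials$task == "numerical_operation"
  key <- if (all(num)) {
    factor(trials$target_numerosity)
  } else if (all(!num)) {
    interaction(trials$instruction, trials$preoperational_numerosity,
                sep = ":", drop = TRUE)
  } else stop("mixed tasks: compute selection rates per task")
  tab <- table(key, factor(trials$chosen_numerosity, levels = 0:6))
  n_row <- rowSums(tab)
  props <- sweep(unclass(tab), 1, pmax(n_row, 1), "/")
  structure(list(proportions = props, n_trials = as.vector(n_row),
                 conditions = rownames(props),
                 empty = n_row == 0),
            class = "selection_matrix")
}

#' Gaussian tuning fit per condition
#'
#' Fits a Gaussian profile `A * exp(-(x - mu)^2 / (2 sigma^2))` to each row of
#' a selection matrix over chosen numerosity 0-6 by unweighted least squares
#' (amplitude, mean and sigma free), and returns the per-condition sigma
#' together with fit diagnostics. Rows with fewer than 3 occupied numerosity
#' bins, or rows where the fit does not converge, are flagged and excluded
#' from downstream regression.
#'
#' @param sel A [selection_rates()] result.
#' @return A data.frame: condition, `mu`, `sigma`, `amplitude`, `converged`.
#' @export
fit_gaussian_tuning <- function(sel) {
  x <- 0:6
  out <- lapply(seq_along(sel$conditions), function(i) {
    y <- sel$proportions[i, ]
    res <- data.frame(condition = sel$conditions[i], mu = NA_real_,
                      sigma = NA_real_, amplitude = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (sum(y > 0) < 3) return(res)
    mu0 <- sum(x * y)
    sd0 <- max(sqrt(sum((x - mu0)^2 * y)), 0.1)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                        data = data.frame(x = x, y = as.numeric(y)),
                        start = list(A = max(y), mu = mu0, s = sd0),
                        lower = c(A = 1e-6, mu = -2, s = 1e-3),
                        upper = c(A = 2, mu = 8, s = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(res)
    p <- coef(fit)
    res$mu <- p[["mu"]]; res$sigma <- abs(p[["s"]]); res$amplitude <- p[["A"]]
    res$converged <- TRUE
    res
  })
  do.call(rbind, out)
}

#' Numerical size-effect regression
#'
#' Ordinary least squares of the fitted tuning sigma on target numerosity.
#' A positive, significant slope is the numerical size effect: decisions grow
#' more variable as the target numerosity increases.
#'
#' @param fit A [fit_gaussian_tuning()] result whose conditions are target
#'   numerosities (coercible to numeric).
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   slope test), `n`.
#' @export
size_effect_regression <- function(fit) {
  ok <- fit$converged & !is.na(fit$sigma)
  x <- suppressWarnings(as.numeric(as.character(fit$condition[ok])))
  y <- fit$sigma[ok]
  if (sum(ok) < 3) stop("need at least 3 fitted conditions")
  if (length(unique(x)) < 2) stop("degenerate predictor")
  m <- lm(y ~ x)
  sm <- summary(m)
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n = sum(ok))
}

#' Behavioural performance vs chance
#'
#' Per-condition exact binomial test of the correct-response count against
#' the task chance level (25% for the numerical operation task, where four
#' target numerosities are possible; 50% for the instructed task).
#'
#' @param trials Trial data.frame with outcomes.
#' @param p_chance Chance probability; default by task.
#' @return A data.frame: condition, n, n_correct, proportion, p_value.
#' @export
performance_vs_chance <- function(trials, p_chance = NULL) {
  num <- all(trials$task == "numerical_operation")
  if (is.null(p_chance)) p_chance <- if (num) 0.25 else 0.5
  key <- if (num) trials$target_numerosity
         else paste(trials$instruction, trials$preoperational_numerosity,
                    sep = ":")
  agg <- aggregate(correct ~ key, data.frame(key = key,
                                             correct = trials$correct),
                   FUN = function(z) c(n = length(z), k = sum(z)))
  res <- data.frame(condition = agg$key, n = agg$correct[, "n"],
                    n_correct = agg$correct[, "k"])
  res$proportion <- res$n_correct / res$n
  res$p_value <- mapply(binomial_tail_test, res$n_correct, res$n, p_chance)
  res
}

#' Reaction-time congruency contrast
#'
#' Per hand, the median reaction-time difference between addition and
#' subtraction trials with a two-sided Mann-Whitney p-value. A SNARC-like
#' association predicts faster right-hand responses for addition (negative
#' addition-minus-subtraction difference for the right hand) and faster
#' left-hand responses for subtraction (positive difference for the left
#' hand).
#'
#' @param trials Labelled trial data.frame with `reaction_time_ms`.
#' @param min_trials Minimum trials per hand x operation cell (default 5).
#' @return A data.frame: hand, median RT difference (addition - subtraction,
#'   ms), p_value, the four cell counts, and an `evaluable` flag.
#' @export
rt_congruency_contrast <- function(trials, min_trials = 5) {
  trials <- trials[!is.na(trials$hand) & !is.na(trials$arithmetic) &
                     !is.na(trials$reaction_time_ms), , drop = FALSE]
  out <- lapply(c("left", "right"), function(h) {
    add <- trials$reaction_time_ms[trials$hand == h &
                                     trials$arithmetic == "addition"]
    sub <- trials$reaction_time_ms[trials$hand == h &
                                     trials$arithmetic == "subtraction"]
    ok <- length(add) >= min_trials && length(sub) >= min_trials
    data.frame(hand = h,
               rt_diff_ms = if (ok) median(add) - median(sub) else NA_real_,
               p_value = if (ok)
                 suppressWarnings(wilcox.test(add, sub)$p.value)
               else NA_real_,
               n_addition = length(add), n_subtraction = length(sub),
               evaluable = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the behavioural analysis stage
#'
#' @param trials Labelled, filtered numerical-operation trials.
#' @param trials_instructed Labelled, filtered instructed-task trials
#'   (optional).
#' @return A list with the selection matrices, performance tests, Gaussian
#'   tuning fits, size-effect regression and RT congruency contrast.
#' @export
behavior_stage <- function(trials, trials_instructed = NULL) {
  sel <- selection_rates(trials)
  fit <- fit_gaussian_tuning(sel)
  out <- list(
    selection = sel,
    performance = performance_vs_chance(trials),
    gaussian_fit = fit,
    size_effect = tryCatch(size_effect_regression(fit), error = function(e) NULL),
    rt_congruency = rt_congruency_contrast(trials)
  )
  if (!is.null(trials_instructed) && nrow(trials_instructed) > 0) {
    sel_i <- selection_rates(trials_instructed)
    out$selection_instructed <- sel_i
    out$performance_instructed <- performance_vs_chance(trials_instructed)
  }
  out
}
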