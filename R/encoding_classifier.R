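# Per-cell, per-100-ms-bin factor regression, coding histories, the
# instructed-task filter, cell categorisation and period-by-period tracking.
#
# The model per cell and bin is
#   firing rate = b0 + b1*arithmetic + b2*hand + b3*step + b4*stimulus_type
# with 0/1 dummy regressors (addition / right hand / one step / standard = 1)
# and a factor deemed significant when its coefficient's two-sided t-test
# gives p < 0.01. Because the same design matrix applies to every cell and
# bin, the whole population is fit in one pass of matrix algebra.

# OLS of many response columns on one design matrix.
# Returns coefficients (p x m), t p-values (p x m).
.ols_many <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  XtXinv <- chol2inv(qr.R(qrX))
  B <- XtXinv %*% crossprod(X, Y)
  rownames(B) <- colnames(X)
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(XtXinv), s2))
  tval <- B / se
  pval <- 2 * pt(-abs(tval), df)
  pval[se == 0] <- NA          # constant response: coefficient 0/0
  list(coef = B, p = pval, df = df)
}

.design_matrix <- function(trials, factors = .FACTORS, min_per_level = 5) {
  signs <- .trial_signs(trials)[, factors, drop = FALSE]
  dropped <- character(0)
  keep <- character(0)
  for (f in factors) {
    n_pos <- sum(signs[, f] > 0); n_neg <- sum(signs[, f] < 0)
    if (min(n_pos, n_neg) < min_per_level) dropped <- c(dropped, f)
    else keep <- c(keep, f)
  }
  X <- cbind(intercept = 1, (signs[, keep, drop = FALSE] + 1) / 2)
  list(X = X, factors = keep, dropped = dropped)
}

#' Binwise factor regression across a population
#'
#' Fits, for every cell and every requested 100 ms bin, the linear model of
#' firing rate (counts / 0.1 s) on the arithmetic, hand, step and stimulus-
#' type dummies, and flags each factor significant when its coefficient
#' p-value is below `alpha`. Factors with fewer than `min_per_level` trials
#' at either level are unestimable and excluded (p and flags `NA`) with a
#' warning.
#'
#' @param pop A [binned_population()] with labelled trials.
#' @param bins Bin indices to analyse (default all 24).
#' @param factors Regressors to include (default the four task factors;
#'   the instructed-task filter uses `"arithmetic"` alone).
#' @param alpha Per-coefficient significance level (default 0.01).
#' @param min_per_level Minimum trials per factor level (default 5).
#' @return An object of class `bin_regression`: arrays `coef`
#'   (cells x bins x coefficients), `p` and `flags`
#'   (cells x bins x factors), plus the bins and factors analysed.
#' @export
binwise_regression <- function(pop, bins = NULL, factors = .FACTORS,
                               alpha = 0.01, min_per_level = 5) {
  tl <- event_timeline()
  bins <- bins %||% seq_len(tl$n_bins)
  trials <- pop$trials
  d <- .design_matrix(trials, factors, min_per_level)
  if (length(d$dropped))
    warning("unestimable factor(s) excluded: ",
            paste(d$dropped, collapse = ", "))
  n_cells <- dim(pop$counts)[1]
  coef_arr <- array(NA_real_,
                    dim = c(n_cells, length(bins), ncol(d$X)),
                    dimnames = list(NULL, NULL, colnames(d$X)))
  p_arr <- array(NA_real_, dim = c(n_cells, length(bins), length(factors)),
                 dimnames = list(NULL, NULL, factors))
  rate_scale <- 1000 / tl$bin_width_ms     # counts -> spikes/s
  for (k in seq_along(bins)) {
    Y <- t(pop$counts[, , bins[k], drop = FALSE][, , 1]) * rate_scale
    fit <- .ols_many(d$X, Y)
    coef_arr[, k, ] <- t(fit$coef)
    for (f in d$factors) p_arr[, k, f] <- fit$p[f, ]
  }
  flags <- p_arr < alpha
  structure(list(coef = coef_arr, p = p_arr, flags = flags, bins = bins,
                 factors = factors, alpha = alpha,
                 dropped_factors = d$dropped,
                 cell_ids = pop$cell_ids),
            class = "bin_regression")
}

#' Coding history from binwise regression flags
#'
#' A factor (arithmetic, hand or step; the stimulus-type regressor is a
#' counterbalancing control and never enters histories) is recorded in a
#' period's coding set when it is significant in at least one of that
#' period's bins. The cumulative history at each period end is the union of
#' the per-period sets up to that point, so histories are monotone
#' non-decreasing.
#'
#' @param reg A [binwise_regression()] result covering the requested periods.
#' @param periods Named list of bin-index vectors (default: preoperational
#'   1-7, delay2 8-17, operation 18-24).
#' @return An object of class `coding_history`: logical arrays `per_period`
#'   and `cumulative`, both cells x periods x 3 factors.
#' @export
build_coding_history <- function(reg, periods = event_timeline()$periods) {
  hist_factors <- intersect(c("arithmetic", "hand", "step"), reg$factors)
  n_cells <- dim(reg$flags)[1]
  per <- array(FALSE, dim = c(n_cells, length(periods), length(hist_factors)),
               dimnames = list(NULL, names(periods), hist_factors))
  for (p in seq_along(periods)) {
    cols <- match(periods[[p]], reg$bins)
    if (anyNA(cols))
      stop("regression does not cover period '", names(periods)[p], "'")
    for (f in hist_factors) {
      fl <- reg$flags[, cols, f, drop = FALSE]
      per[, p, f] <- apply(fl, 1, function(z) any(z, na.rm = TRUE))
    }
  }
  cum <- per
  if (length(periods) > 1)
    for (p in 2:length(periods)) cum[, p, ] <- cum[, p, ] | cum[, p - 1, ]
  structure(list(per_period = per, cumulative = cum,
                 periods = periods, factors = hist_factors,
                 cell_ids = reg$cell_ids),
            class = "coding_history")
}

#' Instructed-task filter for arithmetic selectivity
#'
#' Candidate arithmetic cells keep their selectivity only if their activity
#' also differentiates the +/- instruction in the instructed task: the model
#' `firing rate = b0 + b5 * instruction` is fit in the seven 100 ms bins
#' following instruction onset and the cell passes when b5 is significant
#' (p < `alpha`) in at least one bin. Cells whose arithmetic code in the
#' numerical task merely reflects the numerosity comparison fail this filter.
#'
#' @param pop_instructed A [binned_population()] of instructed-task trials
#'   aligned to instruction onset.
#' @param candidates Indices of candidate cells (default all).
#' @param bins Bins of the instruction period (default 1-7).
#' @param alpha Significance level (default 0.01).
#' @return A logical vector over all cells: `TRUE` = passes the filter;
#'   `NA` for unevaluable cells (no usable instructed trials).
#' @export
instructed_task_filter <- function(pop_instructed, candidates = NULL,
                                   bins = 1:7, alpha = 0.01) {
  n_cells <- dim(pop_instructed$counts)[1]
  candidates <- candidates %||% seq_len(n_cells)
  out <- rep(NA, n_cells)
  reg <- tryCatch(
    binwise_regression(pop_instructed, bins = bins, factors = "arithmetic",
                       alpha = alpha),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(reg)) return(out)
  pass <- apply(reg$flags[, , "arithmetic", drop = FALSE], 1,
                function(z) any(z, na.rm = TRUE))
  out[candidates] <- pass[candidates]
  out
}

#' Categorise cells from coding history and the instructed-task filter
#'
#' A cell is arithmetic-/hand-/step-related when the factor appears in its
#' preoperational-period coding history in the numerical operation task
#' (categories may overlap); it is arithmetic-*selective* when, in addition,
#' it passes the instructed-task filter.
#'
#' @param history A [build_coding_history()] result (numerical task).
#' @param instructed_pass Logical vector from [instructed_task_filter()]
#'   (optional; `NULL` treats every arithmetic-related cell as selective).
#' @param period Period whose history defines relatedness (default
#'   `"preoperational"`).
#' @return A data.frame of per-cell category flags plus a `counts` attribute
#'   with the category totals.
#' @export
categorize_cells <- function(history, instructed_pass = NULL,
                             period = "preoperational") {
  p <- match(period, names(history$periods))
  rel <- history$per_period[, p, , drop = FALSE]
  tab <- data.frame(
    cell_id = history$cell_ids,
    arithmetic_related = rel[, 1, "arithmetic"],
    hand_related = rel[, 1, "hand"],
    step_related = rel[, 1, "step"]
  )
  tab$arithmetic_selective <- tab$arithmetic_related &
    if (is.null(instructed_pass)) TRUE else instructed_pass %in% TRUE
  counts <- c(arithmetic_related = sum(tab$arithmetic_related),
              hand_related = sum(tab$hand_related),
              step_related = sum(tab$step_related),
              arithmetic_selective = sum(tab$arithmetic_selective),
              total = nrow(tab))
  attr(tab, "counts") <- counts
  tab
}

#' Period-by-period exclusive-arithmetic tracking
#'
#' Tracks, for the arithmetic cells, whether the cumulative coding history is
#' exactly {arithmetic} ("exclusive arithmetic") at the end of the
#' preoperational period versus the end of the operation period, and tests
#' the paired change with the exact McNemar test. Transition cells that pick
#' up hand or step coding later in the trial lose exclusivity.
#'
#' @param history A [build_coding_history()] result.
#' @param cells Indices of the arithmetic cells to track.
#' @param from,to Period names compared (defaults `"preoperational"`,
#'   `"operation"`).
#' @return A list: per-cell logical vectors `exclusive_from`/`exclusive_to`,
#'   the exclusive fractions, discordant counts `b` (lost exclusivity) and
#'   `c` (gained), and the McNemar `p_value`.
#' @export
period_selectivity_tracking <- function(history, cells,
                                        from = "preoperational",
                                        to = "operation") {
  pf <- match(from, names(history$periods))
  pt_ <- match(to, names(history$periods))
  excl <- function(p) {
    h <- history$cumulative[cells, p, , drop = FALSE]
    h[, 1, "arithmetic"] & !h[, 1, "hand"] & !h[, 1, "step"]
  }
  e1 <- excl(pf); e2 <- excl(pt_)
  b <- sum(e1 & !e2); cc <- sum(!e1 & e2)
  list(exclusive_from = e1, exclusive_to = e2,
       fraction_from = mean(e1), fraction_to = mean(e2),
       b = b, c = cc, n = length(cells),
       p_value = mcnemar_consistency(b, cc))
}

#' Run the encoding-classification stage
#'
#' Binwise regression over the full concern period, coding histories, the
#' instructed-task filter, categorisation, and exclusive-arithmetic tracking.
#'
#' @param pop Numerical-task [binned_population()].
#' @param pop_instructed Instructed-task population (optional).
#' @param alpha Significance level for all regressions.
#' @return A list with `regression`, `history`, `instructed_pass`,
#'   `categories` and `tracking`.
#' @export
encoding_stage <- function(pop, pop_instructed = NULL, alpha = 0.01) {
  reg <- binwise_regression(pop, alpha = alpha)
  history <- build_coding_history(reg)
  pass <- if (!is.null(pop_instructed))
    instructed_task_filter(pop_instructed, alpha = alpha) else NULL
  categories <- categorize_cells(history, pass)
  arith_cells <- which(categories$arithmetic_selective)
  tracking <- if (length(arith_cells))
    period_selectivity_tracking(history, arith_cells) else NULL
  list(regression = reg, history = history, instructed_pass = pass,
       categories = categories, tracking = tracking,
       arithmetic_cells = arith_cells)
}
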