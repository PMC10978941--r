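# Sliding-window ROC selectivity, population ellipse and relative-variance
# dynamics, and the simultaneous arithmetic-by-hand coder analysis.
#
# AUC convention: values near 1 indicate a preference for addition, the right
# hand or one step; values near 0 a preference for subtraction, the left hand
# or two steps; 0.5 is no preference.

#' Mann-Whitney AUC
#'
#' Probability that a draw from the positive class exceeds a draw from the
#' negative class, ties counted half:
#' `AUC = (#(pos > neg) + 0.5 #(pos = neg)) / (n_pos * n_neg)`,
#' computed from rank sums.
#'
#' @param values_pos,values_neg Response values (e.g. bin firing rates) of
#'   the two classes; both must be non-empty.
#' @return The AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mann_whitney(c(5, 6, 7), c(1, 2, 3))  # 1
auc_mann_whitney <- function(values_pos, values_neg) {
  n_pos <- length(values_pos); n_neg <- length(values_neg)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be non-empty")
  r <- rank(c(values_pos, values_neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# AUC for every column of a trials x bins matrix given a positive-class mask
.auc_by_bin <- function(counts, pos) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  ranks <- apply(counts, 2, rank)
  (colSums(ranks[pos, , drop = FALSE]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
}

#' ROC trajectories per cell, factor and bin
#'
#' AUC time series over the 24 concern-period bins, one per cell and factor.
#' Factors with fewer than `min_per_class` trials in either class are flagged
#' missing (`NA`).
#'
#' @param pop A [binned_population()] with labelled trials.
#' @param cells Cell indices (default all).
#' @param factors Factors to analyse (default arithmetic, hand, step).
#' @return An object of class `roc_trajectory`: array `auc`
#'   (cells x factors x bins) and per-factor class counts.
#' @export
roc_trajectories <- function(pop, cells = NULL,
                             factors = c("arithmetic", "hand", "step"),
                             min_per_class = 5) {
  cells <- cells %||% seq_len(dim(pop$counts)[1])
  tl <- event_timeline()
  signs <- .trial_signs(pop$trials)
  auc <- array(NA_real_, dim = c(length(cells), length(factors), tl$n_bins),
               dimnames = list(NULL, factors, NULL))
  n_class <- matrix(0L, length(factors), 2,
                    dimnames = list(factors, c("pos", "neg")))
  for (f in factors) {
    use <- signs[, f] != 0
    pos <- signs[use, f] > 0
    n_class[f, ] <- c(sum(pos), sum(!pos))
    if (min(n_class[f, ]) < min_per_class) next
    for (ci in seq_along(cells))
      auc[ci, f, ] <- .auc_by_bin(pop$counts[cells[ci], use, ], pos)
  }
  structure(list(auc = auc, cells = cells, factors = factors,
                 n_class = n_class),
            class = "roc_trajectory")
}

#' 95% confidence ellipse of a 2-D point cloud
#'
#' Fits a two-dimensional Gaussian (sample mean and covariance) and summarises
#' the 95% contour: the ellipse at squared Mahalanobis distance
#' chi-square(2, 0.95) = 5.991. `theta` is the angle of the long axis
#' relative to the first coordinate axis, folded into \[0, 90\] degrees;
#' `axis_ratio` (l/s) is the ratio of the long to short semi-axis, i.e. the
#' square root of the eigenvalue ratio.
#'
#' @param points Two-column matrix (or data.frame) of coordinates.
#' @return An object of class `ellipse_fit`: `center`, `cov`, `theta_deg`,
#'   `axis_ratio`, semi-axis lengths `radii` (95% contour), `degenerate`
#'   flag, `n`.
#' @export
fit_confidence_ellipse <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  points <- points[stats::complete.cases(points), , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 points")
  ctr <- colMeans(points)
  S <- cov(points)
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  degenerate <- lam[2] <= .Machine$double.eps * lam[1]
  v <- eg$vectors[, 1]
  theta <- atan2(v[2], v[1]) * 180 / pi
  theta <- theta %% 180
  if (theta > 90) theta <- 180 - theta
  structure(list(center = ctr, cov = S, theta_deg = theta,
                 axis_ratio = if (degenerate) Inf else sqrt(lam[1] / lam[2]),
                 radii = sqrt(qchisq(0.95, 2) * lam),
                 degenerate = degenerate, n = nrow(points)),
            class = "ellipse_fit")
}

#' Relative variance of ROC values over time
#'
#' Across-cell variance of the AUC at each bin, normalised by the mean of
#' those variances over the period, so the series averages exactly 1. Rising
#' relative variance marks the bins where the population most strongly
#' differentiates that factor.
#'
#' @param traj A [roc_trajectories()] result.
#' @param factor Factor name.
#' @return Numeric vector of length 24 (NA for bins with no data, which are
#'   dropped from the normalisation with a warning).
#' @export
relative_variance <- function(traj, factor) {
  v <- apply(traj$auc[, factor, , drop = FALSE], 3, var, na.rm = TRUE)
  if (anyNA(v)) warning("bins with no AUC values dropped from normalisation")
  v / mean(v, na.rm = TRUE)
}

#' Select simultaneous arithmetic-and-hand coders by permutation test
#'
#' For each cell and factor, the selectivity statistic is the maximum
#' |AUC - 0.5| over the concern-period bins. A permutation null is built by
#' shuffling that factor's trial labels `n_perm` times and recomputing the
#' statistic; a cell is selected when the observed statistic strictly exceeds
#' the null's upper `alpha` quantile for *both* factors. The returned
#' coordinates are each factor's AUC at its most extreme bin.
#'
#' @param pop A [binned_population()].
#' @param cells Candidate cell indices (default all).
#' @param factors Two factors (default arithmetic and hand).
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Per-factor significance level (default 0.05).
#' @param seed Optional RNG seed.
#' @return A data.frame: cell, per-factor observed statistic, permutation
#'   p-value ((1 + #(null >= obs)) / (1 + n_perm)), AUC coordinates at the
#'   extreme bins, and `selected`.
#' @export
select_simultaneous_coders <- function(pop, cells = NULL,
                                       factors = c("arithmetic", "hand"),
                                       n_perm = 1000, alpha = 0.05,
                                       seed = NULL) {
  stopifnot(length(factors) == 2)
  if (!is.null(seed)) set.seed(seed)
  cells <- cells %||% seq_len(dim(pop$counts)[1])
  signs <- .trial_signs(pop$trials)
  k <- max(1L, ceiling(alpha * n_perm))     # rank of the null threshold
  res <- data.frame(cell = cells)
  for (f in factors) {
    use <- which(signs[, f] != 0)
    pos <- signs[use, f] > 0
    n_pos <- sum(pos); n_neg <- sum(!pos)
    # shared shuffles across cells: trials x n_perm matrix of class masks
    perm_mask <- vapply(seq_len(n_perm), function(i) sample(pos),
                        logical(length(pos)))
    obs_stat <- auc_ext <- numeric(length(cells))
    pval <- thr <- numeric(length(cells))
    for (ci in seq_along(cells)) {
      ranks <- apply(pop$counts[cells[ci], use, ], 2, rank)
      a_obs <- (colSums(ranks[pos, , drop = FALSE]) -
                  n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
      stat <- abs(a_obs - 0.5)
      obs_stat[ci] <- max(stat)
      auc_ext[ci] <- a_obs[which.max(stat)]
      # null: rank-sum of shuffled positive class, all bins at once
      S <- crossprod(ranks, perm_mask)      # bins x n_perm
      a_null <- (S - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
      null_stat <- apply(abs(a_null - 0.5), 2, max)
      pval[ci] <- (1 + sum(null_stat >= obs_stat[ci])) / (1 + n_perm)
      thr[ci] <- sort(null_stat, decreasing = TRUE)[k]
    }
    res[[paste0("stat_", f)]] <- obs_stat
    res[[paste0("auc_", f)]] <- auc_ext
    res[[paste0("p_", f)]] <- pval
    res[[paste0("pass_", f)]] <- obs_stat > thr
  }
  res$selected <- res[[paste0("pass_", factors[1])]] &
    res[[paste0("pass_", factors[2])]]
  res
}

#' Quadrant time course of simultaneous coders
#'
#' At each bin, the selected cells are partitioned by the sign of their hand
#' AUC (right vs left preference) and of their arithmetic AUC (addition vs
#' subtraction preference); cells sitting exactly at 0.5 on either factor are
#' excluded from that bin. Within each hand group, a one-sided exact binomial
#' test (chance 0.5) asks whether the group over-represents its
#' SNARC-congruent operation (addition among right-hand coders, subtraction
#' among left-hand coders). The series summary counts the significant bins
#' and tests that count against the nominal rate with
#' [binomial_tail_test()] at chance 0.05.
#'
#' @param sel Selected-coder table from [select_simultaneous_coders()] (only
#'   rows with `selected` are used).
#' @param traj A [roc_trajectories()] result covering the same cells.
#' @param alpha_bin Per-bin significance level (default 0.05).
#' @param min_cells Minimum cells per hand group per bin (default 5).
#' @return An object of class `quadrant_timecourse`: per-bin data.frame
#'   (per-group counts, addition fractions, p-values) and per-group series
#'   summaries (`n_significant`, `series_p`).
#' @export
quadrant_fraction_timecourse <- function(sel, traj, alpha_bin = 0.05,
                                         min_cells = 5) {
  cells <- sel$cell[sel$selected]
  idx <- match(cells, traj$cells)
  if (anyNA(idx)) stop("selected cells missing from trajectory")
  n_bins <- dim(traj$auc)[3]
  rows <- lapply(seq_len(n_bins), function(b) {
    a <- traj$auc[idx, "arithmetic", b]
    h <- traj$auc[idx, "hand", b]
    use <- !is.na(a) & !is.na(h) & a != 0.5 & h != 0.5
    right <- h[use] > 0.5
    add <- a[use] > 0.5
    out <- data.frame(bin = b,
                      n_right = sum(right), n_left = sum(!right),
                      frac_add_right = NA_real_, frac_add_left = NA_real_,
                      p_right = NA_real_, p_left = NA_real_)
    if (out$n_right >= min_cells) {
      out$frac_add_right <- mean(add[right])
      out$p_right <- binomial_tail_test(sum(add[right]), out$n_right, 0.5)
    }
    if (out$n_left >= min_cells) {
      out$frac_add_left <- mean(add[!right])
      out$p_left <- binomial_tail_test(sum(!add[!right]), out$n_left, 0.5)
    }
    out
  })
  tab <- do.call(rbind, rows)
  summarise <- function(p) {
    ok <- !is.na(p)
    k <- sum(p[ok] < alpha_bin)
    list(n_significant = k, n_bins = sum(ok),
         series_p = if (sum(ok)) binomial_tail_test(k, sum(ok), 0.05) else NA)
  }
  structure(list(table = tab,
                 right = summarise(tab$p_right),
                 left = summarise(tab$p_left),
                 n_selected = length(cells)),
            class = "quadrant_timecourse")
}

#' Run the population ROC stage
#'
#' @param pop A [binned_population()].
#' @param cells Arithmetic-cell indices to analyse.
#' @param n_perm Permutations for the simultaneous-coder selection.
#' @param seed Optional RNG seed.
#' @return A list with `trajectories`, `relative_variance` per factor,
#'   `ellipses` (per plane at early/operation/late reference bins),
#'   `coders` and `quadrants`.
#' @export
roc_stage <- function(pop, cells, n_perm = 1000, seed = NULL) {
  traj <- roc_trajectories(pop, cells)
  relvar <- sapply(c("arithmetic", "hand", "step"),
                   function(f) relative_variance(traj, f))
  ref_bins <- c(early = 3, delay = 12, operation = 20, late = 23)
  planes <- list(c("arithmetic", "hand"), c("arithmetic", "step"),
                 c("hand", "step"))
  ellipses <- lapply(ref_bins, function(b) {
    lapply(planes, function(pl) {
      pts <- cbind(traj$auc[, pl[1], b], traj$auc[, pl[2], b])
      colnames(pts) <- pl
      tryCatch(fit_confidence_ellipse(pts), error = function(e) NULL)
    })
  })
  coders <- select_simultaneous_coders(pop, cells, n_perm = n_perm,
                                       seed = seed)
  quad <- if (sum(coders$selected) >= 5)
    quadrant_fraction_timecourse(coders, traj) else NULL
  list(trajectories = traj, relative_variance = relvar, ellipses = ellipses,
       coders = coders, quadrants = quad)
}
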