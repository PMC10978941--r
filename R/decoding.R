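# Pseudopopulation construction and temporal cross-training decoding with a
# linear support vector machine (LIBSVM via e1071), tenfold cross-validation,
# permutation significance, and cross-operation classifier reuse.

#' Build a pseudopopulation of condition-matched trials
#'
#' Cells need not be recorded simultaneously: pseudotrials are assembled by
#' sampling, for every cell and condition, `n_per_condition` of its trials
#' without replacement and aligning them by condition repetition. Cells with
#' fewer than `min_per_condition` trials in any condition are excluded. With
#' the default design (4 target numerosities x 2 arithmetic x 2 hand x 10
#' repetitions) this yields 160 pseudotrials.
#'
#' @param pop A [binned_population()] with labelled trials.
#' @param cells Candidate cell indices (default all).
#' @param condition_vars Label columns defining a condition.
#' @param min_per_condition Inclusion criterion (default 10).
#' @param n_per_condition Repetitions sampled per condition (default
#'   `min_per_condition`).
#' @param seed Optional RNG seed.
#' @return An object of class `pseudopopulation`: `activity`
#'   (cells x pseudotrials x 24), pseudotrial `labels`, the included
#'   `cells`, and per-cell source-trial bookkeeping.
#' @export
build_pseudopopulation <- function(pop, cells = NULL,
                                   condition_vars = c("target_numerosity",
                                                      "arithmetic", "hand"),
                                   min_per_condition = 10,
                                   n_per_condition = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_per_condition <- n_per_condition %||% min_per_condition
  cells <- cells %||% seq_len(dim(pop$counts)[1])
  trials <- pop$trials
  cond <- interaction(trials[condition_vars], sep = ":", drop = TRUE)
  counts_per_cond <- table(cond)
  # all cells share the trial table, so qualification is uniform; cells are
  # still sampled independently, as pseudopopulations combine sessions
  if (any(counts_per_cond < min_per_condition))
    stop("condition(s) below the ", min_per_condition, "-trial criterion: ",
         paste(names(counts_per_cond)[counts_per_cond < min_per_condition],
               collapse = ", "))
  if (length(cells) == 0) stop("no qualifying cells")
  levels_c <- levels(cond)
  n_pt <- length(levels_c) * n_per_condition
  labels <- trials[0, condition_vars, drop = FALSE]
  activity <- array(0L, dim = c(length(cells), n_pt, dim(pop$counts)[3]))
  source_trials <- matrix(0L, length(cells), n_pt)
  pt <- 0L
  lab_rows <- integer(0)
  for (cl in levels_c) {
    rows <- which(cond == cl)
    lab_rows <- c(lab_rows, rep(rows[1], n_per_condition))
    for (ci in seq_along(cells)) {
      pick <- sample(rows, n_per_condition)
      source_trials[ci, pt + seq_len(n_per_condition)] <- pick
      activity[ci, pt + seq_len(n_per_condition), ] <-
        pop$counts[cells[ci], pick, ]
    }
    pt <- pt + n_per_condition
  }
  labels <- trials[lab_rows, condition_vars, drop = FALSE]
  rownames(labels) <- NULL
  labels$condition <- rep(levels_c, each = n_per_condition)
  structure(list(activity = activity, labels = labels, cells = cells,
                 source_trials = source_trials,
                 n_pseudotrials = n_pt),
            class = "pseudopopulation")
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat("<pseudopopulation> ", length(x$cells), " cells x ", x$n_pseudotrials,
      " pseudotrials (", length(unique(x$labels$condition)),
      " conditions)\n", sep = "")
  invisible(x)
}

# condition-stratified fold assignment, reused across all pixels of a grid
.assign_folds <- function(condition, folds) {
  fold <- integer(length(condition))
  for (cl in unique(condition)) {
    rows <- which(condition == cl)
    fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  fold
}

# Core cross-temporal decoding engine. Trains a linear SVM (cost `cost`) per
# (fold, train bin) on per-cell z-scored activity (training-split statistics
# only) and evaluates on every test bin of the held-out split via the
# explicit decision function w'x - rho. Returns the accuracy matrix and,
# optionally, the per-pixel held-out predictions (class index 1/2).
.decode_grid <- function(activity, y, fold, bins, cost = 1,
                         keep_predictions = FALSE) {
  lev <- levels(y)
  stopifnot(length(lev) == 2)
  nb <- length(bins)
  folds <- max(fold)
  n_cells <- dim(activity)[1]
  acc_sum <- matrix(0, nb, nb)
  n_test_total <- length(y)
  pred <- if (keep_predictions)
    array(NA_integer_, dim = c(nb, nb, length(y))) else NULL
  for (k in seq_len(folds)) {
    te <- fold == k; tr <- !te
    y_tr <- y[tr]
    n_te <- sum(te)
    y_te_idx <- as.integer(y)[te]
    # test activity of all bins at once: cells x (n_te * nb)
    A_te <- matrix(activity[, te, bins], n_cells, n_te * nb)
    for (bi in seq_len(nb)) {
      Xtr <- t(activity[, tr, bins[bi]])
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, sd); sdv[sdv == 0] <- 1
      Xtr <- scale(Xtr, mu, sdv)
      m <- e1071::svm(Xtr, y_tr, kernel = "linear", cost = cost,
                      scale = FALSE)
      w <- drop(crossprod(m$coefs, m$SV))
      d_tr <- drop(Xtr[m$index, , drop = FALSE] %*% w) - m$rho
      # class on the positive side of the decision function
      pos_idx <- match(as.character(m$fitted[m$index][which.max(d_tr)]), lev)
      # fold z-scoring into the weights: d = x'(w/sd) - (mu'(w/sd) + rho)
      wv <- w / sdv
      offset <- sum(mu * wv) + m$rho
      d <- crossprod(A_te, wv) - offset          # (n_te * nb) x 1
      pr <- matrix(ifelse(d > 0, pos_idx, 3L - pos_idx), n_te, nb)
      acc_sum[bi, ] <- acc_sum[bi, ] + colSums(pr == y_te_idx)
      if (keep_predictions) pred[bi, , te] <- t(pr)
    }
  }
  list(accuracy = acc_sum / n_test_total, predictions = pred)
}

#' Temporal cross-training decoding
#'
#' Tenfold cross-validated linear SVM decoding of a binary label from
#' pseudopopulation activity, trained at each 100 ms window and tested at
#' every window: a 24 x 24 accuracy grid (rows = training window, columns =
#' testing window) whose diagonal is same-time decoding. Features are
#' z-scored per cell with training-split statistics only; the
#' condition-stratified fold partition is drawn once and reused for all 576
#' pixels so they are comparable.
#'
#' @param pp A [build_pseudopopulation()] result.
#' @param label_var Binary label column to decode (`"arithmetic"` or
#'   `"hand"`).
#' @param folds Cross-validation folds (default 10).
#' @param bins Window indices (default all 24).
#' @param cost SVM regularisation constant (default 1).
#' @param seed Optional RNG seed (governs the fold partition).
#' @return An object of class `decoding_grid`: `accuracy` (train x test),
#'   held-out `predictions`, the fold partition, labels and metadata.
#' @export
crosstemporal_decode <- function(pp, label_var = "arithmetic", folds = 10,
                                 bins = NULL, cost = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bins <- bins %||% seq_len(dim(pp$activity)[3])
  y <- factor(pp$labels[[label_var]])
  if (nlevels(y) != 2) stop("label '", label_var, "' is not binary")
  fold <- .assign_folds(pp$labels$condition, folds)
  if (min(table(y, fold)) < 1)
    warning("some fold lacks a class; accuracy estimates may be unstable")
  fit <- .decode_grid(pp$activity, y, fold, bins, cost,
                      keep_predictions = TRUE)
  structure(list(accuracy = fit$accuracy, predictions = fit$predictions,
                 bins = bins, label_var = label_var, levels = levels(y),
                 y = y, fold = fold, folds = folds, cost = cost,
                 p = NULL, mask = NULL, n_perm = 0),
            class = "decoding_grid")
}

#' @export
print.decoding_grid <- function(x, ...) {
  cat("<decoding_grid> ", length(x$bins), "x", length(x$bins),
      " (train x test), label: ", x$label_var,
      if (!is.null(x$mask)) paste0(", ", sum(x$mask), " significant pixel(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Permutation significance of a decoding grid
#'
#' Builds, for every pixel, a null distribution of accuracies by shuffling
#' the decoded labels `n_perm` times and re-running the full cross-validated
#' decoding (one shuffle per replicate, reused across all pixels of the
#' grid). A pixel is significant when its observed accuracy strictly exceeds
#' the `ceiling(alpha * n_perm)`-th highest null value (for 1000 permutations
#' at alpha 0.05, the 50th highest; ties count as non-significant).
#'
#' @param pp The pseudopopulation the grid was computed from.
#' @param grid A [crosstemporal_decode()] result.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional RNG seed.
#' @return `grid` with `p` (per-pixel permutation p-values), `mask`
#'   (logical significance matrix), `null_mean` and `n_perm` filled in.
#' @export
permutation_significance <- function(pp, grid, n_perm = 1000, alpha = 0.05,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- length(grid$bins)
  null_acc <- array(NA_real_, dim = c(n_perm, nb, nb))
  for (r in seq_len(n_perm)) {
    y_perm <- sample(grid$y)
    null_acc[r, , ] <- .decode_grid(pp$activity, y_perm, grid$fold,
                                    grid$bins, grid$cost)$accuracy
  }
  k <- max(1L, ceiling(alpha * n_perm))
  thr <- apply(null_acc, c(2, 3), function(z) sort(z, decreasing = TRUE)[k])
  ge <- sweep(null_acc, c(2, 3), grid$accuracy, ">=")
  grid$p <- (1 + apply(ge, c(2, 3), sum)) / (1 + n_perm)
  grid$mask <- grid$accuracy > thr
  grid$null_mean <- apply(null_acc, c(2, 3), mean)
  grid$n_perm <- n_perm
  grid$alpha <- alpha
  grid
}

#' Permutation null of cross-validated accuracy at one window pair
#'
#' Shuffles the decoded labels `n_perm` times and re-runs the full
#' cross-validated linear-SVM decoding at a single (train window, test
#' window) pair each time. Under shuffling the expected mean accuracy is 50%;
#' the returned distribution is the per-pixel null used by
#' [permutation_significance()].
#'
#' @param pp A [build_pseudopopulation()] result.
#' @param label_var Binary label to decode.
#' @param train_bin,test_bin Window indices (default: same-time decoding at
#'   window 8, the first delay-2 window).
#' @param n_perm Number of shuffles (default 1000).
#' @param folds CV folds (default 10).
#' @param seed Optional RNG seed.
#' @return A list: `null_accuracy` (length `n_perm`), `null_mean`,
#'   `observed` (unshuffled accuracy at the pair).
#' @export
shuffled_accuracy_null <- function(pp, label_var = "arithmetic",
                                   train_bin = 8, test_bin = train_bin,
                                   n_perm = 1000, folds = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- factor(pp$labels[[label_var]])
  fold <- .assign_folds(pp$labels$condition, folds)
  bins <- unique(c(train_bin, test_bin))
  pick <- function(res) res$accuracy[1, match(test_bin, bins)]
  observed <- pick(.decode_grid(pp$activity, y, fold, bins))
  null_accuracy <- vapply(seq_len(n_perm), function(r)
    pick(.decode_grid(pp$activity, sample(y), fold, bins)), numeric(1))
  list(null_accuracy = null_accuracy, null_mean = mean(null_accuracy),
       observed = observed)
}

#' Cross-operation decoding by classifier reuse
#'
#' Applies the classifiers of a grid trained on one label system, without
#' refitting, to score another label system through a fixed bijection
#' (default: addition to the right hand, subtraction to the left). Train and
#' test splits are those of the original cross-validation, so no pseudotrial
#' is scored by a classifier that saw it.
#'
#' Two permutation nulls are available. `"score"` (default) shuffles the
#' *tested* labels and re-scores the stored predictions — the null of
#' "predictions carry no information about the tested labels", computable at
#' negligible cost. `"refit"` shuffles the *trained* labels, refits the fold
#' classifiers each replicate and scores the mapped predictions against the
#' true tested labels — the full procedure null, which additionally absorbs
#' classifier weight-sampling noise. The distinction matters for reuse
#' grids: weights fit on one label system carry random overlap with any
#' other code present at the tested window, inflating pixel accuracies
#' symmetrically about 50%; only the refit null reflects that variance, so
#' score-based masks are anticonservative on populations without systematic
#' coupling. Refit costs `n_perm` full grid recomputations.
#'
#' @param pp The pseudopopulation.
#' @param trained_on Label system the classifiers were trained on.
#' @param tested_on Label system scored against.
#' @param mapping Named character bijection from trained to tested levels.
#' @param grid Optional precomputed [crosstemporal_decode()] grid for
#'   `trained_on` (computed here if absent).
#' @param n_perm Permutations for significance (0 to skip).
#' @param alpha Significance level.
#' @param seed Optional RNG seed.
#' @param perm_method `"score"` or `"refit"` (see Details).
#' @param ... Passed to [crosstemporal_decode()] when `grid` is absent.
#' @return A `decoding_grid` for the mapped predictions, with permutation
#'   `p`, `mask` and `null_mean` when `n_perm > 0`.
#' @export
cross_operation_decode <- function(pp, trained_on = "arithmetic",
                                   tested_on = "hand",
                                   mapping = c(addition = "right",
                                               subtraction = "left"),
                                   grid = NULL, n_perm = 1000, alpha = 0.05,
                                   seed = NULL,
                                   perm_method = c("score", "refit"), ...) {
  perm_method <- match.arg(perm_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid))
    grid <- crosstemporal_decode(pp, trained_on, ...)
  y_test <- factor(pp$labels[[tested_on]])
  lev_te <- levels(y_test)
  if (!setequal(names(mapping), grid$levels) ||
      !setequal(unname(mapping), lev_te) ||
      anyDuplicated(unname(mapping)))
    stop("mapping must be a bijection from trained to tested levels")
  nb <- length(grid$bins)
  # predictions as tested-system class indices
  map_idx <- match(mapping[grid$levels], lev_te)
  pred_te <- array(map_idx[grid$predictions],
                   dim = dim(grid$predictions))
  y_idx <- as.integer(y_test)
  hits <- sweep(pred_te, 3, y_idx, "==")
  acc <- apply(hits, c(1, 2), mean)
  out <- grid
  out$accuracy <- acc
  out$predictions <- pred_te
  out$label_var <- paste0(grid$label_var, "->", tested_on)
  out$levels <- lev_te
  out$y <- y_test
  out$p <- out$mask <- out$null_mean <- NULL
  out$n_perm <- 0
  if (n_perm > 0) {
    n_pt <- length(y_idx)
    null_acc <- matrix(NA_real_, n_perm, nb * nb)
    if (perm_method == "score") {
      flat <- matrix(pred_te, nb * nb, n_pt)   # pixels x pseudotrials
      for (r in seq_len(n_perm)) {
        yp <- sample(y_idx)
        null_acc[r, ] <- rowMeans(flat == matrix(yp, nb * nb, n_pt,
                                                 byrow = TRUE))
      }
    } else {
      for (r in seq_len(n_perm)) {
        res <- .decode_grid(pp$activity, sample(grid$y), grid$fold,
                            grid$bins, grid$cost, keep_predictions = TRUE)
        pr <- array(map_idx[res$predictions], dim = dim(res$predictions))
        null_acc[r, ] <- as.vector(apply(sweep(pr, 3, y_idx, "=="),
                                         c(1, 2), mean))
      }
    }
    k <- max(1L, ceiling(alpha * n_perm))
    thr <- apply(null_acc, 2, function(z) sort(z, decreasing = TRUE)[k])
    obs <- as.vector(acc)
    out$p <- matrix((1 + colSums(sweep(null_acc, 2, obs, ">="))) /
                      (1 + n_perm), nb, nb)
    out$mask <- matrix(obs > thr, nb, nb)
    out$null_mean <- matrix(colMeans(null_acc), nb, nb)
    out$n_perm <- n_perm
    out$alpha <- alpha
  }
  out
}

#' Prospective / retrospective / same-time decoding summary
#'
#' Partitions the cross-training grid into same-time decoding (the diagonal;
#' 24 windows), prospective decoding in which training precedes testing (the
#' upper triangle; 276 windows) and retrospective decoding in which training
#' follows testing (the lower triangle; 276 windows), counts the significant
#' pixels in each region, and evaluates each count with the exact binomial
#' tail test at a per-pixel chance rate of 0.05.
#'
#' @param grid A `decoding_grid` with a significance mask.
#' @return A data.frame: region, n_windows, n_significant, fraction,
#'   p_value.
#' @export
prospective_retrospective_summary <- function(grid) {
  if (is.null(grid$mask)) stop("grid has no significance mask")
  nb <- nrow(grid$mask)
  tr_bin <- row(grid$mask); te_bin <- col(grid$mask)
  regions <- list(diagonal = tr_bin == te_bin,
                  prospective = tr_bin < te_bin,
                  retrospective = tr_bin > te_bin)
  out <- lapply(names(regions), function(rg) {
    m <- regions[[rg]]
    k <- sum(grid$mask[m]); n <- sum(m)
    data.frame(region = rg, n_windows = n, n_significant = k,
               fraction = k / n,
               p_value = binomial_tail_test(k, n, 0.05),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the decoding stage
#'
#' Builds the pseudopopulation, decodes arithmetic and hand with temporal
#' cross-training and permutation significance, and runs both directions of
#' cross-operation classifier reuse with their prospective/retrospective
#' summaries.
#'
#' @param pop A [binned_population()].
#' @param cells Cell indices entering the pseudopopulation.
#' @param n_perm Permutations (default 1000).
#' @param folds CV folds (default 10).
#' @param min_per_condition Pseudopopulation criterion (default 10).
#' @param seed Optional RNG seed.
#' @param within_perm Run the (costly) within-system permutation refits
#'   (default `TRUE`).
#' @return A list with the pseudopopulation, the arithmetic and hand grids,
#'   both cross-operation grids and their summaries.
#' @export
decoding_stage <- function(pop, cells, n_perm = 1000, folds = 10,
                           min_per_condition = 10, seed = NULL,
                           within_perm = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pp <- build_pseudopopulation(pop, cells,
                               min_per_condition = min_per_condition)
  grid_arith <- crosstemporal_decode(pp, "arithmetic", folds = folds)
  grid_hand <- crosstemporal_decode(pp, "hand", folds = folds)
  if (within_perm && n_perm > 0) {
    grid_arith <- permutation_significance(pp, grid_arith, n_perm)
    grid_hand <- permutation_significance(pp, grid_hand, n_perm)
  }
  xop_ah <- cross_operation_decode(pp, "arithmetic", "hand",
                                   grid = grid_arith, n_perm = n_perm)
  xop_ha <- cross_operation_decode(pp, "hand", "arithmetic",
                                   mapping = c(right = "addition",
                                               left = "subtraction"),
                                   grid = grid_hand, n_perm = n_perm)
  list(pseudopopulation = pp,
       grid_arithmetic = grid_arith, grid_hand = grid_hand,
       cross_arith_to_hand = xop_ah, cross_hand_to_arith = xop_ha,
       summary_arith_to_hand = prospective_retrospective_summary(xop_ah),
       summary_hand_to_arith = prospective_retrospective_summary(xop_ha))
}
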