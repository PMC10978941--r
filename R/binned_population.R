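# Container for binned spike counts: cells x trials x 24 bins.

#' Binned population container
#'
#' Holds spike counts for a population of cells over labelled trials, split
#' into 24 half-open 100 ms bins covering the 2400 ms concern period (bins
#' 1-17 aligned to preoperational-numerosity onset, bins 18-24 to the Go
#' signal; for instructed-task data the alignment event is the instruction
#' onset).
#'
#' @param counts Integer array, cells x trials x 24.
#' @param trials Labelled trial data.frame with one row per trial (second
#'   array dimension).
#' @param cell_ids Optional cell identifiers (default `1:n_cells`).
#' @param bin_width_ms Bin width, must be 100.
#' @param alignment Alignment metadata string.
#' @return An object of class `binned_population`.
#' @export
binned_population <- function(counts, trials, cell_ids = NULL,
                              bin_width_ms = 100,
                              alignment = "preop_onset|go_spliced") {
  tl <- event_timeline()
  if (length(dim(counts)) != 3)
    stop("counts must be a 3-d array (cells x trials x bins)")
  if (dim(counts)[3] != tl$n_bins)
    stop("counts must have ", tl$n_bins, " bins, got ", dim(counts)[3])
  if (dim(counts)[2] != nrow(trials))
    stop("trial dimension (", dim(counts)[2], ") does not match trial table (",
         nrow(trials), " rows)")
  if (any(counts < 0)) stop("negative spike counts")
  if (bin_width_ms != tl$bin_width_ms) stop("bin width must be 100 ms")
  structure(list(counts = counts, trials = trials,
                 cell_ids = cell_ids %||% seq_len(dim(counts)[1]),
                 bin_width_ms = bin_width_ms, alignment = alignment),
            class = "binned_population")
}

#' @export
print.binned_population <- function(x, ...) {
  d <- dim(x$counts)
  cat("<binned_population> ", d[1], " cells x ", d[2], " trials x ", d[3],
      " bins (", x$bin_width_ms, " ms, ", x$alignment, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.binned_population <- function(x) dim(x$counts)

#' Bin spike times into the 24-bin concern period
#'
#' Spike times are binned into half-open 100 ms windows `[t, t + 100)`.
#' Bins 1-17 are aligned to the preoperational-numerosity onset
#' (`t_preop_on`); bins 18-24 to the Go signal (`t_go`), so populations with
#' variable delay timing are spliced seamlessly at the Go signal. Trials
#' missing either event are dropped with a warning.
#'
#' @param spikes A list (length = cells) of lists (length = trials) of spike
#'   time vectors, in ms on the same clock as the trial event times.
#' @param trials Trial data.frame with `t_preop_on` and `t_go` columns.
#' @param ... Passed to [binned_population()].
#' @return A [binned_population()].
#' @export
bin_spike_counts <- function(spikes, trials, ...) {
  tl <- event_timeline()
  ok <- !is.na(trials$t_preop_on) & !is.na(trials$t_go)
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: missing alignment events")
    trials <- trials[ok, , drop = FALSE]
    spikes <- lapply(spikes, function(s) s[ok])
  }
  n_cells <- length(spikes)
  n_trials <- nrow(trials)
  pre_bins <- tl$go_ms %/% tl$bin_width_ms          # 17 preop-aligned bins
  op_bins <- tl$n_bins - pre_bins                   # 7 go-aligned bins
  counts <- array(0L, dim = c(n_cells, n_trials, tl$n_bins))
  for (i in seq_len(n_cells)) {
    for (j in seq_len(n_trials)) {
      st <- spikes[[i]][[j]]
      rel_pre <- st - trials$t_preop_on[j]
      rel_go <- st - trials$t_go[j]
      b_pre <- floor(rel_pre / tl$bin_width_ms) + 1
      b_op <- floor(rel_go / tl$bin_width_ms) + 1
      b_pre <- b_pre[b_pre >= 1 & b_pre <= pre_bins]
      b_op <- b_op[b_op >= 1 & b_op <= op_bins] + pre_bins
      counts[i, j, ] <- tabulate(c(b_pre, b_op), nbins = tl$n_bins)
    }
  }
  binned_population(counts, trials, ...)
}
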