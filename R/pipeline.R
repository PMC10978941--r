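# End-to-end orchestration: configuration, dataset I/O, stage runners and a
# small command-line front-end (see inst/cli/arithpop.R).

#' Pipeline configuration
#'
#' Defaults follow the analysis parameters used throughout: 100 ms bins,
#' regression significance 0.01, permutation significance 0.05 with 1000
#' permutations, tenfold cross-validation, and a 10-trial-per-condition
#' pseudopopulation criterion.
#'
#' @param seed Master RNG seed.
#' @param preset Synthetic preset name (ignored when `input` is given).
#' @param input Optional directory holding a saved dataset.
#' @param outdir Output directory.
#' @param n_cells,n_trials Synthetic population / trial-count overrides.
#' @param alpha_regression,alpha_perm Significance levels.
#' @param n_perm Permutations.
#' @param folds CV folds.
#' @param min_per_condition Pseudopopulation criterion.
#' @param within_perm Run within-system permutation refits in the decoding
#'   stage (the costly part; `FALSE` keeps cross-operation permutations
#'   only).
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, preset = "study_like", input = NULL,
                            outdir = "arithpop_out", n_cells = NULL,
                            n_trials = 1000, alpha_regression = 0.01,
                            alpha_perm = 0.05, n_perm = 1000, folds = 10,
                            min_per_condition = 10, within_perm = FALSE) {
  stopifnot(alpha_regression > 0, alpha_regression < 1,
            alpha_perm > 0, alpha_perm < 1, n_perm >= 0, folds >= 2)
  structure(list(seed = seed, preset = preset, input = input,
                 outdir = outdir, n_cells = n_cells, n_trials = n_trials,
                 alpha_regression = alpha_regression,
                 alpha_perm = alpha_perm, n_perm = n_perm, folds = folds,
                 min_per_condition = min_per_condition,
                 within_perm = within_perm),
            class = "pipeline_config")
}

.counts_to_df <- function(counts, cell_ids) {
  d <- dim(counts)
  df <- data.frame(cell = rep(cell_ids, d[2]),
                   trial = rep(seq_len(d[2]), each = d[1]))
  m <- matrix(counts, d[1] * d[2], d[3])
  colnames(m) <- paste0("b", seq_len(d[3]))
  cbind(df, as.data.frame(m))
}

.df_to_counts <- function(df, n_bins = 24) {
  bin_cols <- grep("^b[0-9]+$", names(df), value = TRUE)
  if (length(bin_cols) != n_bins)
    stop("counts table has ", length(bin_cols), " bin columns; expected ",
         n_bins)
  cells <- sort(unique(df$cell))
  n_trials <- max(df$trial)
  counts <- array(0L, dim = c(length(cells), n_trials, n_bins))
  ci <- match(df$cell, cells)
  for (b in seq_len(n_bins))
    counts[cbind(ci, df$trial, b)] <- df[[bin_cols[b]]]
  list(counts = counts, cell_ids = cells)
}

#' Save a dataset bundle to a directory
#'
#' Writes the trial tables, long-format count tables, ground truth (when
#' present) and a JSON metadata sidecar, all as plain text.
#'
#' @param dataset A [make_fixture_dataset()]-style list.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(.counts_to_df(dataset$pop$counts, dataset$pop$cell_ids),
            file.path(dir, "counts.csv"), row.names = FALSE)
  if (!is.null(dataset$trials_instructed)) {
    write.csv(dataset$trials_instructed,
              file.path(dir, "trials_instructed.csv"), row.names = FALSE)
    write.csv(.counts_to_df(dataset$pop_instructed$counts,
                            dataset$pop_instructed$cell_ids),
              file.path(dir, "counts_instructed.csv"), row.names = FALSE)
  }
  if (!is.null(dataset$ground_truth))
    write.csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  meta <- list(preset = dataset$preset %||% "unknown",
               seed = dataset$seed %||% NA,
               bin_width_ms = dataset$pop$bin_width_ms,
               alignment = dataset$pop$alignment,
               n_cells = dim(dataset$pop$counts)[1])
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a dataset bundle from a directory
#'
#' Schema-validated round trip of [save_dataset()]: trial tables are checked
#' with [validate_trials()] (including the action-replay invariant) and count
#' tables must carry exactly 24 bin columns.
#'
#' @param dir Directory written by [save_dataset()].
#' @return A dataset list (`trials`, `pop`, optional instructed-task pair,
#'   `ground_truth`, `preset`).
#' @export
load_dataset <- function(dir) {
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("trials.csv")))
    stop("no trials.csv in ", dir)
  meta <- jsonlite::read_json(path("metadata.json"))
  trials <- validate_trials(read.csv(path("trials.csv")))
  cc <- .df_to_counts(read.csv(path("counts.csv")))
  if (nrow(trials) != dim(cc$counts)[2])
    stop("trial table and counts table disagree on trial count")
  out <- list(preset = meta$preset, seed = meta$seed, trials = trials,
              pop = binned_population(cc$counts, trials,
                                      cell_ids = cc$cell_ids,
                                      alignment = meta$alignment))
  if (file.exists(path("trials_instructed.csv"))) {
    ti <- validate_trials(read.csv(path("trials_instructed.csv")))
    cci <- .df_to_counts(read.csv(path("counts_instructed.csv")))
    out$trials_instructed <- ti
    out$pop_instructed <- binned_population(cci$counts, ti,
                                            cell_ids = cci$cell_ids,
                                            alignment = "instruction_onset")
  }
  if (file.exists(path("ground_truth.csv")))
    out$ground_truth <- read.csv(path("ground_truth.csv"))
  out
}

.write_stage_outputs <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(outdir, name); write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  put_json <- function(x, name) {
    f <- file.path(outdir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    files <<- c(files, f)
  }
  if (!is.null(results$behavior)) {
    put_csv(results$behavior$performance, "behavior_performance.csv")
    put_csv(results$behavior$gaussian_fit, "behavior_gaussian_fit.csv")
    if (!is.null(results$behavior$size_effect))
      put_json(results$behavior$size_effect, "behavior_size_effect.json")
    put_csv(results$behavior$rt_congruency, "behavior_rt_congruency.csv")
  }
  if (!is.null(results$encoding)) {
    put_csv(results$encoding$categories, "cell_categories.csv")
    if (!is.null(results$encoding$tracking))
      put_json(results$encoding$tracking[c("fraction_from", "fraction_to",
                                           "b", "c", "n", "p_value")],
               "exclusive_arithmetic_tracking.json")
  }
  if (!is.null(results$roc)) {
    traj <- results$roc$trajectories
    long <- expand.grid(cell = traj$cells, factor = traj$factors,
                        bin = seq_len(dim(traj$auc)[3]))
    long$auc <- as.vector(traj$auc)
    put_csv(long, "roc_trajectories.csv")
    put_csv(as.data.frame(results$roc$relative_variance),
            "roc_relative_variance.csv")
    put_csv(results$roc$coders, "simultaneous_coders.csv")
    if (!is.null(results$roc$quadrants)) {
      put_csv(results$roc$quadrants$table, "quadrant_timecourse.csv")
      put_json(results$roc$quadrants[c("right", "left", "n_selected")],
               "quadrant_summary.json")
    }
  }
  if (!is.null(results$decoding)) {
    dec <- results$decoding
    put_csv(as.data.frame(dec$grid_arithmetic$accuracy),
            "decode_arithmetic_accuracy.csv")
    put_csv(as.data.frame(dec$grid_hand$accuracy),
            "decode_hand_accuracy.csv")
    if (!is.null(dec$cross_arith_to_hand$mask)) {
      put_csv(as.data.frame(dec$cross_arith_to_hand$mask * 1L),
              "cross_arith_to_hand_mask.csv")
      put_json(dec$summary_arith_to_hand, "cross_arith_to_hand_summary.json")
      put_csv(as.data.frame(dec$cross_hand_to_arith$mask * 1L),
              "cross_hand_to_arith_mask.csv")
      put_json(dec$summary_hand_to_arith, "cross_hand_to_arith_summary.json")
    }
  }
  files
}

#' Run the full analysis pipeline
#'
#' Synthetic generation (or dataset loading), behavioural statistics, binwise
#' encoding classification, population ROC dynamics, and cross-training
#' decoding; every stage's outputs are written under `config$outdir`
#' together with a machine-readable manifest (config, seed, package version,
#' stage timings, per-file MD5 hashes). Identical (config, seed) pairs yield
#' identical output hashes.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle: `dataset`, `behavior`, `encoding`, `roc`,
#'   `decoding`, `manifest`.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  t_all <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    t_all[[stage]] <<- round(proc.time()[3] - t0, 3)
    out
  }
  set.seed(config$seed)
  dataset <- tick("data", {
    if (!is.null(config$input)) load_dataset(config$input)
    else make_fixture_dataset(config$preset, seed = config$seed,
                              n_cells = config$n_cells,
                              n_trials = config$n_trials)
  })
  results <- list(dataset = dataset)
  results$behavior <- tick("behavior",
    behavior_stage(dataset$trials_all %||% dataset$trials,
                   dataset$trials_instructed_all %||% dataset$trials_instructed))
  results$encoding <- tick("encoding",
    encoding_stage(dataset$pop, dataset$pop_instructed,
                   alpha = config$alpha_regression))
  arith_cells <- results$encoding$arithmetic_cells
  results$roc <- tick("roc", {
    if (length(arith_cells) >= 5)
      roc_stage(dataset$pop, arith_cells, n_perm = config$n_perm)
    else NULL
  })
  results$decoding <- tick("decoding", {
    cells <- if (length(arith_cells) >= 2) arith_cells
             else seq_len(dim(dataset$pop$counts)[1])
    tryCatch(
      decoding_stage(dataset$pop, cells, n_perm = config$n_perm,
                     folds = config$folds,
                     min_per_condition = config$min_per_condition,
                     within_perm = config$within_perm),
      error = function(e) { warning("decoding skipped: ",
                                    conditionMessage(e)); NULL })
  })
  files <- .write_stage_outputs(results, config$outdir)
  no_effects <- sum(results$encoding$categories$arithmetic_selective) <
    0.05 * nrow(results$encoding$categories)
  manifest <- list(
    package_version = as.character(utils::packageVersion("arithpop")),
    config = unclass(config), seed = config$seed,
    stage_timings_s = t_all,
    n_cells = dim(dataset$pop$counts)[1],
    n_arithmetic_selective = sum(results$encoding$categories$arithmetic_selective),
    note = if (no_effects) "no significant population effects" else "",
    files = data.frame(name = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  manifest_file <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  results
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `behavior`, `encode`, `roc`, `decode`, `all`.
#' Flags: `--preset`, `--input`, `--seed`, `--outdir`, `--n-cells`,
#' `--n-trials`, `--n-perm`, `--config` (JSON or YAML file of
#' [pipeline_config()] fields), `--verbose`. Flags override the config file.
#' Returns (invisibly) a process exit status: 0 on success, 2 on usage
#' errors, 1 on stage failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
arith_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: arithpop <simulate|behavior|encode|roc|decode|all> [options]",
    "  --preset <name>    synthetic preset (study_like|null|snarc_reuse|",
    "                     static_code|uncoupled)",
    "  --input <dir>      saved dataset directory (required for behavior/",
    "                     encode/roc/decode unless --preset is given)",
    "  --seed <int>       RNG seed (default 1)",
    "  --outdir <dir>     output directory",
    "  --n-cells <int>    synthetic population size",
    "  --n-trials <int>   synthetic trial count",
    "  --n-perm <int>     permutations",
    "  --config <file>    JSON/YAML config file",
    "  --verbose          progress logging", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "behavior", "encode", "roc", "decode", "all")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  opts <- list(); i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") { opts$verbose <- TRUE; i <- i + 1; next }
    if (!startsWith(a, "--") || i == length(args)) {
      message("bad option: ", a, "\n", usage); return(invisible(2L))
    }
    key <- gsub("-", "_", substring(a, 3))
    opts[[key]] <- args[i + 1]; i <- i + 2
  }
  cfg <- list()
  if (!is.null(opts$config)) {
    cfg <- if (grepl("\\.ya?ml$", opts$config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config needs the 'yaml' package; use JSON instead")
      yaml::read_yaml(opts$config)
    }
    else jsonlite::read_json(opts$config, simplifyVector = TRUE)
  }
  for (k in c("preset", "input", "outdir")) if (!is.null(opts[[k]]))
    cfg[[k]] <- opts[[k]]
  for (k in c("seed", "n_cells", "n_trials", "n_perm")) if (!is.null(opts[[k]]))
    cfg[[k]] <- as.integer(opts[[k]])
  config <- do.call(pipeline_config, cfg[intersect(names(cfg),
                                                   names(formals(pipeline_config)))])
  verbose <- isTRUE(opts$verbose)
  say <- function(...) if (verbose) message("[arithpop] ", ...)
  status <- tryCatch({
    if (cmd == "simulate") {
      say("generating preset '", config$preset, "'")
      make_fixture_dataset(config$preset, seed = config$seed,
                           n_cells = config$n_cells,
                           n_trials = config$n_trials, dir = config$outdir)
      say("dataset written to ", config$outdir)
      0L
    } else if (cmd == "all") {
      run_full_pipeline(config)
      say("pipeline complete; outputs in ", config$outdir)
      0L
    } else {
      if (is.null(config$input))
        stop("subcommand '", cmd, "' needs --input <dir> (a dataset saved ",
             "by 'simulate'); run 'arithpop simulate' first or use 'all'")
      dataset <- load_dataset(config$input)
      if (cmd == "behavior") {
        res <- behavior_stage(dataset$trials, dataset$trials_instructed)
        .write_stage_outputs(list(behavior = res), config$outdir)
      } else {
        enc <- encoding_stage(dataset$pop, dataset$pop_instructed,
                              alpha = config$alpha_regression)
        if (cmd == "encode") {
          .write_stage_outputs(list(encoding = enc), config$outdir)
        } else if (cmd == "roc") {
          res <- roc_stage(dataset$pop, enc$arithmetic_cells,
                           n_perm = config$n_perm)
          .write_stage_outputs(list(roc = res), config$outdir)
        } else {
          res <- decoding_stage(dataset$pop, enc$arithmetic_cells,
                                n_perm = config$n_perm,
                                folds = config$folds,
                                min_per_condition = config$min_per_condition,
                                within_perm = config$within_perm)
          .write_stage_outputs(list(decoding = res), config$outdir)
        }
      }
      0L
    }
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
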