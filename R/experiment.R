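#' Configuration of the D/L experiments
#'
#' Bundles everything that defines a full study: the fixed D/L sweep values
#' (default 0.4 to 1.1 in steps of 0.1), the distributed-D/L ranges
#' (default `[0.6, 1.0]`, `[0.7, 1.0]`, `[0.8, 1.0]`), the number of
#' stochastic runs per condition and of case-disjoint data splits (3 each),
#' the preprocessing constants (margin 25 px in the resized frame, input
#' size 448), the IoU threshold policy, detector-simulator overrides, and
#' the master seed. With the simulated detector the whole pipeline is a pure
#' function of the configuration.
#'
#' @param dl_values fixed D/L ratios to sweep (each in `(0, 2]`).
#' @param dl_ranges list of length-2 D/L ranges.
#' @param n_runs stochastic detector runs per condition (>= 1).
#' @param n_splits case-disjoint data splits.
#' @param test_fraction test share of images per split.
#' @param margin_final,input_size see [margin_pad_size()].
#' @param threshold a fixed IoU threshold (default 0.375) or `"calibrate"`
#'   to calibrate per split by discriminant analysis on the D/L = 1.0
#'   condition's IoU distribution.
#' @param behavior_args named list of overrides passed to
#'   [detector_behavior()] for every condition.
#' @param seed master seed; per-(stage, split, condition, run) child seeds
#'   are derived by stable hashing so added conditions never perturb
#'   existing ones.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dl_values = seq(0.4, 1.1, by = 0.1),
                              dl_ranges = list(c(0.6, 1.0), c(0.7, 1.0), c(0.8, 1.0)),
                              n_runs = 3,
                              n_splits = 3,
                              test_fraction = 0.2,
                              margin_final = 25,
                              input_size = 448,
                              threshold = 0.375,
                              behavior_args = list(),
                              seed = 1) {
  if (length(dl_values) > 0 && (any(dl_values <= 0) || any(dl_values > 2)))
    abort("dl_values must lie in (0, 2]")
  if (n_runs < 1) abort("n_runs must be >= 1")
  if (!identical(threshold, "calibrate") &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1))
    abort("threshold must be a value in (0, 1) or \"calibrate\"")
  structure(list(dl_values = dl_values, dl_ranges = dl_ranges,
                 n_runs = n_runs, n_splits = n_splits,
                 test_fraction = test_fraction,
                 margin_final = margin_final, input_size = input_size,
                 threshold = threshold, behavior_args = behavior_args,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# test images go through the same margin + resize chain as training images
# (no elimination, no flipping); GT is re-derived in this frame at D/L 1.0
prepare_test_frame <- function(annotations, config) {
  padded <- pad_with_margin(NULL, annotations, config$margin_final,
                            config$input_size)$annotations
  resize_with_annotations(NULL, padded, config$input_size)$annotations
}

make_behavior <- function(condition, config, key) {
  args <- c(list(training_dl = condition,
                 seed = child_seed(config$seed, "behavior", key)),
            config$behavior_args)
  do.call(detector_behavior, args)
}

resolve_threshold <- function(config, splits) {
  if (!identical(threshold <- config$threshold, "calibrate"))
    return(list(values = rep(threshold, config$n_splits), source = "fixed"))
  values <- vapply(seq_along(splits), function(s) {
    test <- prepare_test_frame(splits[[s]]$test, config)
    behavior <- make_behavior(dl_condition(1.0), config, c("calibration", s))
    preds <- simulate_detections(test, behavior, run_seed = 0)
    ev <- evaluate_dataset(test, preds, threshold = 0.5)
    as.numeric(calibrate_iou_threshold(ev))
  }, numeric(1))
  list(values = values, source = "discriminant_analysis_dl_1.0")
}

run_condition <- function(condition, label, splits, thresholds, config) {
  per_run <- list(); eliminations <- list()
  for (s in seq_along(splits)) {
    split <- splits[[s]]
    built <- build_training_set(split$training, condition,
                                config$margin_final, config$input_size,
                                seed = child_seed(config$seed, "dl_assign", s, label))
    eliminations[[length(eliminations) + 1L]] <-
      data.frame(condition = label, split = s, n_eliminated = built$n_eliminated)
    test <- prepare_test_frame(split$test, config)
    behavior <- make_behavior(condition, config, c(s, label))
    for (r in seq_len(config$n_runs)) {
      preds <- simulate_detections(test, behavior, run_seed = r)
      ev <- evaluate_dataset(test, preds, threshold = thresholds[s])
      m <- ev$metrics
      m$condition <- label; m$split <- s; m$run <- r
      per_run[[length(per_run) + 1L]] <- m
    }
  }
  list(per_run = do.call(rbind, per_run),
       eliminations = do.call(rbind, eliminations))
}

best_and_weighted <- function(per_run) {
  best <- do.call(rbind, lapply(split(per_run,
                                      per_run[, c("condition", "split")],
                                      drop = TRUE), function(m) {
    agg <- aggregate_runs(m)
    agg$condition <- m$condition[1]; agg$split <- m$split[1]
    agg
  }))
  rownames(best) <- NULL
  weighted <- do.call(rbind, lapply(split(best,
                                          best[, c("condition", "scope")],
                                          drop = TRUE), function(b) {
    data.frame(condition = b$condition[1], scope = b$scope[1],
               precision = weighted_average_across_datasets(b$precision, b$n_images),
               recall = weighted_average_across_datasets(b$recall, b$n_images),
               f1 = weighted_average_across_datasets(b$f1, b$n_images),
               fn = weighted_average_across_datasets(b$fn, b$n_images),
               fn_total = sum(b$fn), n_images = sum(b$n_images),
               stringsAsFactors = FALSE)
  }))
  rownames(weighted) <- NULL
  list(best_of_runs = best, weighted = weighted)
}

#' Run the fixed-D/L sweep
#'
#' For every fixed training D/L value: assign the condition to each split's
#' training images, run the preparation chain (recording how many images
#' are eliminated because their ROI exceeds the padded image), derive the
#' simulated detector's behavior from the condition, simulate `n_runs`
#' detection runs on the split's test set, and evaluate against the
#' D/L = 1.0 ground truth at the configured IoU threshold. Reports per-run
#' metrics, best-of-runs aggregates (max precision/recall/F1, min FN), and
#' per-type + total tables weighted across splits by test-image counts.
#'
#' @param annotations annotation `data.frame` (e.g. from
#'   [generate_phantom_dataset()]).
#' @param config an [experiment_config()].
#' @return An object of class `dl_sweep`: a list with `per_run`,
#'   `best_of_runs`, `weighted`, `eliminations`, `thresholds`, `splits`
#'   (per-split image counts) and `config`.
#' @export
run_dl_sweep <- function(annotations, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  splits <- case_wise_split(annotations, config$test_fraction, config$n_splits,
                            seed = child_seed(config$seed, "split"))
  thr <- resolve_threshold(config, splits)
  per_run <- list(); eliminations <- list()
  for (dl in config$dl_values) {
    res <- run_condition(dl_condition(dl), format(dl), splits, thr$values, config)
    per_run[[length(per_run) + 1L]] <- res$per_run
    eliminations[[length(eliminations) + 1L]] <- res$eliminations
  }
  per_run <- do.call(rbind, per_run)
  per_run$dl <- as.numeric(per_run$condition)
  agg <- best_and_weighted(per_run)
  agg$best_of_runs$dl <- as.numeric(agg$best_of_runs$condition)
  agg$weighted$dl <- as.numeric(agg$weighted$condition)
  structure(list(per_run = per_run,
                 best_of_runs = agg$best_of_runs,
                 weighted = agg$weighted,
                 eliminations = do.call(rbind, eliminations),
                 thresholds = thr,
                 splits = data.frame(
                   split = seq_along(splits),
                   n_training = vapply(splits, function(s) nrow(s$training), numeric(1)),
                   n_test = vapply(splits, function(s) nrow(s$test), numeric(1))),
                 config = config),
            class = "dl_sweep")
}

#' Run the distributed-D/L comparison
#'
#' For every configured D/L range, training D/L values are drawn uniformly
#' per image and the simulated detector's size noise and miss rate scale
#' with the range width; each range is evaluated like a sweep condition.
#' When a completed [run_dl_sweep()] result is supplied, the best fixed-D/L
#' row per split (per metric, with the D/L value it came from) is appended
#' for comparison.
#'
#' @param annotations annotation `data.frame`.
#' @param config an [experiment_config()].
#' @param sweep optional `dl_sweep` result providing the fixed-D/L baseline.
#' @return An object of class `distributed_dl`: a list with `per_run`,
#'   `best_of_runs`, `weighted`, `eliminations`, `fixed_best` (or `NULL`),
#'   `thresholds` and `config`.
#' @export
run_distributed_dl_experiment <- function(annotations,
                                          config = experiment_config(),
                                          sweep = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$dl_ranges) == 0)
    return(structure(list(per_run = NULL, best_of_runs = NULL, weighted = NULL,
                          eliminations = NULL, fixed_best = NULL,
                          thresholds = NULL, config = config),
                     class = "distributed_dl"))
  splits <- case_wise_split(annotations, config$test_fraction, config$n_splits,
                            seed = child_seed(config$seed, "split"))
  thr <- resolve_threshold(config, splits)
  per_run <- list(); eliminations <- list()
  for (rg in config$dl_ranges) {
    label <- sprintf("%g-%g", rg[1], rg[2])
    res <- run_condition(dl_condition(rg), label, splits, thr$values, config)
    per_run[[length(per_run) + 1L]] <- res$per_run
    eliminations[[length(eliminations) + 1L]] <- res$eliminations
  }
  per_run <- do.call(rbind, per_run)
  agg <- best_and_weighted(per_run)
  fixed_best <- NULL
  if (!is.null(sweep)) {
    tot <- sweep$best_of_runs[sweep$best_of_runs$scope == "total", ]
    fixed_best <- do.call(rbind, lapply(split(tot, tot$split), function(b) {
      data.frame(split = b$split[1],
                 fn = min(b$fn), fn_dl = b$dl[which.min(b$fn)],
                 precision = max(b$precision), precision_dl = b$dl[which.max(b$precision)],
                 recall = max(b$recall), recall_dl = b$dl[which.max(b$recall)])
    }))
    rownames(fixed_best) <- NULL
  }
  structure(list(per_run = per_run,
                 best_of_runs = agg$best_of_runs,
                 weighted = agg$weighted,
                 eliminations = do.call(rbind, eliminations),
                 fixed_best = fixed_best,
                 thresholds = thr,
                 config = config),
            class = "distributed_dl")
}

#' Write experiment reports to disk
#'
#' Writes deterministic CSV tables for a sweep and (optionally) a
#' distributed-D/L comparison, plus a JSON metadata file recording the
#' configuration, seed, threshold provenance and package version:
#' \itemize{
#'   \item `fig4_total_metrics.csv` — best-of-runs total precision/recall/F1
#'     per (D/L, split);
#'   \item `fig5_fn.csv` — best-of-runs (minimum) FN per (D/L, split);
#'   \item `fig7_per_type.csv` — per-type weighted averages across splits;
#'   \item `eliminations.csv` — images dropped per (condition, split);
#'   \item `table4_distributed.csv` — distributed ranges vs the best fixed
#'     D/L rows (when a distributed result is supplied);
#'   \item `run_metadata.json`.
#' }
#' D/L values above 1 are annotated `box_smaller_than_tumor` in the tables.
#'
#' @param sweep a `dl_sweep` result.
#' @param dir output directory (created if needed).
#' @param distributed optional `distributed_dl` result.
#' @return The vector of files written, invisibly.
#' @export
write_report <- function(sweep, dir, distributed = NULL) {
  stopifnot(inherits(sweep, "dl_sweep"))
  if (is.null(sweep$best_of_runs) || nrow(sweep$best_of_runs) == 0)
    abort("nothing to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort("cannot create report directory %s", dir)
  files <- character()
  w <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  tot <- sweep$best_of_runs[sweep$best_of_runs$scope == "total", ]
  tot <- tot[order(tot$dl, tot$split), ]
  tot$note <- ifelse(tot$dl > 1, "box_smaller_than_tumor", "")
  w(tot[, c("dl", "split", "precision", "recall", "f1", "n_images", "note")],
    "fig4_total_metrics.csv")
  w(tot[, c("dl", "split", "fn", "n_images", "note")], "fig5_fn.csv")
  per_type <- sweep$weighted[sweep$weighted$scope != "total", ]
  per_type <- per_type[order(per_type$dl, per_type$scope), ]
  w(per_type[, c("dl", "scope", "precision", "recall", "fn", "n_images")],
    "fig7_per_type.csv")
  w(sweep$eliminations, "eliminations.csv")
  if (!is.null(distributed) && !is.null(distributed$best_of_runs)) {
    db <- distributed$best_of_runs[distributed$best_of_runs$scope == "total", ]
    db <- db[order(db$split, db$condition), ]
    tab4 <- db[, c("split", "condition", "fn", "precision", "recall")]
    if (!is.null(distributed$fixed_best)) {
      fb <- distributed$fixed_best
      tab4 <- rbind(tab4, data.frame(
        split = fb$split,
        condition = sprintf("fixed_best (FN@%g, P@%g, R@%g)",
                            fb$fn_dl, fb$precision_dl, fb$recall_dl),
        fn = fb$fn, precision = fb$precision, recall = fb$recall))
      tab4 <- tab4[order(tab4$split), ]
    }
    w(tab4, "table4_distributed.csv")
  }
  meta <- list(package = "dlratio",
               version = as.character(packageVersion("dlratio")),
               config = unclass(sweep$config),
               threshold_source = sweep$thresholds$source,
               threshold_values = sweep$thresholds$values,
               splits = sweep$splits)
  meta_path <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, meta_path)
  invisible(files)
}
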