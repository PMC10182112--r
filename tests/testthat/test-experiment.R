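# shared, deliberately small phantom study used across experiment tests
phantom_ann <- generate_phantom_dataset(phantom_config(scale = 0.04, seed = 13))$annotations

noiseless_args <- list(miss_base = 0, miss_size_penalty = 0, miss_dl_coef = 0,
                       miss_range_coef = 0, center_jitter_sd = 0,
                       size_noise_base = 0, size_noise_range_coef = 0,
                       spurious_rate = 0, confidence_noise_sd = 0)

test_that("experiment configuration rejects invalid settings", {
  expect_error(experiment_config(dl_values = c(0.5, 2.5)), "\\(0, 2\\]")
  expect_error(experiment_config(n_runs = 0), "n_runs")
  expect_error(experiment_config(threshold = 1.2), "threshold")
  expect_s3_class(experiment_config(threshold = "calibrate"), "experiment_config")
})

test_that("child seeds are stable, distinct per key, and within integer range", {
  expect_identical(child_seed(1, "a", 2), child_seed(1, "a", 2))
  expect_false(child_seed(1, "a", 2) == child_seed(1, "a", 3))
  expect_false(child_seed(1, "a", 2) == child_seed(2, "a", 2))
  seeds <- vapply(1:500, function(i) child_seed(42, "cond", i), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2147483646))
  expect_gt(length(unique(seeds)), 490)
})

test_that("noiseless sweep reproduces the analytic IoU = rho^2 collapse", {
  cfg <- experiment_config(dl_values = seq(0.4, 1.0, by = 0.1), dl_ranges = list(),
                           n_runs = 1, behavior_args = noiseless_args, seed = 5)
  sw <- run_dl_sweep(phantom_ann, cfg)
  tot <- sw$per_run[sw$per_run$scope == "total", ]
  for (i in seq_len(nrow(tot))) {
    if (tot$dl[i] <= 0.6) {
      expect_equal(tot$tp[i], 0)
      expect_equal(tot$fp[i], tot$n_images[i])
    } else {
      expect_equal(tot$tp[i], tot$n_images[i])
      expect_equal(tot$recall[i], 1)
    }
  }
  expect_true(all(tot$fn == 0))
})

test_that("sweep output is reproducible and internally consistent", {
  cfg <- experiment_config(dl_values = c(0.6, 0.9), dl_ranges = list(),
                           n_runs = 2, seed = 11)
  sw1 <- run_dl_sweep(phantom_ann, cfg)
  sw2 <- run_dl_sweep(phantom_ann, cfg)
  expect_identical(sw1$per_run, sw2$per_run)
  # per-type rows partition the totals for every (dl, split, run)
  pr <- sw1$per_run
  for (key in split(pr, pr[, c("dl", "split", "run")], drop = TRUE)) {
    tot <- key[key$scope == "total", ]
    typ <- key[key$scope != "total", ]
    expect_equal(sum(typ$tp + typ$fp + typ$fn), tot$n_images)
    expect_equal(sum(typ$fn), tot$fn)
  }
  # best-of-runs never falls below any single run
  best <- sw1$best_of_runs[sw1$best_of_runs$scope == "total", ]
  for (i in seq_len(nrow(best))) {
    rows <- pr[pr$scope == "total" & pr$dl == best$dl[i] & pr$split == best$split[i], ]
    expect_gte(best$recall[i], max(rows$recall))
    expect_lte(best$fn[i], min(rows$fn))
  }
})

test_that("degenerate distributed range equals the fixed condition it collapses to", {
  b_range <- detector_behavior(c(0.9, 0.9), seed = 3)
  b_fixed <- detector_behavior(0.9, seed = 3)
  test <- phantom_ann[1:60, ]
  expect_equal(simulate_detections(test, b_range, 1),
               simulate_detections(test, b_fixed, 1))
})

test_that("distributed experiment orders ranges and handles the empty case", {
  cfg <- experiment_config(dl_values = c(0.9), seed = 17)
  di <- run_distributed_dl_experiment(phantom_ann, cfg)
  tot <- di$weighted[di$weighted$scope == "total", ]
  tot <- tot[order(tot$condition), ]   # "0.6-1", "0.7-1", "0.8-1"
  expect_equal(tot$condition, c("0.6-1", "0.7-1", "0.8-1"))
  expect_true(all(diff(tot$recall) > 0))
  expect_true(all(diff(tot$fn) < 0))

  empty <- run_distributed_dl_experiment(phantom_ann,
                                         experiment_config(dl_ranges = list()))
  expect_s3_class(empty, "distributed_dl")
  expect_null(empty$per_run)
})

test_that("threshold calibration mode records provenance and plausible cuts", {
  cfg <- experiment_config(dl_values = c(0.9), dl_ranges = list(), n_runs = 1,
                           threshold = "calibrate", seed = 19)
  sw <- run_dl_sweep(phantom_ann, cfg)
  expect_equal(sw$thresholds$source, "discriminant_analysis_dl_1.0")
  expect_length(sw$thresholds$values, 3)
  expect_true(all(sw$thresholds$values > 0 & sw$thresholds$values < 1))
})

test_that("reports are deterministic files with the expected shapes", {
  cfg <- experiment_config(dl_values = seq(0.4, 1.1, by = 0.1),
                           dl_ranges = list(c(0.8, 1.0)), n_runs = 1, seed = 23)
  sw <- run_dl_sweep(phantom_ann, cfg)
  di <- run_distributed_dl_experiment(phantom_ann, cfg, sweep = sw)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  files1 <- write_report(sw, dir1, distributed = di)
  write_report(sw, dir2, distributed = di)
  for (f in basename(files1)) {
    expect_true(file.exists(file.path(dir2, f)))
    if (grepl("[.]csv$", f))
      expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  fig4 <- read.csv(file.path(dir1, "fig4_total_metrics.csv"))
  expect_equal(nrow(fig4), 8 * 3)         # 8 dl values x 3 splits, total scope
  expect_true(all(fig4$note[fig4$dl > 1] == "box_smaller_than_tumor"))
  meta <- jsonlite::read_json(file.path(dir1, "run_metadata.json"))
  expect_equal(meta$threshold_source, "fixed")
  tab4 <- read.csv(file.path(dir1, "table4_distributed.csv"))
  expect_true(any(grepl("fixed_best", tab4$condition)))
})
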