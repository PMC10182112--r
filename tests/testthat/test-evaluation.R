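test_that("IoU matches hand values and the rasterization oracle", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box(20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, bounding_box(5, 0, 15, 10)), 1 / 3)
  expect_equal(box_iou(a, bounding_box(5, 0, 15, 10)),
               rasterized_iou(a, bounding_box(5, 0, 15, 10)))
  # symmetry and range on random pairs
  withr::with_seed(5, {
    A <- random_boxes(200)
    B <- random_boxes(200)
    iou <- box_iou(A, B)
    expect_equal(iou, box_iou(B, A))
    expect_true(all(iou >= 0 & iou <= 1))
  })
})

test_that("the single evaluated detection follows the confidence-in-positive-IoU rule", {
  gt <- bounding_box(0, 0, 10, 10)
  dets <- data.frame(image_id = "i",
                     x_min = c(0, 50), y_min = c(0, 50),
                     x_max = c(8, 60), y_max = c(10, 60),
                     confidence = c(0.6, 0.9))
  sel <- select_evaluated_detection(dets, gt)
  expect_equal(sel$index, 1)            # overlap beats higher confidence
  expect_equal(sel$iou, 0.8)

  far <- data.frame(image_id = "i",
                    x_min = c(50, 70), y_min = c(50, 70),
                    x_max = c(60, 80), y_max = c(60, 80),
                    confidence = c(0.3, 0.9))
  sel0 <- select_evaluated_detection(far, gt)
  expect_equal(sel0$index, 2)           # all IoU 0: highest confidence
  expect_equal(sel0$iou, 0)
  expect_null(select_evaluated_detection(far[0, ], gt))
})

test_that("outcome classification applies the threshold with TP on ties", {
  expect_equal(classify_outcome(c(0.5, 0.2, NA), 0.375), c("TP", "FP", "FN"))
  expect_equal(classify_outcome(0.375, 0.375), "TP")
  expect_equal(classify_outcome(0.375, 0.375, ties = "fp"), "FP")
  expect_error(classify_outcome(0.5, 0), "threshold")
})

test_that("discriminant-analysis threshold equals the exhaustive-search optimum", {
  t0 <- otsu_iou_threshold(c(0, 0, 0.9, 0.9))
  expect_equal(as.numeric(t0), 0.45)
  expect_error(otsu_iou_threshold(c(0.1, 0.1, 0.1)), "distinct")

  withr::with_seed(17, {
    for (rep in 1:20) {
      v <- switch(1 + rep %% 4,
                  runif(60),
                  c(rep(0, rpois(1, 15) + 1), runif(40, 0.3, 1)),
                  round(runif(50), 2),
                  pmin(pmax(c(rnorm(500, 0.1, 0.02), rnorm(500, 0.8, 0.02)), 0), 1))
      if (length(unique(v)) < 2) next
      res <- otsu_iou_threshold(v)
      # the returned cut attains the exhaustive-search maximum
      expect_equal(brute_between_var(v, res$threshold),
                   brute_between_var(v, brute_otsu(v)), tolerance = 1e-12)
      expect_equal(max(res$between_var), brute_between_var(v, res$threshold),
                   tolerance = 1e-12)
      # variance decomposition at every candidate cut
      expect_equal(res$between_var + res$within_var,
                   rep(res$total_var, length(res$candidates)),
                   tolerance = 1e-9)
    }
  })
  # clearly bimodal sample: threshold falls between the modes
  withr::with_seed(2, {
    bim <- pmin(pmax(c(rnorm(500, 0.1, 0.02), rnorm(500, 0.8, 0.02)), 0), 1)
    tt <- as.numeric(otsu_iou_threshold(bim))
    expect_gt(tt, 0.2); expect_lt(tt, 0.7)
    # fixed-bin mode agrees closely on a large sample
    tb <- as.numeric(otsu_iou_threshold(bim, method = "bins"))
    expect_lt(abs(tb - tt), 0.05)
  })
})

test_that("precision/recall/F1 handle edge cases and undefined denominators", {
  m <- precision_recall_f1(9, 1, 0)
  expect_equal(c(m$precision, m$recall, m$f1), c(0.9, 1.0, 18 / 19))
  empty <- precision_recall_f1(0, 0, 5)
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
  sym <- precision_recall_f1(10, 10, 10)
  expect_equal(c(sym$precision, sym$recall, sym$f1), c(0.5, 0.5, 0.5))
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("dataset evaluation matches perfect, empty and contained-box predictions", {
  ann <- make_fixture_annotations(n_cases_per_type = 5)
  gt <- make_ground_truth_box(ann, 1.0)
  perfect <- cbind(gt, confidence = 0.9)
  ev <- evaluate_dataset(ann, perfect)
  tot <- ev$metrics[ev$metrics$scope == "total", ]
  expect_equal(c(tot$precision, tot$recall, tot$fn), c(1, 1, 0))

  none <- perfect[0, ]
  ev0 <- evaluate_dataset(ann, none)
  tot0 <- ev0$metrics[ev0$metrics$scope == "total", ]
  expect_equal(tot0$fn, nrow(ann))
  expect_equal(tot0$recall, 0)
  expect_true(all(ev0$outcomes$iou == 0))   # FN recorded as IoU 0

  # noiseless rho = 0.5 detector: every IoU 0.25, all FP at 0.375
  halved <- simulate_detections(ann, noiseless_behavior(0.5), 1)
  evh <- evaluate_dataset(ann, halved, threshold = 0.375)
  toth <- evh$metrics[evh$metrics$scope == "total", ]
  expect_equal(toth$tp, 0)
  expect_equal(toth$fp, nrow(ann))
  expect_equal(unique(round(evh$outcomes$iou, 12)), 0.25)

  bad <- perfect; bad$image_id[1] <- "nonexistent"
  expect_error(evaluate_dataset(ann, bad), "nonexistent")
})

test_that("TP + FP + FN partitions the test set across scopes and thresholds", {
  ann <- make_fixture_annotations(n_cases_per_type = 6)
  withr::with_seed(23, {
    for (rep in 1:10) {
      b <- detector_behavior(runif(1, 0.4, 1.1), miss_base = runif(1, 0, 0.4),
                             spurious_rate = runif(1, 0, 0.3), seed = rep)
      preds <- simulate_detections(ann, b, rep)
      thr <- runif(1, 0.05, 0.95)
      ev <- evaluate_dataset(ann, preds, threshold = thr)
      tot <- ev$metrics[ev$metrics$scope == "total", ]
      expect_equal(tot$tp + tot$fp + tot$fn, nrow(ann))
      per_type <- ev$metrics[ev$metrics$scope != "total", ]
      expect_equal(sum(per_type$tp), tot$tp)
      expect_equal(sum(per_type$fp), tot$fp)
      expect_equal(sum(per_type$fn), tot$fn)
    }
  })
})

test_that("threshold monotonicity: TP falls, FP rises, FN fixed as threshold grows", {
  ann <- make_fixture_annotations(n_cases_per_type = 6)
  preds <- simulate_detections(ann, detector_behavior(0.7, seed = 4), 1)
  thresholds <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  res <- t(vapply(thresholds, function(t) {
    tot <- evaluate_dataset(ann, preds, threshold = t)$metrics
    unlist(tot[tot$scope == "total", c("tp", "fp", "fn")])
  }, numeric(3)))
  expect_true(all(diff(res[, "tp"]) <= 0))
  expect_true(all(diff(res[, "fp"]) >= 0))
  expect_equal(length(unique(res[, "fn"])), 1)
})

test_that("weighted averages and best-of-runs aggregation follow their definitions", {
  expect_equal(weighted_average_across_datasets(c(0.8, 0.8, 0.8), c(5, 1, 3)), 0.8)
  expect_equal(weighted_average_across_datasets(c(1, 0), c(1, 1)), 0.5)
  # recomputed by hand: (0.9*1550 + 0.6*1527 + 0.75*1550) / 4627
  expect_equal(weighted_average_across_datasets(c(0.9, 0.6, 0.75),
                                                c(1550, 1527, 1550)),
               3473.7 / 4627, tolerance = 1e-12)
  expect_equal(weighted_average_across_datasets(c(0.9, NA, 0.7), c(2, 5, 2)), 0.8)

  runs <- data.frame(run = 1:3, scope = "total",
                     precision = c(0.7, 0.75, 0.72),
                     recall = c(0.7, 0.8, 0.75),
                     f1 = c(0.70, 0.77, 0.73),
                     fn = c(300, 250, 280), n_images = 1000)
  agg <- aggregate_runs(runs)
  expect_equal(agg$recall, 0.8)
  expect_equal(agg$recall_run, 2)
  expect_equal(agg$fn, 250)
  expect_equal(agg$precision, 0.75)
  single <- aggregate_runs(runs[1, ])
  expect_equal(single$recall, runs$recall[1])
  identical_runs <- runs; identical_runs[2:3, 3:6] <- identical_runs[1, 3:6]
  expect_equal(aggregate_runs(identical_runs)$f1, runs$f1[1])
})
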