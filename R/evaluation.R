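#' Intersection over union of axis-aligned boxes
#'
#' The set-measure ratio `area(A intersect B) / area(A union B)` of two
#' axis-aligned boxes in continuous coordinates. Symmetric; 1 iff the boxes
#' coincide; 0 iff their interiors are disjoint. Vectorized over rows, with
#' recycling.
#'
#' @param a,b bounding-box `data.frame`s (columns `x_min`..`y_max`).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
#' @examples
#' box_iou(bounding_box(0, 0, 10, 10), bounding_box(5, 0, 15, 10))  # 1/3
box_iou <- function(a, b) {
  assert_cols(a, c("x_min", "y_min", "x_max", "y_max"), "a")
  assert_cols(b, c("x_min", "y_min", "x_max", "y_max"), "b")
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' Select the single evaluated detection for one image
#'
#' The matching rule when a detector emits several boxes for an image that
#' carries one annotated tumor: among detections with positive IoU against
#' the ground truth, evaluate the one with the highest confidence score; if
#' every detection has IoU 0, evaluate the highest-confidence one anyway
#' (it may be hitting an unannotated structure). An empty detection list
#' means the image is a false negative.
#'
#' @param detections predictions `data.frame` for a single image (possibly
#'   zero rows).
#' @param gt_box one-row ground-truth bounding box.
#' @return `NULL` when there is nothing to evaluate, else a list with
#'   `detection` (the selected row), `iou` and `index`.
#' @export
select_evaluated_detection <- function(detections, gt_box) {
  if (is.null(detections) || nrow(detections) == 0) return(NULL)
  ious <- box_iou(detections, gt_box[rep(1, nrow(detections)), , drop = FALSE])
  pos <- which(ious > 0)
  pool <- if (length(pos) > 0) pos else seq_len(nrow(detections))
  idx <- pool[which.max(detections$confidence[pool])]
  list(detection = detections[idx, , drop = FALSE], iou = ious[idx], index = idx)
}

#' Classify one image's evaluated detection as TP, FP or FN
#'
#' TP when the evaluated detection's IoU clears the threshold, FP when it
#' does not, FN when the detector emitted nothing (`iou = NA`). IoU exactly
#' equal to the threshold counts as TP by default (ties are measure-zero;
#' the convention is configurable).
#'
#' @param iou IoU of the evaluated detection, or `NA` for an empty image.
#' @param threshold IoU threshold in `(0, 1)`.
#' @param ties `"tp"` (default) or `"fp"`: side on which IoU == threshold falls.
#' @return Character vector over `{"TP", "FP", "FN"}`; vectorized over `iou`.
#' @export
classify_outcome <- function(iou, threshold = 0.375, ties = c("tp", "fp")) {
  ties <- match.arg(ties)
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  hit <- if (ties == "tp") iou >= threshold else iou > threshold
  ifelse(is.na(iou), "FN", ifelse(hit, "TP", "FP"))
}

#' Calibrate the IoU threshold by discriminant analysis (Otsu's method)
#'
#' Chooses the cut `t` of a 1-D IoU sample that maximizes the between-class
#' variance `sigma2_B(t) = w0 w1 (mu0 - mu1)^2` of the two classes
#' `{iou <= t}` and `{iou > t}` — discriminant analysis as used for image
#' binarization. False negatives must be included as IoU = 0 by the caller
#' (see [evaluate_dataset()], whose outcome table does this).
#'
#' Candidate cuts are midpoints between consecutive sorted unique values
#' (exact for finite samples) or, optionally, a fixed grid of bin edges on
#' `[0, 1]`. When several candidate cuts attain the maximum (the
#' between-class variance is constant across any empty gap between the two
#' classes), the center of the maximizing set is returned.
#'
#' @param values numeric IoU sample (including a 0 for every FN).
#' @param method `"midpoint"` (default) or `"bins"`.
#' @param n_bins number of bins for `method = "bins"`.
#' @return An object of class `otsu_threshold`: a list with `threshold`,
#'   `candidates`, `between_var` (the sigma2_B curve), `within_var` and
#'   `total_var`. `as.numeric()` extracts the threshold.
#' @export
#' @examples
#' as.numeric(otsu_iou_threshold(c(0, 0, 0.9, 0.9)))  # 0.45
otsu_iou_threshold <- function(values, method = c("midpoint", "bins"),
                               n_bins = 256) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 2 || length(unique(values)) < 2)
    abort("need at least two distinct IoU values to separate two classes")
  if (method == "midpoint") {
    u <- sort(unique(values))
    candidates <- (u[-1] + u[-length(u)]) / 2
  } else {
    candidates <- seq(0, 1, length.out = n_bins + 1)
    candidates <- candidates[-c(1, length(candidates))]
  }
  n <- length(values)
  mu <- mean(values)
  pop_var <- function(x) if (length(x) == 0) 0 else mean((x - mean(x))^2)
  stats_at <- vapply(candidates, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / n; w1 <- 1 - w0
    sb <- if (w0 == 0 || w1 == 0) 0 else w0 * w1 * (mean(lo) - mean(hi))^2
    sw <- w0 * pop_var(lo) + w1 * pop_var(hi)
    c(sb, sw)
  }, numeric(2))
  # the sigma2_B curve is flat across any gap between the two classes; every
  # cut on that plateau is optimal, so take the plateau's center
  sb <- stats_at[1, ]
  best <- which(sb >= max(sb) * (1 - 1e-12))
  structure(list(threshold = mean(candidates[best]),
                 candidates = candidates,
                 between_var = stats_at[1, ],
                 within_var = stats_at[2, ],
                 total_var = pop_var(values)),
            class = "otsu_threshold")
}

#' @export
as.double.otsu_threshold <- function(x, ...) x$threshold

#' @export
print.otsu_threshold <- function(x, ...) {
  cat(sprintf("<otsu_threshold> t = %.4f (max between-class variance %.5f over %d candidates)\n",
              x$threshold, max(x$between_var), length(x$candidates)))
  invisible(x)
}

#' Precision, recall and F1 from outcome counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. A metric whose denominator is zero is reported as
#' `NA` ("absent") rather than 0, so that averages can skip it instead of
#' being silently biased.
#'
#' @param tp,fp,fn non-negative counts.
#' @return A one-row `data.frame` with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
#' @examples
#' precision_recall_f1(9, 1, 0)   # precision 0.9, recall 1, F1 18/19
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f1 = f1)
}

#' Evaluate detector predictions against a test set
#'
#' Implements the single-threshold, one-detection-per-image protocol: the
#' ground truth of every test image is the square ROI built at
#' `test_dl` (fixed at 1.0 — the tangent box — so that training conditions
#' with enlarged ROIs cannot inflate their own scores), the evaluated
#' detection is chosen by [select_evaluated_detection()], and the image is
#' classified TP/FP/FN by [classify_outcome()]. Counts and metrics are
#' reported per tumor type and in total; the per-type rows partition the
#' totals.
#'
#' @param test_annotations annotation `data.frame` (one annotated tumor per
#'   image).
#' @param predictions predictions `data.frame`; every `image_id` must exist
#'   in the test set.
#' @param threshold IoU threshold (default 0.375, the discriminant-analysis
#'   calibration shipped as fallback) or an `otsu_threshold` object.
#' @param test_dl D/L at which the test ground truth is built (default 1.0).
#' @return An object of class `detection_evaluation`: a list with
#'   `outcomes` (per image: `image_id`, `tumor_type`, `outcome`, `iou`,
#'   `confidence` and evaluated box corners; FN rows carry `iou = 0`),
#'   `metrics` (per-type + total rows of [precision_recall_f1()] with a
#'   `scope` column), `threshold` and `test_dl`.
#' @export
evaluate_dataset <- function(test_annotations, predictions,
                             threshold = 0.375, test_dl = 1.0) {
  if (inherits(threshold, "otsu_threshold")) threshold <- as.numeric(threshold)
  validate_annotations(test_annotations)
  assert_cols(predictions, c("image_id", "x_min", "y_min", "x_max", "y_max",
                             "confidence"))
  ann <- test_annotations[!duplicated(test_annotations$image_id), , drop = FALSE]
  unknown <- setdiff(unique(predictions$image_id), ann$image_id)
  if (length(unknown) > 0)
    abort("predictions reference image(s) absent from the test set: %s",
          paste(head(unknown, 10), collapse = ", "))
  gt <- make_ground_truth_box(ann, test_dl)
  dets_by_image <- split(predictions, predictions$image_id)
  n <- nrow(ann)
  outcome <- character(n); iou <- numeric(n); conf <- rep(NA_real_, n)
  bx <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("x_min", "y_min", "x_max", "y_max")))
  for (i in seq_len(n)) {
    sel <- select_evaluated_detection(dets_by_image[[ann$image_id[i]]],
                                      gt[i, , drop = FALSE])
    if (is.null(sel)) {
      outcome[i] <- "FN"; iou[i] <- 0        # FN recorded as IoU = 0
    } else {
      outcome[i] <- classify_outcome(sel$iou, threshold)
      iou[i] <- sel$iou
      conf[i] <- sel$detection$confidence
      bx[i, ] <- unlist(sel$detection[1, c("x_min", "y_min", "x_max", "y_max")])
    }
  }
  outcomes <- data.frame(image_id = ann$image_id, tumor_type = ann$tumor_type,
                         outcome = outcome, iou = iou, confidence = conf,
                         bx, stringsAsFactors = FALSE)
  scopes <- c(tumor_types, "total")
  metrics <- do.call(rbind, lapply(scopes, function(sc) {
    rows <- if (sc == "total") outcomes else outcomes[outcomes$tumor_type == sc, ]
    m <- precision_recall_f1(sum(rows$outcome == "TP"), sum(rows$outcome == "FP"),
                             sum(rows$outcome == "FN"))
    cbind(scope = sc, m, n_images = nrow(rows))
  }))
  structure(list(outcomes = outcomes, metrics = metrics,
                 threshold = threshold, test_dl = test_dl),
            class = "detection_evaluation")
}

#' @export
print.detection_evaluation <- function(x, ...) {
  cat(sprintf("<detection_evaluation> %d images, IoU threshold %.3f, test D/L %.2f\n",
              nrow(x$outcomes), x$threshold, x$test_dl))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Weighted average of a metric across data sets
#'
#' `sum(w v) / sum(w)` with the weights being each data set's number of test
#' images. Pairs whose value is `NA` (an undefined metric) are skipped
#' together with their weights.
#'
#' @param values per-dataset metric values.
#' @param weights per-dataset test-image counts (positive, same length).
#' @return A single numeric.
#' @export
#' @examples
#' weighted_average_across_datasets(c(0.9, 0.6, 0.75), c(1550, 1527, 1550))
weighted_average_across_datasets <- function(values, weights) {
  if (length(values) != length(weights)) abort("values and weights differ in length")
  if (any(weights <= 0)) abort("weights must be positive")
  keep <- !is.na(values)
  if (!any(keep)) return(NA_real_)
  sum(values[keep] * weights[keep]) / sum(weights[keep])
}

#' Best-of-runs aggregation of evaluation metrics
#'
#' Detector runs are stochastic, so each condition is run several times and
#' the reported figures are the maximum of precision, recall and F1 and the
#' minimum of FN over the runs — each extremum taken independently, possibly
#' from different runs; the contributing run index is recorded per metric.
#'
#' @param metrics a `data.frame` of per-run metric rows (as `$metrics` of
#'   [evaluate_dataset()]) with a `run` column; any `scope` values present
#'   are aggregated separately.
#' @return A `data.frame` with one row per scope: `precision`, `recall`,
#'   `f1` maxima, `fn` minimum, and `*_run` columns naming the run each came
#'   from.
#' @export
aggregate_runs <- function(metrics) {
  assert_cols(metrics, c("run", "precision", "recall", "f1", "fn"))
  if (!"scope" %in% names(metrics)) metrics$scope <- "total"
  pick <- function(v, runs, best) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    i <- if (best == "max") which.max(v) else which.min(v)
    c(v[i], runs[i])
  }
  do.call(rbind, lapply(split(metrics, metrics$scope), function(m) {
    p <- pick(m$precision, m$run, "max")
    r <- pick(m$recall, m$run, "max")
    f <- pick(m$f1, m$run, "max")
    fn <- pick(m$fn, m$run, "min")
    data.frame(scope = m$scope[1], n_runs = nrow(m),
               precision = p[1], precision_run = p[2],
               recall = r[1], recall_run = r[2],
               f1 = f[1], f1_run = f[2],
               fn = fn[1], fn_run = fn[2],
               n_images = if ("n_images" %in% names(m)) m$n_images[1] else NA,
               stringsAsFactors = FALSE)
  }))
}

#' Calibrate the IoU threshold from an evaluation's IoU distribution
#'
#' Convenience wrapper: takes the per-image outcome table of an evaluation
#' run (which records IoU = 0 for every FN) and applies
#' [otsu_iou_threshold()] to its IoU column.
#'
#' @param evaluation a `detection_evaluation` or its `outcomes` `data.frame`.
#' @param ... passed to [otsu_iou_threshold()].
#' @return An `otsu_threshold` object.
#' @export
calibrate_iou_threshold <- function(evaluation, ...) {
  outcomes <- if (inherits(evaluation, "detection_evaluation"))
    evaluation$outcomes else evaluation
  assert_cols(outcomes, "iou")
  otsu_iou_threshold(outcomes$iou, ...)
}
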