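#' Describe a simulated detector conditioned on its training D/L
#'
#' The simulator stands in for a trained one-class tumor detector and encodes
#' how detection behavior depends on the D/L condition of the training
#' ground truth. Its load-bearing assumption is that the predicted box side
#' tracks the training ROI scale: boxes come out larger as the training D/L
#' shrinks, so the systematic size factor is `1 / mean(training D/L)`
#' (`size_bias`). Around that: lognormal size noise whose spread grows with
#' the width of the training D/L range, Gaussian center jitter proportional
#' to the tumor diameter, a miss (false-negative) probability with extra
#' penalties for very small and very large tumors and for training
#' conditions far from the D/L ~ 0.9 optimum or spread over a wide range,
#' occasional spurious non-tumor detections, and a confidence score that
#' decreases with the realized localization error.
#'
#' @param training_dl the training [dl_condition()] (or coercible value).
#' @param miss_base baseline miss probability.
#' @param miss_size_penalty extra miss probability for tumors with
#'   `D < small_frac * image` or `D > large_frac * image`.
#' @param small_frac,large_frac diameter cutoffs as fractions of image size.
#' @param miss_dl_coef extra miss probability per unit `|mean D/L - dl_opt|`.
#' @param miss_range_coef extra miss probability per unit range width.
#' @param dl_opt training D/L with the lowest miss rate.
#' @param center_jitter_sd center jitter s.d. as a fraction of D.
#' @param size_noise_base lognormal s.d. of the box side at zero range width.
#' @param size_noise_range_coef added lognormal s.d. per unit range width.
#' @param spurious_rate probability of one additional non-tumor detection.
#' @param confidence_noise_sd s.d. of the confidence-score noise.
#' @param seed behavior seed, combined with the per-run seed in
#'   [simulate_detections()].
#' @return An object of class `detector_behavior`.
#' @export
#' @examples
#' detector_behavior(0.8)               # trained at fixed D/L 0.8
#' detector_behavior(c(0.6, 1.0))       # trained on a distributed D/L
#' noiseless_behavior(0.5)              # deterministic containment regime
detector_behavior <- function(training_dl,
                              miss_base = 0.08,
                              miss_size_penalty = 0.25,
                              small_frac = 0.04,
                              large_frac = 0.55,
                              miss_dl_coef = 0.3,
                              miss_range_coef = 0.3,
                              dl_opt = 0.9,
                              center_jitter_sd = 0.05,
                              size_noise_base = 0.08,
                              size_noise_range_coef = 0.25,
                              spurious_rate = 0.05,
                              confidence_noise_sd = 0.05,
                              seed = 1) {
  cond <- dl_condition(training_dl)
  mdl <- dl_mean(cond)
  width <- dl_width(cond)
  b <- list(training_dl = cond,
            miss_base = miss_base,
            miss_size_penalty = miss_size_penalty,
            small_frac = small_frac, large_frac = large_frac,
            miss_condition = miss_dl_coef * abs(mdl - dl_opt) + miss_range_coef * width,
            center_jitter_sd = center_jitter_sd,
            size_bias = 1 / mdl,
            size_noise_sd = size_noise_base + size_noise_range_coef * width,
            spurious_rate = spurious_rate,
            confidence_noise_sd = confidence_noise_sd,
            seed = as.integer(seed))
  probs <- c(b$miss_base, b$miss_size_penalty, b$spurious_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (b$size_bias <= 0) abort("size_bias must be positive")
  structure(b, class = "detector_behavior")
}

#' @rdname detector_behavior
#' @param ... passed on to [detector_behavior()].
#' @export
noiseless_behavior <- function(training_dl, ...) {
  detector_behavior(training_dl, miss_base = 0, miss_size_penalty = 0,
                    miss_dl_coef = 0, miss_range_coef = 0,
                    center_jitter_sd = 0, size_noise_base = 0,
                    size_noise_range_coef = 0, spurious_rate = 0,
                    confidence_noise_sd = 0, ...)
}

#' @export
print.detector_behavior <- function(x, ...) {
  cat(sprintf("<detector_behavior> size_bias %.3f, size_noise_sd %.3f, miss %.3f (+%.3f condition)\n",
              x$size_bias, x$size_noise_sd, x$miss_base, x$miss_condition))
  invisible(x)
}

#' Simulate detector outputs on a test set
#'
#' For each test image: with the behavior's miss probability the detector
#' emits nothing (a false negative); otherwise it emits one tumor-aimed
#' square box with side `D * size_bias * exp(eps)`,
#' `eps ~ Normal(0, size_noise_sd)`, its center jittered per axis by
#' `Normal(0, center_jitter_sd * D)`, and a confidence score decreasing in
#' the realized localization error. With probability `spurious_rate` an
#' additional low-confidence box is placed so as not to overlap the
#' annotated tumor (emulating detections of unannotated structures such as
#' vessels). Output is reproducible under `(behavior$seed, run_seed)`.
#'
#' Boxes are emitted in the annotations' own frame: if the annotations carry
#' `scale_x`/`scale_y` columns from [resize_with_annotations()], the
#' detector sees the tumor at its resized extent, exactly like a detector
#' operating on the resized pixels would.
#'
#' @param test_annotations annotation `data.frame` (one annotated tumor per
#'   image) with image dimension columns.
#' @param behavior a [detector_behavior()].
#' @param run_seed integer per-run seed (runs re-randomize the noise only).
#' @return A predictions `data.frame`: `image_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence` — zero or more rows per image.
#' @export
simulate_detections <- function(test_annotations, behavior, run_seed = 1) {
  stopifnot(inherits(behavior, "detector_behavior"))
  validate_annotations(test_annotations)
  assert_cols(test_annotations, c("image_width", "image_height"))
  ann <- test_annotations[!duplicated(test_annotations$image_id), , drop = FALSE]
  # tumor extent in the annotations' (possibly resized) frame, per axis
  Dx_all <- ann$max_diameter * (ann$scale_x %||% 1)
  Dy_all <- ann$max_diameter * (ann$scale_y %||% 1)
  rows <- withr::with_seed(child_seed(behavior$seed, "run", run_seed), {
    out <- vector("list", nrow(ann))
    for (i in seq_len(nrow(ann))) {
      Dx <- Dx_all[i]; Dy <- Dy_all[i]
      W <- ann$image_width[i]; H <- ann$image_height[i]
      p_miss <- clamp(behavior$miss_base + behavior$miss_condition +
                        ifelse(Dx < behavior$small_frac * W |
                                 Dx > behavior$large_frac * W,
                               behavior$miss_size_penalty, 0), 0, 1)
      dets <- NULL
      if (runif(1) >= p_miss) {
        eps <- rnorm(1, 0, behavior$size_noise_sd)
        side_x <- Dx * behavior$size_bias * exp(eps)
        side_y <- Dy * behavior$size_bias * exp(eps)
        cx <- ann$center_x[i] + rnorm(1, 0, behavior$center_jitter_sd * Dx)
        cy <- ann$center_y[i] + rnorm(1, 0, behavior$center_jitter_sd * Dy)
        err <- sqrt((cx - ann$center_x[i])^2 + (cy - ann$center_y[i])^2) /
          ((Dx + Dy) / 2) + abs(eps)
        conf <- clamp(0.9 - 0.6 * err + rnorm(1, 0, behavior$confidence_noise_sd),
                      0.05, 0.99)
        dets <- data.frame(image_id = ann$image_id[i],
                           x_min = cx - side_x / 2, y_min = cy - side_y / 2,
                           x_max = cx + side_x / 2, y_max = cy + side_y / 2,
                           confidence = conf, stringsAsFactors = FALSE)
      }
      if (runif(1) < behavior$spurious_rate) {
        sp <- place_spurious_box(ann[i, ], W, H)
        if (!is.null(sp)) {
          sp$image_id <- ann$image_id[i]
          dets <- rbind(dets, sp[, c("image_id", "x_min", "y_min",
                                     "x_max", "y_max", "confidence")])
        }
      }
      out[[i]] <- dets
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(image_id = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(), y_max = numeric(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# a square box not overlapping the tumor's tangent (D/L = 1) box
place_spurious_box <- function(ann_row, W, H) {
  tumor <- make_ground_truth_box(ann_row, 1.0)
  for (i in seq_len(50)) {
    side <- runif(1, 0.05, 0.2) * W
    cx <- runif(1, side / 2, W - side / 2)
    cy <- runif(1, side / 2, H - side / 2)
    cand <- data.frame(x_min = cx - side / 2, y_min = cy - side / 2,
                       x_max = cx + side / 2, y_max = cy + side / 2)
    if (box_iou(cand, tumor[, c("x_min", "y_min", "x_max", "y_max")]) == 0) {
      cand$confidence <- runif(1, 0.05, 0.5)
      return(cand)
    }
  }
  NULL
}

#' Read / write detector prediction files
#'
#' CSV with one row per detection: `image_id`, box corners and `confidence`.
#' The same format is accepted from external detectors (e.g. converted YOLO
#' output), keeping the evaluation detector-agnostic.
#'
#' @param path file path.
#' @param predictions predictions `data.frame`.
#' @return `read_predictions()` returns the predictions `data.frame`;
#'   `write_predictions()` returns `path` invisibly.
#' @export
read_predictions <- function(path) {
  pred <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(image_id = "character"))
  assert_cols(pred, c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence"))
  if (nrow(pred) > 0 && (any(pred$confidence < 0) || any(pred$confidence > 1)))
    abort("confidence scores must lie in [0, 1]")
  pred
}

#' @rdname read_predictions
#' @export
write_predictions <- function(predictions, path) {
  assert_cols(predictions, c("image_id", "x_min", "y_min", "x_max", "y_max",
                             "confidence"))
  write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
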