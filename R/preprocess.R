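#' Per-side pad amount for a target margin in the resized frame
#'
#' The background margin is specified at the *output* scale: after the final
#' resize to `input_size` x `input_size`, the margin must occupy
#' `margin_final` px on each side. For an original extent `d` the per-side
#' pad at the original scale is therefore
#' `m = d * margin_final / (input_size - 2 * margin_final)`.
#'
#' @param extent original image extent along one axis (px).
#' @param margin_final margin in the resized frame (px per side; default 25).
#' @param input_size side of the square network input (default 448).
#' @return Per-side pad amount at the original scale (px).
#' @export
#' @examples
#' margin_pad_size(398)  # exactly 25: 398 * 25 / (448 - 50)
margin_pad_size <- function(extent, margin_final = 25, input_size = 448) {
  if (margin_final < 0) abort("margin_final must be >= 0")
  if (margin_final >= input_size / 2)
    abort("margin_final (%g) must be < input_size/2 (%g); the margin would consume the whole image",
          margin_final, input_size / 2)
  extent * margin_final / (input_size - 2 * margin_final)
}

#' Pad an image with a background margin, shifting annotations
#'
#' Adds a zero-intensity background border on all four sides so that, after
#' the final resize to `input_size`, the border occupies exactly
#' `margin_final` px per side (see [margin_pad_size()]). Annotation centers
#' (and box corners, if box columns are present) are shifted by the per-side
#' pad; image dimension columns are updated.
#'
#' @param image optional grayscale raster, a numeric matrix indexed
#'   `[x, y]` with values in `[0, 1]`; `NULL` for annotation-only use.
#' @param annotations annotation `data.frame` with `image_width` /
#'   `image_height` columns.
#' @param margin_final,input_size see [margin_pad_size()].
#' @return A list with `image` (padded matrix or `NULL`), `annotations`
#'   (shifted), and `pad` (`c(x, y)` per-side pad actually applied, px).
#' @export
pad_with_margin <- function(image = NULL, annotations, margin_final = 25,
                            input_size = 448) {
  validate_annotations(annotations)
  assert_cols(annotations, c("image_width", "image_height"))
  pad_x <- margin_pad_size(annotations$image_width, margin_final, input_size)
  pad_y <- margin_pad_size(annotations$image_height, margin_final, input_size)
  out <- annotations
  out$center_x <- out$center_x + pad_x
  out$center_y <- out$center_y + pad_y
  for (col in c("x_min", "x_max")) if (col %in% names(out)) out[[col]] <- out[[col]] + pad_x
  for (col in c("y_min", "y_max")) if (col %in% names(out)) out[[col]] <- out[[col]] + pad_y
  out$image_width <- out$image_width + 2 * pad_x
  out$image_height <- out$image_height + 2 * pad_y
  padded <- NULL
  if (!is.null(image)) {
    if (length(unique(annotations$image_id)) > 1)
      abort("pixel-level padding takes the annotations of a single image")
    px <- round(pad_x[1]); py <- round(pad_y[1])
    padded <- matrix(0, nrow = nrow(image) + 2 * px, ncol = ncol(image) + 2 * py)
    padded[px + seq_len(nrow(image)), py + seq_len(ncol(image))] <- image
  }
  list(image = padded, annotations = out, pad = c(x = pad_x[1], y = pad_y[1]))
}

#' Resize an image to the network input size, rescaling annotations
#'
#' Anisotropic resize to `target` x `target` px by bilinear interpolation
#' (via EBImage). Annotation x coordinates are scaled by `target / width` and
#' y by `target / height`; the cumulative per-axis scale factors are recorded
#' in `scale_x` / `scale_y` columns so that square ground-truth boxes can be
#' re-derived in the resized frame by [make_ground_truth_box()]. Box corner
#' columns, if present, are scaled per axis.
#'
#' @param image optional grayscale matrix indexed `[x, y]`; `NULL` for
#'   annotation-only use.
#' @param annotations annotation `data.frame` with image dimension columns.
#' @param target side of the square output (px; default 448).
#' @return A list with `image` (resized matrix or `NULL`) and `annotations`.
#' @export
resize_with_annotations <- function(image = NULL, annotations, target = 448) {
  if (target <= 0) abort("target size must be positive")
  validate_annotations(annotations)
  assert_cols(annotations, c("image_width", "image_height"))
  sx <- target / annotations$image_width
  sy <- target / annotations$image_height
  out <- annotations
  out$center_x <- out$center_x * sx
  out$center_y <- out$center_y * sy
  for (col in c("x_min", "x_max")) if (col %in% names(out)) out[[col]] <- out[[col]] * sx
  for (col in c("y_min", "y_max")) if (col %in% names(out)) out[[col]] <- out[[col]] * sy
  out$scale_x <- (annotations$scale_x %||% 1) * sx
  out$scale_y <- (annotations$scale_y %||% 1) * sy
  out$image_width <- target
  out$image_height <- target
  resized <- NULL
  if (!is.null(image)) {
    if (length(unique(annotations$image_id)) > 1)
      abort("pixel-level resizing takes the annotations of a single image")
    resized <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                  w = target, h = target,
                                                  filter = "bilinear"))
  }
  list(image = resized, annotations = out)
}

#' Double a training set by horizontal flipping
#'
#' Appends a mirrored copy of every record: x coordinates map to
#' `width - x`, so mirrored centers are `width - center_x` and box corners
#' swap (`x_min' = width - x_max`). Flipping is an involution; applying it to
#' the mirrored half recovers the originals. The output is exactly twice the
#' input.
#'
#' @param annotations annotation `data.frame` with an `image_width` column.
#' @return A `data.frame` with `2 * nrow(annotations)` rows; the added rows
#'   have `flipped = TRUE` and `image_id` suffixed with `"_flip"`.
#' @export
horizontal_flip_augment <- function(annotations) {
  validate_annotations(annotations)
  assert_cols(annotations, "image_width")
  w <- annotations$image_width
  flipped <- annotations
  flipped$center_x <- w - flipped$center_x
  if (all(c("x_min", "x_max") %in% names(flipped))) {
    xmin <- w - annotations$x_max
    xmax <- w - annotations$x_min
    flipped$x_min <- xmin
    flipped$x_max <- xmax
  }
  flipped$image_id <- paste0(flipped$image_id, "_flip")
  annotations$flipped <- FALSE
  flipped$flipped <- TRUE
  rbind(annotations, flipped)
}

#' Mirror a grayscale image horizontally
#'
#' @param image numeric matrix indexed `[x, y]`.
#' @return The matrix with the x axis reversed.
#' @export
flip_image_horizontal <- function(image) image[rev(seq_len(nrow(image))), , drop = FALSE]

#' Case-wise train/test splitting into disjoint test partitions
#'
#' Produces `n_splits` train/test divisions of the data at roughly
#' `(1 - test_fraction) : test_fraction` by *whole cases*, so that no case
#' contributes images to both the training and test side of the same split
#' (ultrasound images from one case are highly similar) and the test sets of
#' the different splits are pairwise disjoint by image. Cases are stratified
#' by tumor type, shuffled under `seed`, and greedily packed into the test
#' partitions, each targeting `test_fraction` of that type's images; exact
#' fractions are unattainable with whole-case assignment, so the greedy
#' packing gets as close as case granularity allows. Each split's training
#' set is the complement of its own test partition (training sets of
#' different splits may overlap).
#'
#' @param annotations annotation `data.frame`.
#' @param test_fraction target fraction of images per test set (default 0.2).
#' @param n_splits number of splits with disjoint test sets (default 3).
#' @param seed integer seed for the case shuffle.
#' @return A list of `n_splits` lists, each with `split_index`, `training`
#'   and `test` annotation `data.frame`s.
#' @export
case_wise_split <- function(annotations, test_fraction = 0.2, n_splits = 3,
                            seed = 1) {
  validate_annotations(annotations)
  if (test_fraction <= 0 || n_splits < 1 || n_splits * test_fraction > 1)
    abort("need 0 < test_fraction and n_splits * test_fraction <= 1")
  case_type <- unique(annotations[, c("case_id", "tumor_type")])
  n_cases_type <- table(case_type$tumor_type)
  if (any(n_cases_type < 5))
    abort("every tumor type needs >= 5 cases to form %d disjoint ~%d%% test partitions; too few: %s",
          n_splits, round(100 * test_fraction),
          paste(names(n_cases_type)[n_cases_type < 5], collapse = ", "))
  images_per_case <- tapply(annotations$image_id, annotations$case_id,
                            function(x) length(unique(x)))
  # partition of case_ids: 0 = never in a test set, 1..n_splits = test set k
  assignment <- setNames(integer(nrow(case_type)), case_type$case_id)
  withr::with_seed(seed, {
    for (type in unique(case_type$tumor_type)) {
      cases <- case_type$case_id[case_type$tumor_type == type]
      cases <- sample(cases)
      target <- test_fraction * sum(images_per_case[cases])
      assigned <- numeric(n_splits)
      for (cs in cases) {
        deficit <- target - assigned
        k <- which.max(deficit)
        # assign only if it brings partition k closer to target than skipping
        if (deficit[k] > 0 && images_per_case[cs] < 2 * deficit[k]) {
          assignment[cs] <- k
          assigned[k] <- assigned[k] + images_per_case[cs]
        }
      }
    }
  })
  lapply(seq_len(n_splits), function(k) {
    test_cases <- names(assignment)[assignment == k]
    in_test <- annotations$case_id %in% test_cases
    list(split_index = k,
         training = annotations[!in_test, , drop = FALSE],
         test = annotations[in_test, , drop = FALSE])
  })
}

#' Build a prepared training set under a D/L condition
#'
#' Runs the data-preparation chain on an annotation table: assign D/L values
#' under `condition`; construct the square ground-truth boxes; pad with the
#' background margin; eliminate images whose ROI exceeds the padded image
#' area; resize the frame to `input_size` x `input_size` (annotations
#' rescaled, per-axis scales recorded); and double by horizontal flipping.
#' Smaller D/L means larger ROIs, so the elimination count is non-increasing
#' in D/L on a fixed input set.
#'
#' @param annotations annotation `data.frame` with image dimensions.
#' @param condition a [dl_condition()] (or coercible value).
#' @param margin_final,input_size see [margin_pad_size()].
#' @param seed seed for uniform-range D/L draws.
#' @return A list with `training` (prepared, flip-doubled annotations with
#'   `dl` and ground-truth box columns in the resized frame), `n_eliminated`,
#'   and `eliminated_image_ids`.
#' @export
build_training_set <- function(annotations, condition, margin_final = 25,
                               input_size = 448, seed = 1) {
  ann <- assign_dl_values(annotations, condition, seed = seed)
  gt <- make_ground_truth_box(ann, ann$dl)
  ann <- cbind(ann, gt[, c("x_min", "y_min", "x_max", "y_max")])
  padded <- pad_with_margin(NULL, ann, margin_final, input_size)$annotations
  keep <- box_within_bounds(padded, padded$image_width, padded$image_height)
  eliminated <- unique(padded$image_id[!keep])
  surviving <- padded[keep, , drop = FALSE]
  if (nrow(surviving) == 0)
    abort("no training images survive elimination under this D/L condition")
  resized <- resize_with_annotations(NULL, surviving, input_size)$annotations
  list(training = horizontal_flip_augment(resized),
       n_eliminated = length(eliminated),
       eliminated_image_ids = eliminated)
}

#' Tabulate eliminations across D/L values
#'
#' Convenience wrapper running [build_training_set()]'s elimination stage for
#' several fixed D/L values and reporting the number of dropped images per
#' value (the count falls as D/L rises, since ROIs shrink).
#'
#' @param annotations annotation `data.frame`.
#' @param dl_values numeric vector of fixed D/L ratios.
#' @param margin_final,input_size see [margin_pad_size()].
#' @return A `data.frame` with columns `dl` and `n_eliminated`.
#' @export
elimination_counts <- function(annotations, dl_values = seq(0.4, 1.1, by = 0.1),
                               margin_final = 25, input_size = 448) {
  counts <- vapply(dl_values, function(d) {
    ann <- assign_dl_values(annotations, dl_condition(d))
    gt <- make_ground_truth_box(ann, ann$dl)
    ann <- cbind(ann, gt[, c("x_min", "y_min", "x_max", "y_max")])
    padded <- pad_with_margin(NULL, ann, margin_final, input_size)$annotations
    keep <- box_within_bounds(padded, padded$image_width, padded$image_height)
    length(unique(padded$image_id[!keep]))
  }, numeric(1))
  data.frame(dl = dl_values, n_eliminated = counts)
}
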