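#' Liver tumor type labels
#'
#' The four lesion classes of the annotation model: simple hepatic cyst,
#' hepatocellular carcinoma (HCC), hepatic hemangioma and metastatic liver
#' cancer.
#' @export
tumor_types <- c("cyst", "hcc", "hemangioma", "metastasis")

#' Construct a tumor annotation table
#'
#' One row per annotated tumor on one image: the case and image identifiers,
#' the lesion type, the tumor center (the center of the smallest circle
#' circumscribing the tumor, in continuous image coordinates with the origin
#' at the top-left), and the maximum tumor diameter D in pixels.
#'
#' @param case_id,image_id identifiers (coerced to character).
#' @param tumor_type one of `"cyst"`, `"hcc"`, `"hemangioma"`, `"metastasis"`.
#' @param center_x,center_y tumor center coordinates (px).
#' @param max_diameter maximum tumor diameter D (px, strictly positive).
#' @param image_width,image_height dimensions of the referenced image (px).
#' @return A `data.frame` with one row per annotation.
#' @export
#' @examples
#' tumor_annotation("c1", "c1_i1", "cyst", 100, 100, 50, 448, 448)
tumor_annotation <- function(case_id, image_id, tumor_type,
                             center_x, center_y, max_diameter,
                             image_width = NA_real_, image_height = NA_real_) {
  ann <- data.frame(case_id = as.character(case_id),
                    image_id = as.character(image_id),
                    tumor_type = as.character(tumor_type),
                    center_x = as.numeric(center_x),
                    center_y = as.numeric(center_y),
                    max_diameter = as.numeric(max_diameter),
                    image_width = as.numeric(image_width),
                    image_height = as.numeric(image_height),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' Validate a tumor annotation table
#'
#' Checks the annotation invariants: positive maximum diameter, known tumor
#' type, and (when image dimensions are present) tumor center inside the image.
#'
#' @param ann annotation `data.frame` as from [tumor_annotation()].
#' @return `ann`, invisibly usable, after validation.
#' @export
validate_annotations <- function(ann) {
  assert_cols(ann, c("case_id", "image_id", "tumor_type",
                     "center_x", "center_y", "max_diameter"), "annotation table")
  if (any(!ann$tumor_type %in% tumor_types))
    abort("unknown tumor_type(s): %s",
          paste(unique(setdiff(ann$tumor_type, tumor_types)), collapse = ", "))
  if (any(!is.finite(ann$max_diameter)) || any(ann$max_diameter <= 0))
    abort("max_diameter must be strictly positive for every annotation")
  if (all(c("image_width", "image_height") %in% names(ann))) {
    known <- is.finite(ann$image_width) & is.finite(ann$image_height)
    bad <- known & (ann$center_x < 0 | ann$center_y < 0 |
                      ann$center_x > ann$image_width |
                      ann$center_y > ann$image_height)
    if (any(bad))
      abort("tumor center outside image bounds for image(s): %s",
            paste(head(ann$image_id[bad], 5), collapse = ", "))
  }
  ann
}

#' Construct a bounding-box table
#'
#' Axis-aligned boxes in continuous image coordinates, represented as closed
#' real intervals; the area is the real product of side lengths, with no
#' pixel-grid corrections.
#'
#' @param x_min,y_min,x_max,y_max box corners (px); must satisfy
#'   `x_max > x_min`, `y_max > y_min`.
#' @return A `data.frame` with the four corner columns.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  box <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                    x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(box$x_max <= box$x_min) || any(box$y_max <= box$y_min))
    abort("boxes must have strictly positive width and height")
  box
}

#' Box areas
#' @param box bounding-box `data.frame`.
#' @return Numeric vector of areas (px^2).
#' @export
box_area <- function(box) {
  assert_cols(box, c("x_min", "y_min", "x_max", "y_max"))
  (box$x_max - box$x_min) * (box$y_max - box$y_min)
}

#' Specify a D/L condition
#'
#' Either a fixed D/L ratio applied to every image, or a range from which one
#' D/L value per image is drawn uniformly at random. D/L is the maximum tumor
#' diameter divided by the side of the square ground-truth ROI, so D/L = 1
#' makes the ROI tangent to the tumor, smaller values enlarge the ROI and
#' larger values shrink it below the tumor.
#'
#' @param value a single D/L ratio (fixed mode) or a length-2 numeric
#'   `c(low, high)` (uniform-range mode). All values must be strictly positive
#'   and `low <= high`.
#' @return An object of class `dl_condition`.
#' @export
#' @examples
#' dl_condition(0.8)
#' dl_condition(c(0.6, 1.0))
dl_condition <- function(value) {
  if (inherits(value, "dl_condition")) return(value)
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0))
    abort("D/L values must be strictly positive and finite")
  if (length(value) == 1) {
    cond <- list(mode = "fixed", value = value)
  } else if (length(value) == 2) {
    if (value[1] > value[2]) abort("D/L range must have low <= high")
    cond <- list(mode = "uniform_range", low = value[1], high = value[2])
  } else {
    abort("supply one D/L value or a length-2 range")
  }
  structure(cond, class = "dl_condition")
}

#' @export
print.dl_condition <- function(x, ...) {
  if (x$mode == "fixed")
    cat(sprintf("<dl_condition> fixed D/L = %g\n", x$value))
  else
    cat(sprintf("<dl_condition> D/L ~ Uniform[%g, %g]\n", x$low, x$high))
  invisible(x)
}

#' Mean and width of a D/L condition
#'
#' `dl_mean()` is the condition's expected D/L (the fixed value, or the
#' midpoint of a uniform range); `dl_width()` is the range width (0 for fixed).
#'
#' @param condition a [dl_condition()] (or a value coercible to one).
#' @return A single numeric.
#' @export
dl_mean <- function(condition) {
  condition <- dl_condition(condition)
  if (condition$mode == "fixed") condition$value else (condition$low + condition$high) / 2
}

#' @rdname dl_mean
#' @export
dl_width <- function(condition) {
  condition <- dl_condition(condition)
  if (condition$mode == "fixed") 0 else condition$high - condition$low
}

#' Build square ground-truth boxes at a given D/L
#'
#' The ground-truth ROI for a tumor with maximum diameter D at ratio `dl` is
#' the square of side L = D / dl centered on the tumor center. `dl = 1`
#' yields a box tangent to the tumor; `dl < 1` a larger box; `dl > 1` a
#' smaller one. The center is never shifted.
#'
#' If the annotations carry `scale_x`/`scale_y` columns (set by
#' [resize_with_annotations()] after an anisotropic resize), the box
#' half-sides are scaled per axis, re-deriving the ROI in the resized frame.
#'
#' @param annotations annotation `data.frame` ([tumor_annotation()]).
#' @param dl D/L ratio(s), strictly positive; recycled over rows. Defaults to
#'   the `dl` column of `annotations` if present.
#' @return A `data.frame` of boxes (`x_min`..`y_max`) with `image_id` carried
#'   through.
#' @export
#' @examples
#' a <- tumor_annotation("c1", "i1", "cyst", 100, 100, 50)
#' make_ground_truth_box(a, 1.0)   # side 50, tangent to the tumor
#' make_ground_truth_box(a, 0.5)   # side 100, box twice the tumor
make_ground_truth_box <- function(annotations, dl = annotations$dl) {
  validate_annotations(annotations)
  if (is.null(dl)) abort("no D/L value supplied and no 'dl' column present")
  dl <- as.numeric(dl)
  if (any(!is.finite(dl)) || any(dl <= 0))
    abort("D/L must be strictly positive and finite")
  L <- annotations$max_diameter / dl
  sx <- annotations$scale_x %||% 1
  sy <- annotations$scale_y %||% 1
  data.frame(image_id = annotations$image_id,
             x_min = annotations$center_x - L / 2 * sx,
             y_min = annotations$center_y - L / 2 * sy,
             x_max = annotations$center_x + L / 2 * sx,
             y_max = annotations$center_y + L / 2 * sy,
             stringsAsFactors = FALSE)
}

#' Recover the D/L ratio of a square ground-truth box
#'
#' The inverse of [make_ground_truth_box()]: D divided by the box side.
#' Ground-truth ROIs are square, so boxes whose sides differ beyond the
#' tolerance are rejected.
#'
#' @param box bounding-box `data.frame`.
#' @param max_diameter maximum tumor diameter(s) D (px, > 0); recycled.
#' @param tol relative tolerance on the side-length mismatch.
#' @return Numeric vector of D/L ratios.
#' @export
dl_of_box <- function(box, max_diameter, tol = 1e-6) {
  assert_cols(box, c("x_min", "y_min", "x_max", "y_max"))
  max_diameter <- as.numeric(max_diameter)
  if (any(max_diameter <= 0)) abort("max_diameter must be strictly positive")
  w <- box$x_max - box$x_min
  h <- box$y_max - box$y_min
  bad <- abs(w - h) > tol * pmax(w, h)
  if (any(bad))
    abort("box is not square (width %g vs height %g); ground-truth ROIs are square",
          w[which(bad)[1]], h[which(bad)[1]])
  max_diameter / ((w + h) / 2)
}

#' Test whether boxes lie inside an image
#'
#' True iff `0 <= x_min`, `0 <= y_min`, `x_max <= width` and
#' `y_max <= height`; boundary-touching boxes count as inside. Used to drop
#' training images whose ROI exceeds the (margin-padded) image area.
#'
#' @param box bounding-box `data.frame`.
#' @param image_width,image_height image dimensions (px, > 0); recycled.
#' @return Logical vector.
#' @export
box_within_bounds <- function(box, image_width, image_height) {
  assert_cols(box, c("x_min", "y_min", "x_max", "y_max"))
  if (any(image_width <= 0) || any(image_height <= 0))
    abort("image dimensions must be positive")
  box$x_min >= 0 & box$y_min >= 0 &
    box$x_max <= image_width & box$y_max <= image_height
}

#' Assign D/L values to annotations under a condition
#'
#' In fixed mode every annotation receives the same value. In uniform-range
#' mode one value per image is drawn i.i.d. from Uniform(low, high),
#' reproducibly under `seed`; annotations sharing an `image_id` share the
#' draw.
#'
#' @param annotations annotation `data.frame`.
#' @param condition a [dl_condition()] (or coercible value).
#' @param seed integer seed for the uniform-range draws.
#' @return `annotations` with a `dl` column appended.
#' @export
assign_dl_values <- function(annotations, condition, seed = 1) {
  validate_annotations(annotations)
  condition <- dl_condition(condition)
  if (condition$mode == "fixed") {
    annotations$dl <- rep(condition$value, nrow(annotations))
  } else {
    ids <- unique(annotations$image_id)
    draws <- withr::with_seed(seed, runif(length(ids), condition$low, condition$high))
    annotations$dl <- draws[match(annotations$image_id, ids)]
  }
  annotations
}

#' Read / write annotation tables
#'
#' Lossless CSV round trip of the annotation format: header columns
#' `case_id, image_id, tumor_type, center_x, center_y, max_diameter` plus any
#' extra columns present (image dimensions, assigned `dl`, ...).
#'
#' @param path file path.
#' @param annotations annotation `data.frame`.
#' @return `read_annotations()` returns the validated annotation table;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(case_id = "character", image_id = "character"))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Export square ground-truth boxes as COCO-style JSON
#'
#' Writes an object-detection annotation file in the COCO layout (`images`,
#' `annotations` with `[x, y, width, height]` boxes, `categories`) so the
#' ground truth can be consumed by external detector tooling.
#'
#' @param annotations annotation `data.frame` with image dimensions.
#' @param dl D/L ratio used to build the boxes (default 1.0, tangent boxes).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coco_annotations <- function(annotations, path, dl = 1.0) {
  validate_annotations(annotations)
  boxes <- make_ground_truth_box(annotations, dl)
  ids <- unique(annotations$image_id)
  img_idx <- match(annotations$image_id, ids)
  first <- match(ids, annotations$image_id)
  coco <- list(
    images = data.frame(id = seq_along(ids), file_name = paste0(ids, ".png"),
                        width = annotations$image_width[first],
                        height = annotations$image_height[first]),
    annotations = data.frame(
      id = seq_len(nrow(annotations)),
      image_id = img_idx,
      category_id = match(annotations$tumor_type, tumor_types),
      bbox = I(lapply(seq_len(nrow(boxes)), function(i)
        c(boxes$x_min[i], boxes$y_min[i],
          boxes$x_max[i] - boxes$x_min[i], boxes$y_max[i] - boxes$y_min[i]))),
      area = box_area(boxes)),
    categories = data.frame(id = seq_along(tumor_types), name = tumor_types,
                            supercategory = "liver_tumor"))
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
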