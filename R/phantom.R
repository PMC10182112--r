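#' Configuration of the synthetic ultrasound phantom generator
#'
#' The generator emulates the structure of the multi-center Japanese liver
#' ultrasound collection (JSUM/AMED) the study design is proportioned to:
#' four tumor types with case and image counts in the published proportions
#' (cyst 3245 images / 925 cases, HCC 1364/304, hemangioma 1786/562,
#' metastasis 1212/205; see [liver_reference_counts()]), several images per
#' case, tumor diameters spanning very small to more than half the image,
#' speckled B-mode-like backgrounds inside a sector (fan) mask, and
#' type-specific appearance including posterior echo features (the bright
#' band behind a cyst, the shadow behind a solid mass).
#'
#' @param image_size side of the square phantom images (px; default 256).
#' @param scale fraction of the reference collection to generate (default
#'   0.1, i.e. roughly 760 images over roughly 198 cases).
#' @param cases_per_type,images_per_type named integer vectors overriding the
#'   scaled reference counts.
#' @param diameter_range tumor maximum-diameter range as fractions of
#'   `image_size` (default `c(0.05, 0.62)`: small tumors up to lesions wider
#'   than half the image).
#' @param background_mean mean background echo intensity in `[0, 1]`.
#' @param speckle_shape gamma shape of the multiplicative speckle (smaller =
#'   grainier; 4 approximates fully developed speckle).
#' @param sector_mask render inside a fan-shaped acquisition sector.
#' @param posterior_feature_strength amplitude in `[0, 1]` of posterior
#'   enhancement/shadowing; 0 disables the feature.
#' @param images_per_case_range admissible images-per-case range; counts are
#'   distributed over cases within it.
#' @param seed master seed; the whole dataset is a pure function of the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256,
                           scale = 0.1,
                           cases_per_type = NULL,
                           images_per_type = NULL,
                           diameter_range = c(0.05, 0.62),
                           background_mean = 0.35,
                           speckle_shape = 4,
                           sector_mask = TRUE,
                           posterior_feature_strength = 0.7,
                           images_per_case_range = c(1, 12),
                           seed = 1) {
  ref <- liver_reference_counts()$composition
  ref_cases <- setNames(ref$cases, ref$tumor_type)
  ref_images <- setNames(ref$images, ref$tumor_type)
  cases_per_type <- cases_per_type %||% pmax(1L, round(ref_cases[tumor_types] * scale))
  images_per_type <- images_per_type %||% pmax(1L, round(ref_images[tumor_types] * scale))
  cases_per_type <- setNames(as.integer(cases_per_type), tumor_types)
  images_per_type <- setNames(as.integer(images_per_type), tumor_types)
  if (any(cases_per_type < 1) || any(images_per_type < 1))
    abort("all per-type case and image counts must be >= 1")
  if (any(images_per_type < cases_per_type))
    abort("need at least one image per case for every type")
  if (diameter_range[1] <= 0 || diameter_range[2] >= 1 ||
      diameter_range[1] > diameter_range[2])
    abort("diameter_range must be fractions within (0, 1) with low <= high")
  if (posterior_feature_strength < 0 || posterior_feature_strength > 1)
    abort("posterior_feature_strength must lie in [0, 1]")
  structure(list(image_size = image_size,
                 cases_per_type = cases_per_type,
                 images_per_type = images_per_type,
                 diameter_range = diameter_range * image_size,
                 background_mean = background_mean,
                 speckle_shape = speckle_shape,
                 sector_mask = sector_mask,
                 posterior_feature_strength = posterior_feature_strength,
                 images_per_case_range = images_per_case_range,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %dx%d px, %d cases / %d images, seed %d\n",
              x$image_size, x$image_size, sum(x$cases_per_type),
              sum(x$images_per_type), x$seed))
  invisible(x)
}

# fan-shaped acquisition sector: apex above the top edge, half-angle 38 deg
sector_mask_matrix <- function(size) {
  apex <- c(size / 2, -0.15 * size)
  x <- matrix(seq_len(size) - 0.5, nrow = size, ncol = size)
  y <- matrix(rep(seq_len(size) - 0.5, each = size), nrow = size)
  dx <- x - apex[1]; dy <- y - apex[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dx, dy)                     # 0 = straight down
  abs(theta) <= 38 * pi / 180 & r >= 0.2 * size & r <= 1.25 * size
}

point_in_sector <- function(px, py, size) {
  apex <- c(size / 2, -0.15 * size)
  dx <- px - apex[1]; dy <- py - apex[2]
  r <- sqrt(dx^2 + dy^2)
  abs(atan2(dx, dy)) <= 38 * pi / 180 & r >= 0.2 * size & r <= 1.25 * size
}

circle_in_sector <- function(cx, cy, radius, size) {
  phi <- seq(0, 2 * pi, length.out = 17)[-17]
  all(point_in_sector(cx + radius * cos(phi), cy + radius * sin(phi), size))
}

#' Render one ultrasound-like phantom image
#'
#' Produces a grayscale B-mode-like phantom: multiplicative gamma speckle
#' over a mean background level, an optional fan-shaped sector mask, and one
#' elliptical tumor (major axis = `diameter`) with a type-specific
#' appearance archetype: cyst = near-anechoic interior with a posterior
#' high-intensity band; hemangioma = hyperechoic interior; HCC = hypoechoic
#' mosaic texture; metastasis = hypoechoic rim with a brighter core (the
#' bull's-eye pattern) and a posterior shadow. Rendering is deterministic
#' under `seed`.
#'
#' @param tumor_type one of [tumor_types].
#' @param diameter maximum tumor diameter D (px): the ellipse major axis.
#' @param center length-2 tumor center `c(x, y)` (px); the ellipse center,
#'   which is also the center of the smallest circumscribing circle.
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @param axis_ratio minor/major axis ratio in `(0, 1]`.
#' @param echo_jitter multiplicative perturbation of the type's echo levels
#'   (1 = archetype).
#' @return A list with `image` (numeric matrix `[x, y]` in `[0, 1]`) and
#'   `annotation` (one-row annotation `data.frame`; `case_id`/`image_id`
#'   are `"phantom"` unless relabeled by the caller).
#' @export
generate_phantom_image <- function(tumor_type, diameter, center, config,
                                   seed = 1, axis_ratio = 0.85,
                                   echo_jitter = 1) {
  stopifnot(tumor_type %in% tumor_types, length(center) == 2)
  size <- config$image_size
  a <- diameter / 2
  b <- a * axis_ratio
  if (config$sector_mask && !circle_in_sector(center[1], center[2], a, size))
    abort("tumor (center %g,%g, D=%g) lies outside the acquisition sector",
          center[1], center[2], diameter)
  withr::with_seed(seed, {
    bg <- config$background_mean * echo_jitter
    img <- matrix(rgamma(size * size, shape = config$speckle_shape,
                         rate = config$speckle_shape) * bg,
                  nrow = size, ncol = size)
    x <- matrix(seq_len(size) - 0.5, nrow = size, ncol = size)
    y <- matrix(rep(seq_len(size) - 0.5, each = size), nrow = size)
    u <- (x - center[1]) / a
    v <- (y - center[2]) / b
    rho2 <- u^2 + v^2
    inside <- rho2 <= 1
    strength <- config$posterior_feature_strength
    # interior echogenicity relative to background, by archetype
    gain <- switch(tumor_type,
      cyst = 0.10,
      hemangioma = 1.75,
      hcc = 0.65 * (1 + 0.35 * sin(x / (0.16 * diameter) + seed %% 7) *
                      sin(y / (0.13 * diameter) + seed %% 5)),
      metastasis = ifelse(rho2 <= 0.45, 1.35, 0.50))
    img[inside] <- img[inside] * (if (length(gain) > 1) gain[inside] else gain)
    if (strength > 0) {
      # posterior echo feature: below the tumor, within its lateral footprint
      lateral <- exp(-pmax(abs(u) - 0.8, 0)^2 / 0.08)
      depth <- (y - (center[2] + b)) / (0.8 * diameter)
      band <- lateral * exp(-pmax(depth, 0)^2 * 4) * (depth > 0)
      if (tumor_type == "cyst") {
        img <- img * (1 + 1.4 * strength * band)      # posterior enhancement
      } else if (tumor_type %in% c("hcc", "metastasis")) {
        img <- img * (1 - 0.6 * strength * band)      # posterior shadow
      }
    }
    if (config$sector_mask) img[!sector_mask_matrix(size)] <- 0
    img <- clamp(img, 0, 1)
  })
  ann <- tumor_annotation("phantom", "phantom", tumor_type,
                          center[1], center[2], diameter, size, size)
  list(image = img, annotation = ann)
}

#' Generate a phantom dataset with annotations grouped by case
#'
#' Draws per-type case and image counts from the configuration, shares
#' appearance parameters (base diameter, axis ratio, echo level) within each
#' case with small per-image perturbations (images from the same case are
#' similar), places each tumor so that it fits inside the acquisition
#' sector, and returns the annotation table. Pixel rendering is deferred by
#' default: every row records the parameters and seed needed to reproduce
#' its image bit-identically via [render_phantom()], so large annotation-only
#' studies never touch pixels.
#'
#' @param config a [phantom_config()].
#' @param render if `TRUE`, also return the rendered images as a named list
#'   of matrices (memory-heavy for large configurations).
#' @return A list with `annotations` (one row per image, including the
#'   per-case appearance columns `axis_ratio`, `echo_jitter`, `render_seed`)
#'   and `images` (`NULL` unless `render = TRUE`).
#' @export
generate_phantom_dataset <- function(config, render = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  size <- config$image_size
  rows <- withr::with_seed(config$seed, {
    out <- list()
    for (type in tumor_types) {
      n_cases <- config$cases_per_type[[type]]
      n_images <- config$images_per_type[[type]]
      counts <- distribute_images(n_images, n_cases, config$images_per_case_range)
      for (ci in seq_len(n_cases)) {
        case_id <- sprintf("%s_c%03d", type, ci)
        base_d <- exp(runif(1, log(config$diameter_range[1]),
                            log(config$diameter_range[2])))
        axis_ratio <- runif(1, 0.7, 1)
        echo_jitter <- exp(rnorm(1, 0, 0.1))
        for (ii in seq_len(counts[ci])) {
          d <- clamp(base_d * runif(1, 0.85, 1.15),
                     config$diameter_range[1], config$diameter_range[2])
          ctr <- sample_center(d / 2, size, config$sector_mask)
          out[[length(out) + 1L]] <- data.frame(
            case_id = case_id,
            image_id = sprintf("%s_i%02d", case_id, ii),
            tumor_type = type,
            center_x = ctr[1], center_y = ctr[2],
            max_diameter = d,
            image_width = size, image_height = size,
            axis_ratio = axis_ratio, echo_jitter = echo_jitter,
            render_seed = sample.int(2147483646L, 1),
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  })
  ann <- validate_annotations(do.call(rbind, rows))
  images <- NULL
  if (render) {
    images <- lapply(seq_len(nrow(ann)), function(i) render_phantom(ann[i, ], config)$image)
    names(images) <- ann$image_id
  }
  list(annotations = ann, images = images, config = config)
}

# split n_images over n_cases, each case within the admissible range
distribute_images <- function(n_images, n_cases, range) {
  lo <- max(1, range[1])
  counts <- rep(lo, n_cases)
  extra <- n_images - sum(counts)
  if (extra < 0) abort("images_per_type too small for cases_per_type")
  while (extra > 0) {
    open <- which(counts < range[2])
    if (length(open) == 0) open <- seq_len(n_cases)
    take <- open[sample.int(length(open), min(extra, length(open)))]
    counts[take] <- counts[take] + 1
    extra <- extra - length(take)
  }
  counts
}

# rejection-sample a tumor center whose circumscribing circle fits the frame
sample_center <- function(radius, size, use_sector) {
  for (i in seq_len(200)) {
    cx <- runif(1, radius, size - radius)
    cy <- runif(1, radius, size - radius)
    if (!use_sector || circle_in_sector(cx, cy, radius, size))
      return(c(cx, cy))
  }
  # very large tumors: fall back to the sector's central axis
  c(size / 2, clamp(size * 0.55, radius, size - radius))
}

#' Re-render the phantom image of one annotation row
#'
#' @param annotation one row of a [generate_phantom_dataset()] annotation
#'   table (carries the stored appearance parameters and render seed).
#' @param config the [phantom_config()] the dataset was generated with.
#' @return As [generate_phantom_image()].
#' @export
render_phantom <- function(annotation, config) {
  assert_cols(annotation, c("tumor_type", "center_x", "center_y",
                            "max_diameter", "axis_ratio", "echo_jitter",
                            "render_seed"))
  generate_phantom_image(annotation$tumor_type[1], annotation$max_diameter[1],
                         c(annotation$center_x[1], annotation$center_y[1]),
                         config, seed = annotation$render_seed[1],
                         axis_ratio = annotation$axis_ratio[1],
                         echo_jitter = annotation$echo_jitter[1])
}

#' Write a phantom image as an 8-bit grayscale PNG
#'
#' @param image numeric matrix `[x, y]` in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phantom_png <- function(image, path) {
  png::writePNG(t(clamp(image, 0, 1)), path)
  invisible(path)
}
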