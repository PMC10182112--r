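# Programmatic fixtures shared across test files.

# A small multi-case annotation set: n_cases per type, images per case drawn
# from images_per_case, tumors placed centrally so no preprocessing stage
# drops them unless asked for.
make_fixture_annotations <- function(n_cases_per_type = 6, images_per_case = 2:4,
                                     image_size = 400, seed = 101,
                                     diameter_range = c(20, 80)) {
  withr::with_seed(seed, {
    rows <- list()
    for (type in tumor_types) {
      for (ci in seq_len(n_cases_per_type)) {
        case_id <- sprintf("%s%02d", type, ci)
        n_img <- sample(images_per_case, 1)
        for (ii in seq_len(n_img)) {
          d <- runif(1, diameter_range[1], diameter_range[2])
          rows[[length(rows) + 1L]] <- tumor_annotation(
            case_id, sprintf("%s_i%d", case_id, ii), type,
            center_x = runif(1, 0.35, 0.65) * image_size,
            center_y = runif(1, 0.35, 0.65) * image_size,
            max_diameter = d,
            image_width = image_size, image_height = image_size)
        }
      }
    }
    do.call(rbind, rows)
  })
}

# Annotations with tumors pushed toward the image border, so enlarged ROIs
# (small D/L) overflow even the padded frame while tangent ROIs survive.
make_edge_annotations <- function(n = 12, image_size = 400, seed = 7) {
  withr::with_seed(seed, {
    d <- runif(n, 60, 120)
    # centers a hair more than D/2 from the left/top edge
    off <- d / 2 + runif(n, 1, 10)
    do.call(rbind, lapply(seq_len(n), function(i)
      tumor_annotation(sprintf("edge%02d", i), sprintf("edge%02d_i1", i),
                       sample(tumor_types, 1), off[i], off[i], d[i],
                       image_size, image_size)))
  })
}

random_boxes <- function(n, max_coord = 100, integer_coords = TRUE) {
  pick <- function() {
    if (integer_coords) sort(sample(0:max_coord, 2)) else sort(runif(2, 0, max_coord))
  }
  do.call(rbind, replicate(n, {
    x <- pick(); y <- pick()
    if (x[1] == x[2]) x[2] <- x[2] + 1
    if (y[1] == y[2]) y[2] <- y[2] + 1
    bounding_box(x[1], y[1], x[2], y[2])
  }, simplify = FALSE))
}
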