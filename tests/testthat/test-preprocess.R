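test_that("margin arithmetic puts exactly the target margin in the resized frame", {
  # 398 px original: pad = 398 * 25 / (448 - 50) = 25 exactly
  expect_equal(margin_pad_size(398), 25)
  expect_equal(margin_pad_size(800), 800 * 25 / 398)
  expect_error(margin_pad_size(400, margin_final = 224), "consume")
  # generic consistency: padded-and-resized margin equals margin_final
  for (d in c(200, 313, 448, 1024)) {
    m <- margin_pad_size(d)
    expect_equal(448 * m / (d + 2 * m), 25, tolerance = 1e-12)
  }
})

test_that("padding shifts annotations and is the identity at margin 0", {
  ann <- tumor_annotation("c", "i", "cyst", 10, 10, 8, 398, 398)
  out <- pad_with_margin(NULL, ann, margin_final = 25)
  expect_equal(out$annotations$center_x, 35)
  expect_equal(out$annotations$center_y, 35)
  expect_equal(out$annotations$image_width, 448)
  ident <- pad_with_margin(NULL, ann, margin_final = 0)
  expect_equal(ident$annotations$center_x, ann$center_x)
  expect_equal(ident$annotations$image_width, ann$image_width)

  img <- matrix(runif(20 * 20), 20, 20)
  ann2 <- tumor_annotation("c", "i", "cyst", 10, 10, 8, 20, 20)
  padded <- pad_with_margin(img, ann2, margin_final = 25, input_size = 448)
  expect_equal(dim(padded$image), dim(img) + 2 * round(padded$pad[["x"]]))
  expect_equal(sum(padded$image), sum(img))   # border is zero background
})

test_that("resizing rescales annotations per axis and is identity at the target size", {
  ann <- tumor_annotation("c", "i", "cyst", 100, 100, 50, 448, 448)
  same <- resize_with_annotations(NULL, ann, 448)$annotations
  expect_equal(same$center_x, 100)
  expect_equal(same$scale_x, 1)

  wide <- tumor_annotation("c", "i", "cyst", 150, 150, 50, 896, 448)
  wide <- cbind(wide, bounding_box(100, 100, 200, 200))
  res <- resize_with_annotations(NULL, wide, 448)$annotations
  expect_equal(c(res$x_min, res$y_min, res$x_max, res$y_max),
               c(50, 100, 100, 200))
  expect_equal(res$scale_x, 0.5)
  expect_equal(res$scale_y, 1)

  up <- tumor_annotation("c", "i", "cyst", 112, 112, 30, 224, 224)
  expect_equal(resize_with_annotations(NULL, up, 448)$annotations$center_x, 224)

  # pixel path: resizing a constant image preserves it within round-off
  img <- matrix(0.5, 64, 64)
  a64 <- tumor_annotation("c", "i", "cyst", 32, 32, 10, 64, 64)
  r <- resize_with_annotations(img, a64, 64)
  expect_equal(r$image, img, tolerance = 1e-6)
})

test_that("ground-truth geometry re-derived after resize preserves D/L", {
  ann <- tumor_annotation("c", "i", "hcc", 120, 200, 60, 400, 400)
  pre <- make_ground_truth_box(ann, 0.8)
  res <- resize_with_annotations(NULL, ann, 448)$annotations
  post <- make_ground_truth_box(res, 0.8)
  # square input: scales equal, box stays square and D/L survives
  expect_equal(dl_of_box(post, res$max_diameter * res$scale_x), 0.8,
               tolerance = 1e-9)
  expect_equal(post$x_max - post$x_min, (pre$x_max - pre$x_min) * 448 / 400)
})

test_that("horizontal flip doubles the set, mirrors x, and is an involution", {
  ann <- make_fixture_annotations(n_cases_per_type = 5)
  doubled <- horizontal_flip_augment(ann)
  expect_equal(nrow(doubled), 2 * nrow(ann))
  mirrored <- doubled[doubled$flipped, ]
  expect_equal(mirrored$center_x, ann$image_width - ann$center_x)
  expect_equal(mirrored$center_y, ann$center_y)

  one <- tumor_annotation("c", "i", "cyst", 100, 50, 20, 448, 448)
  one <- cbind(one, bounding_box(90, 40, 110, 60))
  flip1 <- horizontal_flip_augment(one)[2, ]
  expect_equal(flip1$center_x, 348)
  expect_equal(c(flip1$x_min, flip1$x_max), c(338, 358))
  flip1$flipped <- NULL
  flip2 <- horizontal_flip_augment(flip1)[2, ]
  expect_equal(flip2$center_x, one$center_x)
  expect_equal(c(flip2$x_min, flip2$x_max), c(one$x_min, one$x_max))

  img <- matrix(runif(30 * 20), 30, 20)
  expect_identical(flip_image_horizontal(flip_image_horizontal(img)), img)
})

test_that("case-wise split keeps cases whole, test sets disjoint, fractions near target", {
  # divisible toy case: 10 cases x 10 images per type -> exactly 2 cases per test set
  ann <- do.call(rbind, lapply(tumor_types, function(type)
    do.call(rbind, lapply(1:10, function(ci)
      do.call(rbind, lapply(1:10, function(ii)
        tumor_annotation(sprintf("%s%02d", type, ci),
                         sprintf("%s%02d_i%02d", type, ci, ii),
                         type, 200, 200, 40, 400, 400)))))))
  splits <- case_wise_split(ann, 0.2, 3, seed = 1)
  for (s in splits) {
    expect_length(intersect(s$training$case_id, s$test$case_id), 0)
    expect_equal(length(unique(s$test$case_id)), 8)  # 2 cases x 4 types
    expect_equal(nrow(s$test), 80)
  }
  test_ids <- lapply(splits, function(s) s$test$image_id)
  expect_length(intersect(test_ids[[1]], test_ids[[2]]), 0)
  expect_length(intersect(test_ids[[1]], test_ids[[3]]), 0)
  expect_length(intersect(test_ids[[2]], test_ids[[3]]), 0)

  # uneven case sizes: achieved test fraction close to 20%
  ann2 <- make_fixture_annotations(n_cases_per_type = 12, images_per_case = 1:6)
  for (s in case_wise_split(ann2, 0.2, 3, seed = 2)) {
    frac <- nrow(s$test) / nrow(ann2)
    expect_gt(frac, 0.14)
    expect_lt(frac, 0.26)
  }
  tiny <- make_fixture_annotations(n_cases_per_type = 4)
  expect_error(case_wise_split(tiny), "5 cases")
})

test_that("training-set build eliminates overflowing ROIs and flip-doubles the rest", {
  central <- make_fixture_annotations(n_cases_per_type = 6, image_size = 400,
                                      diameter_range = c(20, 60))
  built <- build_training_set(central, dl_condition(1.0))
  expect_equal(built$n_eliminated, 0)
  expect_equal(nrow(built$training), 2 * nrow(central))

  edge <- rbind(central, make_edge_annotations())
  built_small_dl <- build_training_set(edge, dl_condition(0.4))
  expect_gt(built_small_dl$n_eliminated, 0)
  expect_equal(nrow(built_small_dl$training),
               2 * (nrow(edge) - built_small_dl$n_eliminated))

  counts <- elimination_counts(edge)
  expect_true(all(diff(counts$n_eliminated) <= 0))  # non-increasing in D/L
  expect_equal(counts$n_eliminated[counts$dl == 1.1], 0)

  # eliminated sets are nested: dl 0.4 drops a superset of dl 0.6's drops
  el4 <- build_training_set(edge, dl_condition(0.4))$eliminated_image_ids
  el6 <- build_training_set(edge, dl_condition(0.6))$eliminated_image_ids
  expect_true(all(el6 %in% el4))
})
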