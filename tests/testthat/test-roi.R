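# Region-of-interest module: rendering, detection, contrast selection,
# expansion, label merging.

test_that("rendering conserves counts and round-trips coordinates", {
  one <- tibble::tibble(x = 230, y = 470)
  img <- render_image(one, pixel_size = 100)
  expect_equal(sum(img$intensity > 0), 1)
  expect_equal(max(img$intensity), 1)

  withr::with_seed(1, {
    locs <- tibble::tibble(x = runif(500, 0, 5000), y = runif(500, 0, 3000))
  })
  img2 <- render_image(locs, pixel_size = 100)
  expect_equal(sum(img2$counts), 500) # conservation before clipping
  expect_true(all(img2$intensity >= 0 & img2$intensity <= 1))

  # pixel -> nm -> pixel identity for in-range indices
  p <- img2$pixel_size
  for (ix in c(1, 10, ncol(img2$intensity))) {
    x_nm <- img2$origin[1] + (ix - 0.5) * p
    expect_equal(floor((x_nm - img2$origin[1]) / p) + 1, ix)
  }
  expect_error(render_image(locs[0, ]), class = "sarcloc_parameter_error")
})

test_that("the classical detector finds isolated double lines", {
  # blank image -> no boxes
  blank <- render_image(tibble::tibble(x = 1, y = 1))
  blank$intensity[] <- 0
  expect_equal(nrow(detect_boxes(blank)), 0)

  # single double-line object: exactly one box holding >= 95% of its locs
  single <- simulate_field(
    double_line_spec(n_pairs = 1, epitope_density = 40, origin = c(500, 3000)),
    noise_spec(field_width = 7000, field_height = 6000),
    seed = 21
  )
  sel <- select_contrast(single)
  expect_equal(nrow(sel$boxes), 1)
  obj <- single[single$label == "object", ]
  b <- as.numeric(sel$boxes[1, c("xmin", "ymin", "xmax", "ymax")])
  inside <- obj$x >= b[1] & obj$x < b[3] & obj$y >= b[2] & obj$y < b[4]
  expect_gte(mean(inside), 0.95)

  # two pairs separated by L = 3.4 um -> two disjoint boxes
  two <- simulate_field(
    double_line_spec(n_pairs = 2, epitope_density = 40, origin = c(500, 3000)),
    noise_spec(field_width = 9000, field_height = 6000),
    seed = 22
  )
  sel2 <- select_contrast(two)
  expect_equal(nrow(sel2$boxes), 2)
  bx <- dplyr::arrange(sel2$boxes, .data$xmin)
  expect_lt(bx$xmax[1], bx$xmin[2])
})

test_that("contrast selection follows the lexicographic rule", {
  locs <- small_field()
  # a one-element grid returns that setting
  only <- select_contrast(locs, percentile_grid = 99.5)
  expect_equal(only$contrast_percentile, 99.5)
  expect_identical(
    only$boxes,
    detect_boxes(render_image(locs, contrast_percentile = 99.5))
  )
  # full grid: the winner can never find fewer boxes than any grid member
  sel <- select_contrast(locs)
  counts <- vapply(c(99, 99.5, 99.9), function(p) {
    nrow(detect_boxes(render_image(locs, contrast_percentile = p)))
  }, numeric(1))
  expect_equal(nrow(sel$boxes), max(counts))
})

test_that("ROI expansion applies the subset arithmetic and increments", {
  # 600 localizations in the detect box, 900 within the first margin:
  # estimate 600 -> 2 subsets of 450
  withr::with_seed(31, {
    inside <- tibble::tibble(
      x = runif(600, 1000, 2000), y = runif(600, 1000, 2000)
    )
    margin <- tibble::tibble(
      x = runif(300, 2000, 2800), y = runif(300, 1000, 2000)
    )
  })
  locs <- dplyr::bind_rows(inside, margin)
  roi <- expand_roi(c(1000, 1000, 2000, 2000), locs, seed = 1)
  expect_equal(roi$est_object_locs, 600)
  expect_equal(roi$n_expansions, 0)
  expect_equal(sort(lengths(roi$subsets)), c(450L, 450L))
  expect_setequal(unlist(roi$subsets), seq_len(900))
  # every subset member lies inside the analysis box
  b <- roi$analysis_box
  expect_true(all(
    locs$x[unlist(roi$subsets)] >= b[1] & locs$x[unlist(roi$subsets)] < b[3]
  ))

  # sparse region: rejected after the increment budget
  sparse <- tibble::tibble(x = runif(100, 0, 500), y = runif(100, 0, 500))
  expect_error(
    expand_roi(c(0, 0, 500, 500), sparse, seed = 1),
    class = "sarcloc_roi_rejected"
  )

  # points that only reach 351+ after growth: expansion is recorded and the
  # analysis box is strictly larger than the first attempt
  withr::with_seed(32, {
    near <- tibble::tibble(x = runif(200, 900, 2100), y = runif(200, 900, 2100))
    far <- tibble::tibble(x = runif(200, -900, 3900), y = runif(200, -900, 3900))
  })
  locs2 <- dplyr::bind_rows(near, far)
  roi2 <- expand_roi(c(1000, 1000, 2000, 2000), locs2, seed = 1)
  expect_gt(roi2$n_expansions, 0)
  first_box <- c(1000, 1000, 2000, 2000) + c(-1000, -1000, 1000, 1000)
  expect_true(all(roi2$analysis_box[1:2] < first_box[1:2]))
  expect_true(all(roi2$analysis_box[3:4] > first_box[3:4]))
})

test_that("per-ROI labels merge with a logical OR", {
  pred <- tibble::tibble(
    .row = c(1, 2, 2, 3, 3, 4),
    roi = c(1, 1, 2, 1, 2, 2),
    .pred = c("object", "object", "noise", "noise", "noise", "noise")
  )
  merged <- merge_roi_labels(pred)
  expect_equal(merged$.pred[merged$.row == 1], "object") # single ROI: unchanged
  expect_equal(merged$.pred[merged$.row == 2], "object") # (object, noise) -> object
  expect_equal(merged$.pred[merged$.row == 3], "noise") # all noise -> noise
  expect_equal(merged$n_rois, c(1L, 2L, 2L, 1L))
})

test_that("most simulated objects are covered by exactly one detection box", {
  locs <- small_field()
  sel <- select_contrast(locs)
  rois <- purrr::map(seq_len(nrow(sel$boxes)), function(b) {
    expand_roi(
      as.numeric(sel$boxes[b, c("xmin", "ymin", "xmax", "ymax")]),
      locs,
      seed = b
    )
  })
  recall <- detection_recall(locs, rois)
  expect_gte(recall, 0.9)
})
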