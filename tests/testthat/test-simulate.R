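# Simulator: geometry, noise statistics, exclusion merge, splits.

test_that("spec constructors validate their invariants", {
  expect_s3_class(double_line_spec(), "double_line_spec")
  expect_error(double_line_spec(d = 0), class = "sarcloc_parameter_error")
  expect_error(double_line_spec(L = 100, d = 200),
    class = "sarcloc_parameter_error"
  )
  expect_error(double_line_spec(epitope_density = -1),
    class = "sarcloc_parameter_error"
  )
  expect_error(noise_spec(field_width = 0), class = "sarcloc_parameter_error")
})

test_that("double-line objects reproduce the requested geometry", {
  spec <- double_line_spec(n_pairs = 5, epitope_density = 40, d = 120)
  locs <- simulate_double_lines(spec, seed = 11)
  expect_setequal(unique(locs$object_id), 1:5)
  expect_true(all(locs$label == "object"))
  expect_true(all(locs$sigma > 0 & locs$photons > 0 & locs$precision > 0))

  # per-object transverse centroid separation close to d (jitter-limited)
  seps <- vapply(1:5, function(i) {
    o <- locs[locs$object_id == i, ]
    mu <- mean(o$x)
    mean(o$x[o$x >= mu]) - mean(o$x[o$x < mu])
  }, numeric(1))
  expect_true(all(abs(seps - 120) < 15))

  # pairs repeat every L along the strand
  centres <- vapply(1:5, function(i) mean(locs$x[locs$object_id == i]),
    numeric(1)
  )
  expect_equal(diff(centres), rep(3400, 4), tolerance = 0.01)
})

test_that("zero jitter and zero linker put localizations exactly on the two lines", {
  spec <- double_line_spec(
    n_pairs = 3, epitope_density = 30, d = 200,
    linker_length = 0, blinks_per_label_mean = 0,
    loc_precision_mean = 1e-9, loc_precision_sd = 0
  )
  locs <- simulate_double_lines(spec, seed = 5)
  # geometric oracle: the true line x-positions are known from the spec
  expected_x <- function(pair) {
    spec$origin[1] + (pair - 0.5) * spec$L + c(-100, 100)
  }
  resid <- vapply(seq_len(nrow(locs)), function(i) {
    min(abs(locs$x[i] - expected_x(locs$object_id[i])))
  }, numeric(1))
  expect_lt(max(resid), 1e-5)
  # and every localization sits within the projected disc length
  expect_true(all(abs(locs$y - spec$origin[2]) <= spec$D / 2 + 1e-6))
})

test_that("zero density yields an empty localization table", {
  locs <- simulate_double_lines(
    double_line_spec(epitope_density = 0),
    seed = 1
  )
  expect_identical(nrow(locs), 0L)
  expect_named(locs, c(
    "frame", "x", "y", "sigma", "photons", "precision", "label", "object_id"
  ))
  empty_noise <- simulate_noise(
    noise_spec(vesicle_density = 0, uniform_density = 0),
    seed = 1
  )
  expect_identical(nrow(empty_noise), 0L)
})

test_that("fixed seed gives bit-identical output tables", {
  a <- simulate_double_lines(double_line_spec(n_pairs = 3), seed = 42)
  b <- simulate_double_lines(double_line_spec(n_pairs = 3), seed = 42)
  expect_identical(a, b)
  an <- simulate_noise(noise_spec(field_width = 10000), seed = 42)
  bn <- simulate_noise(noise_spec(field_width = 10000), seed = 42)
  expect_identical(an, bn)
})

test_that("uniform noise counts follow the Poisson mean", {
  # 3 / um^2 on a 10 x 10 um field: mean 300 per draw
  spec <- noise_spec(
    vesicle_density = 0, uniform_density = 3,
    field_width = 10000, field_height = 10000
  )
  counts <- vapply(1:1000, function(s) nrow(simulate_noise(spec, seed = s)),
    numeric(1)
  )
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 300), 3 * se + 1e-9)
})

test_that("localization counts scale linearly with density", {
  count_at <- function(dens) {
    nrow(simulate_noise(
      noise_spec(
        vesicle_density = 0, uniform_density = dens,
        field_width = 20000, field_height = 20000
      ),
      seed = 99
    ))
  }
  counts <- vapply(c(5, 10, 20), count_at, numeric(1))
  # slope test: doubling density doubles counts within Poisson tolerance
  expect_lt(abs(counts[2] / counts[1] - 2), 0.15)
  expect_lt(abs(counts[3] / counts[2] - 2), 0.15)
})

test_that("exclusion merge removes noise strictly inside the radius", {
  obj <- tibble::tibble(
    frame = 1L, x = 0, y = 0, sigma = 130, photons = 1000, precision = 10,
    label = "object", object_id = 1L
  )
  noise <- tibble::tibble(
    frame = 1L, x = c(30, 80), y = c(0, 0), sigma = 130, photons = 1000,
    precision = 10, label = "noise", object_id = NA_integer_
  )
  merged <- merge_with_exclusion(obj, noise, radius = 50)
  expect_equal(merged$x, c(0, 80)) # 30 < 50 removed, 80 kept
  # radius 0: plain concatenation
  expect_equal(nrow(merge_with_exclusion(obj, noise, radius = 0)), 3)
  expect_error(merge_with_exclusion(obj, noise, radius = -1),
    class = "sarcloc_parameter_error"
  )
})

test_that("exclusion merge matches the all-pairs oracle on random fields", {
  for (s in 1:5) {
    withr::with_seed(s, {
      obj_xy <- cbind(runif(200, 0, 2000), runif(200, 0, 2000))
      noise_xy <- cbind(runif(300, 0, 2000), runif(300, 0, 2000))
    })
    obj <- tibble::tibble(
      x = obj_xy[, 1], y = obj_xy[, 2], label = "object"
    )
    noise <- tibble::tibble(
      x = noise_xy[, 1], y = noise_xy[, 2], label = "noise"
    )
    merged <- merge_with_exclusion(obj, noise, radius = 50)
    kept_noise <- merged[merged$label == "noise", ]
    keep_oracle <- oracle_exclusion_keep(noise_xy, obj_xy, 50)
    expect_equal(kept_noise$x, noise$x[keep_oracle])
    # post-condition: no kept noise point within 50 nm of any object point
    if (nrow(kept_noise) > 0) {
      dmin <- vapply(seq_len(nrow(kept_noise)), function(i) {
        sqrt(min((obj_xy[, 1] - kept_noise$x[i])^2 +
          (obj_xy[, 2] - kept_noise$y[i])^2))
      }, numeric(1))
      expect_true(all(dmin >= 50))
    }
  }
})

test_that("train/val/test split is a stratified partition", {
  data <- tibble::tibble(value = 1:10) # single stratum
  sp <- split_train_val_test(data, seed = 1)
  expect_equal(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(sp), 1:10)
  expect_equal(sum(duplicated(unlist(sp))), 0)

  # stratification: per-split class ratio within one item of the global
  data2 <- tibble::tibble(label = rep(c("object", "noise"), c(60, 40)))
  for (s in 1:5) {
    sp2 <- split_train_val_test(data2, seed = s)
    for (part in sp2) {
      n_obj <- sum(data2$label[part] == "object")
      expect_lte(abs(n_obj - 0.6 * length(part)), 1)
    }
  }
  expect_identical(
    split_train_val_test(data2, seed = 3),
    split_train_val_test(data2, seed = 3)
  )
  expect_error(split_train_val_test(data, fractions = c(0.5, 0.5, 0.5)),
    class = "sarcloc_parameter_error"
  )
})

test_that("photon counts are Thompson-consistent with the drawn precision", {
  locs <- small_field()
  recomputed <- thompson_precision(
    locs$sigma, locs$photons,
    pixel_size = 160, background = 19
  )
  rel <- abs(recomputed - locs$precision) / locs$precision
  expect_lt(stats::quantile(rel, 0.99), 0.2)
})
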