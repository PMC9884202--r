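# Classifier: training behaviour, prediction contracts, metrics arithmetic,
# ablation interface, serialization.

# small linearly separable toy: "object" rows have uniformly small sorted
# neighbour distances, "noise" rows large ones
toy_features <- function(n = 4000, p = 40, seed = 1) {
  withr::with_seed(seed, {
    obj <- t(apply(matrix(runif(n / 2 * p, 10, 60), n / 2), 1, sort))
    noi <- t(apply(matrix(runif(n / 2 * p, 600, 1200), n / 2), 1, sort))
  })
  list(
    X = rbind(obj, noi),
    labels = rep(c("object", "noise"), each = n / 2)
  )
}

test_that("classifier spec validates hyperparameters", {
  expect_s3_class(classifier_spec(), "classifier_spec")
  expect_error(classifier_spec(threshold = 1.2),
    class = "sarcloc_parameter_error"
  )
  expect_error(classifier_spec(hidden_units = 0),
    class = "sarcloc_parameter_error"
  )
})

test_that("a linearly separable toy reaches perfect training accuracy", {
  toy <- toy_features()
  fit <- fit_classifier(toy$X, toy$labels, seed = 1)
  pred <- predict(fit, toy$X)
  expect_equal(mean(pred$.pred == toy$labels), 1)
})

test_that("training loss decreases from first to last epoch across seeds", {
  toy <- toy_features(n = 1200, p = 60, seed = 2)
  for (s in 1:5) {
    fit <- fit_classifier(toy$X, toy$labels, seed = s)
    expect_lte(tail(fit$history$loss, 1), fit$history$loss[1])
  }
})

test_that("all three ablation widths train and predict", {
  fx <- small_features()
  sp <- split_train_val_test(tibble::tibble(label = fx$labels), seed = 5)
  for (set in c("distances", "directions", "combined")) {
    fit <- fit_classifier(
      fx$feats[sp$train, ], fx$labels[sp$train],
      spec = classifier_spec(epochs = 2), feature_set = set, seed = 1
    )
    expect_length(
      fit$feature_names,
      c(distances = 350L, directions = 30L, combined = 380L)[[set]]
    )
    pred <- predict(fit, fx$feats[sp$test, ])
    expect_true(all(pred$.prob >= 0 & pred$.prob <= 1))
  }
})

test_that("prediction width mismatches and NaN inputs error", {
  toy <- toy_features()
  fit <- fit_classifier(toy$X, toy$labels, seed = 1)
  expect_error(predict(fit, toy$X[, 1:10]),
    class = "sarcloc_parameter_error"
  )
  bad <- toy$X
  bad[1, 1] <- NaN
  expect_error(fit_classifier(bad, toy$labels, seed = 1),
    class = "sarcloc_parameter_error"
  )
})

test_that("labels move monotonically from object to noise as the threshold rises", {
  toy <- toy_features(seed = 3)
  fit <- fit_classifier(toy$X, toy$labels, seed = 2)
  expect_true(all(predict(fit, toy$X, threshold = 0)$.pred == "object"))
  expect_true(all(predict(fit, toy$X, threshold = 1)$.pred == "noise"))
  prev <- rep(TRUE, nrow(toy$X))
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    now <- predict(fit, toy$X, threshold = th)$.pred == "object"
    expect_true(all(now <= prev)) # object -> noise transitions only
    prev <- now
  }
})

test_that("confusion metrics match hand arithmetic", {
  pred <- rep(c("object", "noise", "noise", "object"), c(90, 10, 80, 20))
  truth <- rep(c("object", "noise"), c(100, 100))
  m <- evaluate_classification(pred, truth)
  expect_equal(m$tp, 90)
  expect_equal(m$fn, 10)
  expect_equal(m$tn, 80)
  expect_equal(m$fp, 20)
  expect_equal(m$tp_rate, 0.90)
  expect_equal(m$tn_rate, 0.80)

  perfect <- evaluate_classification(truth, truth)
  expect_equal(c(perfect$tp_rate, perfect$tn_rate), c(1, 1))

  all_obj <- evaluate_classification(rep("object", 200), truth)
  expect_equal(c(all_obj$tp_rate, all_obj$tn_rate), c(1, 0))

  no_noise <- evaluate_classification(rep("object", 3), rep("object", 3))
  expect_true(is.na(no_noise$tn_rate))
  expect_error(evaluate_classification("object", c("object", "noise")),
    class = "sarcloc_parameter_error"
  )
})

test_that("training and the ablation table are deterministic under a seed", {
  toy <- toy_features(seed = 4)
  f1 <- fit_classifier(toy$X, toy$labels, seed = 7)
  f2 <- fit_classifier(toy$X, toy$labels, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)

  fx <- small_features()
  sp <- split_train_val_test(tibble::tibble(label = fx$labels), seed = 5)
  spec <- classifier_spec(epochs = 2)
  t1 <- run_ablation(fx$feats, fx$labels, sp, spec = spec, seed = 9)
  t2 <- run_ablation(fx$feats, fx$labels, sp, spec = spec, seed = 9)
  expect_identical(t1, t2)
  expect_equal(t1$feature_set, c("distances", "directions", "combined"))
})

test_that("classifier serialization round-trips predictions exactly", {
  toy <- toy_features(seed = 5)
  fit <- fit_classifier(toy$X, toy$labels, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(fit, path)
  back <- load_classifier(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_identical(
    predict(back, toy$X)$.pred,
    predict(fit, toy$X)$.pred
  )
})

test_that("tidy and glance summarise a fitted classifier", {
  toy <- toy_features(seed = 6)
  fit <- fit_classifier(toy$X, toy$labels, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("epoch", "loss", "val_loss"))
  expect_equal(nrow(td), 10)
  gl <- glance(fit)
  expect_equal(gl$hidden_units, 32L)
  expect_equal(gl$n_parameters, 40 * 32 + 32 + 32 + 1)
})
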