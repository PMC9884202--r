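#' Classifier hyperparameters
#'
#' Architecture and training settings of the binary localization classifier:
#' one hidden layer of rectified-linear units, a single sigmoid output neuron,
#' binary cross-entropy loss minimised with minibatch Adam.
#'
#' @param hidden_units Hidden-layer width (default 32).
#' @param epochs Training epochs (default 10).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate,beta1,beta2,adam_eps Adam settings (framework-default
#'   values).
#' @param threshold Decision threshold on the output probability, in (0, 1).
#' @param standardize Z-score feature columns with training-set statistics
#'   before fitting (default FALSE: distances are fed raw in nm).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_units = 32, epochs = 10, batch_size = 32,
                            learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, threshold = 0.5,
                            standardize = FALSE) {
  check_number(hidden_units, "hidden_units", 1)
  check_number(epochs, "epochs", 1)
  check_number(batch_size, "batch_size", 1)
  check_number(learning_rate, "learning_rate", 0, strict = TRUE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1)", class = "sarcloc_parameter_error")
  }
  structure(
    list(
      hidden_units = as.integer(hidden_units), epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
      threshold = threshold, standardize = isTRUE(standardize)
    ),
    class = "classifier_spec"
  )
}

# features argument -> numeric matrix with stable column names
feature_matrix <- function(features, feature_names = NULL) {
  if (is.data.frame(features)) {
    if (is.null(feature_names)) {
      feature_names <- setdiff(names(features), c(".row", ".subset"))
      feature_names <- feature_names[vapply(
        features[feature_names], is.numeric,
        logical(1)
      )]
    }
    missing <- setdiff(feature_names, names(features))
    if (length(missing) > 0) {
      abort(paste0(
        "feature width mismatch: missing columns ",
        paste(head(missing, 5), collapse = ", ")
      ), class = "sarcloc_parameter_error")
    }
    X <- as.matrix(features[feature_names])
  } else {
    X <- as.matrix(features)
    if (is.null(colnames(X))) {
      colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
    }
    if (!is.null(feature_names)) {
      if (ncol(X) != length(feature_names)) {
        abort(paste0(
          "feature width mismatch: got ", ncol(X), " columns, model expects ",
          length(feature_names)
        ), class = "sarcloc_parameter_error")
      }
      colnames(X) <- feature_names
    }
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort("features contain NA or non-finite values",
      class = "sarcloc_parameter_error"
    )
  }
  X
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) {
    return(as.numeric(labels))
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      abort("numeric labels must be 0/1", class = "sarcloc_parameter_error")
    }
    return(as.numeric(labels))
  }
  as.numeric(labels == "object")
}

#' Fit the localization classifier
#'
#' Trains the one-hidden-layer network on per-localization feature vectors.
#' Any of the three feature sets can be used (combined 380-wide, distances
#' only, directions only); the validation set, when given, is only monitored,
#' never used for early stopping.
#'
#' @param features Feature tibble (from [featurize()]) or numeric matrix.
#' @param labels Truth labels: `"object"`/`"noise"`, logical, or 0/1.
#' @param spec A [classifier_spec()].
#' @param val_features,val_labels Optional validation data for loss
#'   monitoring.
#' @param feature_set Which columns of a feature tibble to train on
#'   (`"combined"`, `"distances"`, `"directions"`); ignored for plain
#'   matrices.
#' @param seed Integer RNG seed (weight initialization and epoch shuffling).
#' @return An object of class `sarcloc_mlp` with elements `weights`, `spec`,
#'   `history` (per-epoch loss tibble), `feature_names`.
#' @export
fit_classifier <- function(features, labels, spec = classifier_spec(),
                           val_features = NULL, val_labels = NULL,
                           feature_set = c("combined", "distances", "directions"),
                           seed = 1L) {
  feature_set <- match.arg(feature_set)
  feature_names <- if (is.data.frame(features) &&
    all(feature_col_names() %in% names(features))) {
    feature_cols(feature_set)
  } else {
    NULL
  }
  X <- feature_matrix(features, feature_names)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) {
    abort("`labels` length must match feature rows",
      class = "sarcloc_parameter_error"
    )
  }

  centre <- scale_sd <- NULL
  if (spec$standardize) {
    centre <- colMeans(X)
    scale_sd <- pmax(apply(X, 2, sd), .Machine$double.eps)
    X <- sweep(sweep(X, 2, centre), 2, scale_sd, "/")
  }

  has_val <- !is.null(val_features)
  Xv <- matrix(numeric(), 0, ncol(X))
  yv <- numeric()
  if (has_val) {
    Xv <- feature_matrix(val_features, colnames(X))
    yv <- as_binary_labels(val_labels)
    if (spec$standardize) {
      Xv <- sweep(sweep(Xv, 2, centre), 2, scale_sd, "/")
    }
  }

  fit <- mlp_train_cpp(
    X, y, spec$hidden_units, spec$epochs, spec$batch_size,
    spec$learning_rate, spec$beta1, spec$beta2, spec$adam_eps,
    as.integer(seed), Xv, yv
  )
  history <- tibble(
    epoch = seq_len(spec$epochs),
    loss = as.numeric(fit$loss),
    val_loss = if (has_val) as.numeric(fit$val_loss) else NA_real_
  )
  structure(
    list(
      weights = list(
        W1 = fit$W1, b1 = as.numeric(fit$b1),
        w2 = as.numeric(fit$w2), b2 = as.numeric(fit$b2)
      ),
      spec = spec, history = history, feature_names = colnames(X),
      centre = centre, scale = scale_sd, seed = as.integer(seed)
    ),
    class = "sarcloc_mlp"
  )
}

#' Predict localization classes
#'
#' @param object A fitted `sarcloc_mlp`.
#' @param features Feature tibble or matrix with the columns the model was
#'   trained on.
#' @param threshold Decision threshold; probabilities at or above it are
#'   labelled `"object"`. Defaults to the model's spec. A threshold of 0
#'   labels everything object; 1 labels everything noise.
#' @param ... Unused.
#' @return A tibble with `.prob` and `.pred` (`"object"`/`"noise"`); carries
#'   `.row` over from a feature tibble when present.
#' @export
predict.sarcloc_mlp <- function(object, features,
                                threshold = object$spec$threshold, ...) {
  X <- feature_matrix(features, object$feature_names)
  if (!is.null(object$centre)) {
    X <- sweep(sweep(X, 2, object$centre), 2, object$scale, "/")
  }
  prob <- as.numeric(mlp_forward_cpp(
    X, object$weights$W1, object$weights$b1,
    object$weights$w2, object$weights$b2
  ))
  out <- tibble(
    .prob = prob,
    .pred = if_else(prob >= threshold, "object", "noise")
  )
  if (is.data.frame(features) && ".row" %in% names(features)) {
    out <- dplyr::bind_cols(tibble(.row = features$.row), out)
  }
  out
}

#' Confusion metrics for a binary localization classification
#'
#' True-positive rate is the fraction of true object localizations classified
#' object; true-negative rate the fraction of true noise localizations
#' classified noise.
#'
#' @param pred_labels Predicted labels (`"object"`/`"noise"`, logical or 0/1).
#' @param true_labels Truth labels, same encoding.
#' @return One-row tibble: `tp`, `fn`, `tn`, `fp`, `tp_rate`, `tn_rate`.
#'   Rates are `NA` when the corresponding truth class is absent.
#' @export
evaluate_classification <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    abort("prediction and truth lengths differ",
      class = "sarcloc_parameter_error"
    )
  }
  pred <- as_binary_labels(pred_labels)
  truth <- as_binary_labels(true_labels)
  tp <- sum(pred == 1 & truth == 1)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    tp_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tn_rate = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Feature-set ablation of the classifier
#'
#' Trains three classifiers on the same corpus — distances only (350
#' columns), directions only (30 columns) and the combined 380-wide vector —
#' and evaluates each on the test split.
#'
#' @param features Feature tibble from [featurize()]/[featurize_corpus()].
#' @param labels Truth labels aligned with `features` rows.
#' @param split A list from [split_train_val_test()] with positions into
#'   `features` rows.
#' @param spec A [classifier_spec()].
#' @param seed Integer RNG seed.
#' @return A tibble with one row per feature set: confusion counts and
#'   TP/TN rates on the test split.
#' @export
run_ablation <- function(features, labels, split, spec = classifier_spec(),
                         seed = 1L) {
  purrr::map_dfr(
    c("distances", "directions", "combined"),
    function(set) {
      fit <- fit_classifier(
        features[split$train, ], labels[split$train],
        spec = spec,
        val_features = features[split$val, ], val_labels = labels[split$val],
        feature_set = set, seed = seed
      )
      pred <- predict(fit, features[split$test, ])
      dplyr::bind_cols(
        tibble(feature_set = set),
        evaluate_classification(pred$.pred, labels[split$test])
      )
    }
  )
}

#' @export
tidy.sarcloc_mlp <- function(x, ...) {
  x$history
}

#' @export
glance.sarcloc_mlp <- function(x, ...) {
  w <- x$weights
  tibble(
    hidden_units = x$spec$hidden_units,
    epochs = x$spec$epochs,
    n_features = length(x$feature_names),
    n_parameters = length(w$W1) + length(w$b1) + length(w$w2) + 1L,
    final_loss = tail(x$history$loss, 1),
    final_val_loss = tail(x$history$val_loss, 1)
  )
}

#' @export
print.sarcloc_mlp <- function(x, ...) {
  cat(
    "<sarcloc_mlp> ", length(x$feature_names), "-feature input, ",
    x$spec$hidden_units, " hidden units\n",
    "  final training loss: ", signif(tail(x$history$loss, 1), 4), "\n",
    sep = ""
  )
  invisible(x)
}
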